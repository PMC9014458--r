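#' Vertical and adiabatic electron detachment energies
#'
#' Bookkeeping for charge-state energy differences supplied by an external
#' electronic-structure engine. The vertical detachment energy (VDE) is the
#' energy of the (n-1)-charge state at the frozen geometry of the initial
#' state minus the initial-state energy; the adiabatic detachment energy
#' (ADE) uses the relaxed final-state geometry instead, so ADE <= VDE for a
#' well-behaved surface.
#'
#' @param records Data frame with columns `label`, `e_dianion_opt`
#'   (initial state at its own optimum), `e_monoanion_vertical` (final state
#'   at the SAME geometry), `e_monoanion_opt` (final state relaxed). Any
#'   column may be NA; the corresponding quantity comes out NA.
#' @param unit `"hartree"` or `"eV"`; hartree differences are converted at
#'   27.211386 eV/hartree.
#' @param includes_zpe Flag recorded in the output (whether the supplied
#'   energies carry zero-point/thermal corrections); the arithmetic is
#'   identical either way.
#' @return Tibble with `label`, `vde`, `ade` (eV) and `includes_zpe`.
#'   A negative VDE (unbound initial state) and any ADE > VDE row trigger a
#'   warning, not an error — the values are returned as computed.
#' @export
detachment_energies <- function(records, unit = c("hartree", "eV"),
                                includes_zpe = FALSE) {
  unit <- match.arg(unit)
  records <- tibble::as_tibble(records)
  needed <- c("label", "e_dianion_opt", "e_monoanion_vertical", "e_monoanion_opt")
  for (col in setdiff(needed, names(records))) records[[col]] <- NA_real_
  conv <- if (unit == "hartree") HARTREE_TO_EV else 1
  vde <- (records$e_monoanion_vertical - records$e_dianion_opt) * conv
  ade <- (records$e_monoanion_opt - records$e_dianion_opt) * conv
  neg <- which(!is.na(vde) & vde < 0)
  if (length(neg) > 0) {
    warning(
      "negative VDE (unbound dianion) for: ",
      paste(records$label[neg], collapse = ", "),
      call. = FALSE
    )
  }
  bad <- which(!is.na(vde) & !is.na(ade) & ade > vde + 1e-12)
  if (length(bad) > 0) {
    warning(
      "ADE > VDE for: ", paste(records$label[bad], collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(
    label = records$label, vde = vde, ade = ade,
    includes_zpe = includes_zpe
  )
}

#' @rdname detachment_energies
#' @param e_dianion_opt,e_monoanion_vertical,e_monoanion_opt Scalar energies.
#' @export
vertical_detachment_energy <- function(e_dianion_opt, e_monoanion_vertical,
                                       unit = c("hartree", "eV")) {
  unit <- match.arg(unit)
  conv <- if (unit == "hartree") HARTREE_TO_EV else 1
  vde <- (e_monoanion_vertical - e_dianion_opt) * conv
  if (!is.na(vde) && vde < 0) {
    warning("negative VDE: dianion electronically unbound at this geometry",
      call. = FALSE
    )
  }
  vde
}

#' @rdname detachment_energies
#' @export
adiabatic_detachment_energy <- function(e_dianion_opt, e_monoanion_opt,
                                        unit = c("hartree", "eV")) {
  unit <- match.arg(unit)
  conv <- if (unit == "hartree") HARTREE_TO_EV else 1
  (e_monoanion_opt - e_dianion_opt) * conv
}
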