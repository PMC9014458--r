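#' Counterpoise (BSSE) correction from fragment energies
#'
#' Generalized many-fragment counterpoise: for every fragment, the energy in
#' its own basis minus the energy in the full-cluster ("ghost") basis at the
#' cluster geometry, summed over fragments. Under the variational contract
#' the ghost-basis energy is the lower one, so the correction is >= 0; a
#' fragment violating that yields a warning and its (negative) contribution
#' is retained.
#'
#' @param fragments Data frame with columns `fragment` (id/label), `e_own`
#'   and `e_ghost` (fragment energy in its own and in the full-cluster
#'   basis).
#' @param unit `"hartree"` or `"kcal/mol"`.
#' @return BSSE correction in kcal/mol (scalar).
#' @export
counterpoise_correction <- function(fragments, unit = c("hartree", "kcal/mol")) {
  unit <- match.arg(unit)
  fragments <- tibble::as_tibble(fragments)
  if (!all(c("e_own", "e_ghost") %in% names(fragments))) {
    stop("fragments need e_own and e_ghost columns", call. = FALSE)
  }
  if (anyNA(fragments$e_own) || anyNA(fragments$e_ghost)) {
    stop("missing fragment energy entry", call. = FALSE)
  }
  contrib <- fragments$e_own - fragments$e_ghost
  if (unit == "hartree") contrib <- hartree_to_kcal(contrib)
  neg <- which(contrib < -1e-9)
  if (length(neg) > 0) {
    warning(
      "ghost-basis energy above own-basis energy for fragment(s) ",
      paste(neg, collapse = ", "),
      " (non-variational input); contribution retained",
      call. = FALSE
    )
  }
  sum(contrib)
}

#' BSSE-corrected water binding free energy
#'
#' The water binding energy (WBE) of an n-water cluster is the cluster free
#' energy minus the sum of the isolated-monomer free energies, plus the
#' counterpoise correction:
#' `WBE = G(cluster) - sum_frag G(frag, own basis) + BSSE`.
#' Negative values mean favourable binding.
#'
#' @param cluster_g Cluster free energy.
#' @param fragments Data frame as in [counterpoise_correction()]; one row
#'   per fragment (solute + each water).
#' @param n_waters Number of water molecules in the cluster.
#' @param unit `"hartree"` or `"kcal/mol"` for `cluster_g` and the fragment
#'   energies (one consistent unit).
#' @return Tibble (class `binding_result`) with `n_waters`, `wbe`,
#'   `wbe_per_water`, `bsse` (all kcal/mol).
#' @export
water_binding_free_energy <- function(cluster_g, fragments, n_waters,
                                      unit = c("hartree", "kcal/mol")) {
  unit <- match.arg(unit)
  fragments <- tibble::as_tibble(fragments)
  bsse <- counterpoise_correction(fragments, unit = unit)
  raw <- cluster_g - sum(fragments$e_own)
  if (unit == "hartree") raw <- hartree_to_kcal(raw)
  wbe <- raw + bsse
  out <- tibble::tibble(
    n_waters = as.integer(n_waters),
    wbe = wbe,
    wbe_per_water = wbe / n_waters,
    bsse = bsse
  )
  class(out) <- c("binding_result", class(out))
  out
}

#' Ordinary least-squares fit with coefficient of determination
#'
#' Thin wrapper over `stats::lm()` returning the slope, intercept and
#' R^2 = 1 - SS_res/SS_tot of a simple linear regression.
#'
#' @param x,y Numeric vectors (>= 2 points; `x` must not be constant).
#' @return Object of class `ols_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `model` (the underlying `lm`) and `data`.
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 points", call. = FALSE)
  if (diff(range(x)) == 0) stop("degenerate x: all values equal", call. = FALSE)
  d <- data.frame(x = x, y = y)
  m <- stats::lm(y ~ x, data = d)
  structure(
    list(
      slope = unname(stats::coef(m)[2]),
      intercept = unname(stats::coef(m)[1]),
      r_squared = summary(m)$r.squared,
      model = m,
      data = tibble::as_tibble(d)
    ),
    class = "ols_fit"
  )
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(
    "<ols_fit> y = ", signif(x$slope, 6), " x + ", signif(x$intercept, 6),
    ", R^2 = ", sprintf("%.4f", x$r_squared), "\n",
    sep = ""
  )
  invisible(x)
}

#' @method tidy ols_fit
#' @export
tidy.ols_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "x"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @method glance ols_fit
#' @export
glance.ols_fit <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared,
    slope = x$slope,
    intercept = x$intercept,
    n = nrow(x$data)
  )
}

#' Regress per-water binding free energy on detachment-energy shifts
#'
#' Correlates the per-water binding free energy `WBE/n` against the
#' incremental vertical-detachment-energy shift `VDE(n) - VDE(n-1)` across
#' cluster sizes — the stronger each added water binds, the larger the extra
#' electrostatic stabilisation of the excess charge it provides.
#'
#' @param binding Data frame with `n_waters` and `wbe` (kcal/mol), one row
#'   per cluster size in increasing n.
#' @param vde_series Numeric vector of VDEs (eV) ordered by n, INCLUDING the
#'   bare (n = 0) cluster as its first element, so that incremental shifts
#'   align with `binding$n_waters`.
#' @return An [ols_fit()] with `x` = incremental VDE shift (eV) and `y` =
#'   WBE per water (kcal/mol); the fitted data are kept in `$data` with
#'   column names `shift` and `wbe_per_water` as well.
#' @export
wbe_vde_regression <- function(binding, vde_series) {
  binding <- dplyr::arrange(tibble::as_tibble(binding), .data$n_waters)
  shifts <- incremental_shifts(vde_series)
  if (length(shifts) != nrow(binding)) {
    stop("vde_series must have one more entry than binding has rows",
      call. = FALSE
    )
  }
  per_water <- binding$wbe / binding$n_waters
  fit <- ols_fit(shifts, per_water)
  fit$data$shift <- shifts
  fit$data$wbe_per_water <- per_water
  fit$data$n_waters <- binding$n_waters
  fit
}
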