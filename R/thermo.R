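#' Relative Gibbs free energies
#'
#' Subtracts the minimum from a set of absolute (or already-relative) free
#' energies so the most stable record gets exactly 0. Hartree inputs are
#' converted to kcal/mol (627.5095 kcal/mol per hartree).
#'
#' @param energies Data frame with columns `label` and `g` (or a named/plain
#'   numeric vector).
#' @param unit `"kcal/mol"` or `"hartree"`; must be declared, no
#'   autodetection.
#' @return Tibble with `label` and `delta_g` (kcal/mol).
#' @export
relative_free_energies <- function(energies, unit = c("kcal/mol", "hartree")) {
  unit <- match.arg(unit)
  if (is.numeric(energies)) {
    labels <- names(energies)
    if (is.null(labels)) labels <- as.character(seq_along(energies))
    energies <- tibble::tibble(label = labels, g = as.numeric(energies))
  }
  if (nrow(energies) == 0) stop("no energies supplied", call. = FALSE)
  g <- energies$g
  if (unit == "hartree") g <- hartree_to_kcal(g)
  tibble::tibble(label = energies$label, delta_g = g - min(g))
}

#' Boltzmann equilibrium fractions of a conformer ensemble
#'
#' Converts relative Gibbs free energies into equilibrium populations
#' `x_i = exp(-dG_i/RT) / sum_j exp(-dG_j/RT)` with
#' R = 0.0019872 kcal mol^-1 K^-1. Free energies are shifted by their
#' minimum before exponentiation so large dG cannot underflow the
#' normalisation.
#'
#' @param delta_g Numeric vector of relative free energies (kcal/mol).
#' @param temperature Temperature in kelvin (> 0); default 298.15.
#' @return Numeric vector of fractions summing to 1.
#' @examples
#' equilibrium_fractions(c(0, 0.5922), temperature = 298) # approx. RT split
#' @export
equilibrium_fractions <- function(delta_g, temperature = 298.15) {
  if (length(delta_g) == 0) stop("empty free-energy set", call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  w <- exp(-(delta_g - min(delta_g)) / (R_KCAL * temperature))
  w / sum(w)
}

#' Population-weighted ensemble observable
#'
#' @param values Numeric vector of per-conformer observables.
#' @param weights Non-negative weights (equilibrium fractions); need not sum
#'   to 1.
#' @param renormalize If `TRUE` (default) divide by `sum(weights)`, so the
#'   result is a weighted mean lying within the range of `values`; if
#'   `FALSE` return the plain weighted sum.
#' @return Scalar.
#' @export
weighted_observable <- function(values, weights, renormalize = TRUE) {
  if (length(values) != length(weights)) {
    stop("values and weights differ in length", call. = FALSE)
  }
  if (any(weights < 0)) stop("negative weights", call. = FALSE)
  if (sum(weights) <= 0) stop("weights sum to zero", call. = FALSE)
  s <- sum(values * weights)
  if (renormalize) s / sum(weights) else s
}

#' Incremental shifts of an observable along cluster size
#'
#' For a series of values ordered by the number of bound waters n, returns
#' the consecutive differences `value[n] - value[n-1]` — the per-water shift
#' of, e.g., the vertical detachment energy.
#'
#' @param series Numeric vector ordered by n (length >= 2).
#' @return Numeric vector of length `length(series) - 1`.
#' @export
incremental_shifts <- function(series) {
  if (length(series) < 2) stop("need at least 2 entries", call. = FALSE)
  diff(series)
}

#' Build a population-weighted conformer table
#'
#' The quantitative core of the ensemble analysis: equilibrium fractions are
#' computed over the FULL record set, weighted-average VDE and ADE are taken
#' over the full set, and records below `population_threshold` are only
#' hidden from display (column `displayed`), never dropped from the
#' computation.
#'
#' @param records Data frame with columns `label`, `delta_g` (kcal/mol;
#'   alternatively `g` + `unit` for absolute energies), `vde`, `ade` (eV).
#' @param temperature Kelvin; default 298.15.
#' @param population_threshold Display cutoff on x_m; default 0.01.
#' @param unit Unit of a `g` column if `delta_g` is absent.
#' @return A `thermo_table`: tibble with `label`, `delta_g`, `vde`, `ade`,
#'   `x_m`, `displayed`, plus attributes `temperature`, `weighted_vde`,
#'   `weighted_ade`, `population_threshold`.
#' @export
build_thermo_table <- function(records, temperature = 298.15,
                               population_threshold = 0.01,
                               unit = c("kcal/mol", "hartree")) {
  records <- tibble::as_tibble(records)
  if (anyDuplicated(records$label)) {
    stop("duplicate conformer labels in thermo records", call. = FALSE)
  }
  if (!"delta_g" %in% names(records)) {
    if (!"g" %in% names(records)) {
      stop("records need a delta_g or g column", call. = FALSE)
    }
    rel <- relative_free_energies(records[, c("label", "g")], unit = unit)
    records$delta_g <- rel$delta_g
  }
  if (any(records$delta_g < 0)) {
    records$delta_g <- records$delta_g - min(records$delta_g)
  }
  x_m <- equilibrium_fractions(records$delta_g, temperature)
  out <- dplyr::mutate(
    records[, intersect(c("label", "delta_g", "vde", "ade"), names(records))],
    x_m = x_m,
    displayed = x_m >= population_threshold
  )
  if (all(c("vde", "ade") %in% names(out))) {
    bad <- which(out$ade > out$vde + 1e-9)
    if (length(bad) > 0) {
      warning(
        "ADE exceeds VDE for: ", paste(out$label[bad], collapse = ", "),
        call. = FALSE
      )
    }
  }
  structure(
    out,
    temperature = temperature,
    population_threshold = population_threshold,
    weighted_vde = if ("vde" %in% names(out)) {
      weighted_observable(out$vde, x_m)
    } else {
      NA_real_
    },
    weighted_ade = if ("ade" %in% names(out)) {
      weighted_observable(out$ade, x_m)
    } else {
      NA_real_
    },
    class = c("thermo_table", class(out))
  )
}

#' @export
print.thermo_table <- function(x, ...) {
  cat(
    "<thermo_table> ", nrow(x), " conformer(s) at ",
    attr(x, "temperature"), " K; weighted VDE ",
    round(attr(x, "weighted_vde"), 2), " eV, weighted ADE ",
    round(attr(x, "weighted_ade"), 2), " eV\n",
    sep = ""
  )
  print(format_thermo_table(x, displayed_only = FALSE))
  invisible(x)
}

#' Format a thermo table at report precision
#'
#' Mirrors the conventional table layout: relative free energies to one
#' decimal, detachment energies to two, equilibrium fractions to two.
#' Internal computation always keeps full precision; rounding happens only
#' here.
#'
#' @param tt A [build_thermo_table()] result.
#' @param displayed_only Keep only rows with `x_m >=` the population
#'   threshold (default `TRUE`).
#' @return Tibble of character-free rounded numeric columns.
#' @export
format_thermo_table <- function(tt, displayed_only = TRUE) {
  rows <- if (displayed_only) tt[tt$displayed, ] else tt
  tibble::tibble(
    label = rows$label,
    delta_g = round(rows$delta_g, 1),
    vde = if ("vde" %in% names(rows)) round(rows$vde, 2) else NULL,
    ade = if ("ade" %in% names(rows)) round(rows$ade, 2) else NULL,
    x_m = round(rows$x_m, 2)
  )
}

#' @method tidy thermo_table
#' @export
tidy.thermo_table <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @method glance thermo_table
#' @export
glance.thermo_table <- function(x, ...) {
  tibble::tibble(
    temperature = attr(x, "temperature"),
    n_conformers = nrow(x),
    n_displayed = sum(x$displayed),
    weighted_vde = attr(x, "weighted_vde"),
    weighted_ade = attr(x, "weighted_ade"),
    population_threshold = attr(x, "population_threshold")
  )
}
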