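#' Published reference data for microhydrated guanosine-phosphate dianions
#'
#' Per-conformer thermochemistry and detachment energies reported for
#' doubly deprotonated 2'-deoxyguanosine-5'-monophosphate hydrated by one to
#' four waters, `[dGMP - 2H]^2- . nH2O` (n = 1-4): relative Gibbs free
#' energies (kcal/mol), vertical and adiabatic detachment energies (eV) and
#' the printed equilibrium fractions `x_m` of every conformer populated at
#' `x_m >= 0.01`. These tables are inputs to the weighting and regression
#' stages — the package recomputes the ensemble aggregates from them.
#'
#' @param n Optional vector of cluster sizes to keep (1-4).
#' @return `dgmp_conformer_tables()`: tibble with `n_waters`, `label`,
#'   `delta_g`, `vde`, `ade`, `x_m`.
#' @export
dgmp_conformer_tables <- function(n = NULL) {
  out <- read_extdata("dgmp_conformer_tables.tsv")
  if (!is.null(n)) out <- out[out$n_waters %in% n, ]
  out
}

#' @rdname dgmp_conformer_tables
#' @return `dgmp_experimental_energies()`: tibble with `n_waters`,
#'   `vde_exp`, `ade_exp` (eV) from the photoelectron measurements; the
#'   n = 0 row is the bare-dianion reference implied by the 0.50 eV
#'   first-water shift.
#' @export
dgmp_experimental_energies <- function() {
  read_extdata("dgmp_experimental_energies.tsv")
}

#' @rdname dgmp_conformer_tables
#' @return `dgmp_binding_energies()`: tibble with `n_waters` and `wbe`, the
#'   BSSE-corrected water binding free energy (kcal/mol) of the n-water
#'   cluster.
#' @export
dgmp_binding_energies <- function() {
  read_extdata("dgmp_binding_energies.tsv")
}

read_extdata <- function(name) {
  path <- system.file("extdata", name, package = "microsolv", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
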