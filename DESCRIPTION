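Package: microsolv
Title: Conformer Ensembles and Electron Detachment Energetics of Microsolvated Ion Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for microsolvated ion clusters sampled by
    molecular simulation: RMSD-based conformational clustering (Kabsch
    superposition with optimal solvent-permutation matching, Daura
    neighbour-count clustering), Boltzmann equilibrium-fraction weighting of
    conformer free energies, population-weighted vertical and adiabatic
    electron detachment energies, counterpoise (BSSE) corrected water binding
    free energies with per-water regression against detachment-energy shifts,
    and geometric hydrogen-bond classification of hydration sites. Includes a
    rigid-water Metropolis Monte Carlo generator with a known-ground-truth
    detachment-energy model so the full pipeline is testable end to end, plus
    readers and writers for multi-frame extended XYZ.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    readr,
    jsonlite,
    ggplot2,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    knitr,
    rmarkdown
Config/testthat/edition: 3
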