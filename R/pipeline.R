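#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Two modes:
#' \describe{
#'   \item{`synthetic`}{Generate ensembles with the toy Monte Carlo sampler
#'     for each cluster size in `n_waters`, cluster them, attach synthetic
#'     detachment energies and classify hydration sites.}
#'   \item{`from_files`}{Load per-conformer energy tables (TSV with columns
#'     `label`, `delta_g` (kcal/mol), `vde`, `ade` (eV)) — one file per
#'     cluster size — and run the weighting stages; optionally regress
#'     binding energies against a supplied VDE series.}
#' }
#'
#' @param mode `"synthetic"` or `"from_files"`.
#' @param n_waters Cluster sizes to run (synthetic mode).
#' @param params A [toy_model_params()] template (its `n_waters` and `seed`
#'   are overridden per size).
#' @param model An [observable_model()].
#' @param energy_files Named list (names = cluster size) of TSV paths
#'   (from_files mode).
#' @param binding_file Optional TSV with `n_waters`, `wbe` (kcal/mol).
#' @param vde_series Optional numeric VDE ladder (eV) starting at n = 0,
#'   used with `binding_file` for the WBE regression.
#' @param temperature Kelvin.
#' @param cluster_cutoff RMSD cutoff (Angstrom) for Daura clustering.
#' @param population_threshold Display threshold on equilibrium fractions.
#' @param hbond_d_max,hbond_angle_min Hydrogen-bond criteria (Angstrom,
#'   degrees).
#' @param seed Integer master seed; per-stage seeds are derived from it.
#' @param output_dir Directory for report artefacts (created if needed);
#'   `NULL` to skip writing.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "from_files"),
                            n_waters = 1:2,
                            params = toy_model_params(),
                            model = observable_model(),
                            energy_files = NULL,
                            binding_file = NULL,
                            vde_series = NULL,
                            temperature = 298.15,
                            cluster_cutoff = 1.0,
                            population_threshold = 0.01,
                            hbond_d_max = 3.5,
                            hbond_angle_min = 140,
                            seed = 1L,
                            output_dir = NULL) {
  mode <- match.arg(mode)
  if (is.null(cluster_cutoff) || !is.numeric(cluster_cutoff) ||
    cluster_cutoff <= 0) {
    stop("cluster_cutoff must be a positive number", call. = FALSE)
  }
  if (is.null(temperature) || temperature <= 0) {
    stop("temperature must be > 0", call. = FALSE)
  }
  if (mode == "from_files" && is.null(energy_files)) {
    stop("from_files mode requires energy_files", call. = FALSE)
  }
  if (mode == "synthetic" && length(n_waters) == 0) {
    stop("synthetic mode requires at least one cluster size", call. = FALSE)
  }
  structure(
    list(
      mode = mode, n_waters = as.integer(n_waters), params = params,
      model = model, energy_files = energy_files,
      binding_file = binding_file, vde_series = vde_series,
      temperature = temperature, cluster_cutoff = cluster_cutoff,
      population_threshold = population_threshold,
      hbond_d_max = hbond_d_max, hbond_angle_min = hbond_angle_min,
      seed = as.integer(seed), output_dir = output_dir
    ),
    class = "pipeline_config"
  )
}

# Deterministic per-stage seed derivation from the master seed (kept below
# 2^31 - 1).
derive_seed <- function(seed, stage_index) {
  as.integer((as.double(seed) * 48271 + 1013904223 * stage_index) %% 2147483647)
}

#' Run the full microsolvation analysis pipeline
#'
#' Sample (or load) per-cluster-size conformer sets, cluster, weight,
#' average, regress and classify, then write tables, a JSON summary and a
#' run log. The run is fully determined by the config and its seed.
#'
#' @param config A [pipeline_config()].
#' @return List (invisibly if `output_dir` is set) with elements
#'   `thermo_tables` (per size), `site_occupancy` (per size, synthetic
#'   mode), `weighted` (tibble of weighted VDE/ADE per size), `shifts`
#'   (incremental VDE shifts), `regression` (an [ols_fit()] or `NULL`) and
#'   `summary` (the list written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- c(
    "microsolv pipeline run",
    paste0("mode = ", config$mode),
    paste0("seed = ", config$seed),
    paste0("temperature_K = ", config$temperature),
    paste0("cluster_cutoff_A = ", config$cluster_cutoff),
    paste0("population_threshold = ", config$population_threshold),
    paste0("hbond_d_max_A = ", config$hbond_d_max),
    paste0("hbond_angle_min_deg = ", config$hbond_angle_min)
  )
  thermo_tables <- list()
  occupancies <- list()
  representatives_by_n <- list()

  if (config$mode == "synthetic") {
    sizes <- config$n_waters
    for (k in seq_along(sizes)) {
      n <- sizes[k]
      p <- config$params
      p$n_waters <- n
      p$seed <- derive_seed(config$seed, k)
      p$temperature <- config$temperature
      solute <- build_toy_solute(p)
      ens <- sample_configurations(solute, p)
      if (!is.null(attr(ens, "sampling_warning"))) {
        log_lines <- c(log_lines, paste0(
          "WARNING n=", n, ": ",
          attr(ens, "sampling_warning")
        ))
      }
      mat <- rmsd_matrix(ens)
      asg <- cluster_daura(mat, cutoff = config$cluster_cutoff)
      reps <- select_representatives(asg, ens)
      # cluster populations -> effective free energies, so the thermo stage
      # applies uniformly to sampled and file-based inputs
      sizes_k <- vapply(reps, function(r) attr(r, "cluster_size"), numeric(1))
      delta_g_eff <- -R_KCAL * config$temperature *
        log(sizes_k / max(sizes_k))
      m <- config$model
      m$seed <- derive_seed(config$seed, 1000L + k)
      obs <- assign_observables(reps, m,
        d_max = config$hbond_d_max, angle_min = config$hbond_angle_min
      )
      records <- dplyr::mutate(obs, delta_g = delta_g_eff)
      tt <- build_thermo_table(records[, c("label", "delta_g", "vde", "ade")],
        temperature = config$temperature,
        population_threshold = config$population_threshold
      )
      thermo_tables[[as.character(n)]] <- tt
      representatives_by_n[[as.character(n)]] <- reps
      occupancies[[as.character(n)]] <- site_occupancy(reps, tt,
        d_max = config$hbond_d_max, angle_min = config$hbond_angle_min
      )
      log_lines <- c(log_lines, sprintf(
        "n=%d: %d frames, %d clusters, acceptance %.3f",
        n, length(ens), length(asg$cluster_sizes),
        attr(ens, "acceptance_rate")
      ))
    }
  } else {
    for (nm in names(config$energy_files)) {
      records <- readr::read_tsv(config$energy_files[[nm]],
        show_col_types = FALSE, progress = FALSE
      )
      tt <- build_thermo_table(records,
        temperature = config$temperature,
        population_threshold = config$population_threshold
      )
      thermo_tables[[nm]] <- tt
      log_lines <- c(log_lines, sprintf(
        "n=%s: %d conformer records from %s",
        nm, nrow(tt), config$energy_files[[nm]]
      ))
    }
  }

  weighted <- purrr::imap_dfr(thermo_tables, function(tt, nm) {
    tibble::tibble(
      n_waters = as.integer(nm),
      weighted_vde = attr(tt, "weighted_vde"),
      weighted_ade = attr(tt, "weighted_ade")
    )
  })
  weighted <- dplyr::arrange(weighted, .data$n_waters)

  vde_series <- config$vde_series
  if (is.null(vde_series) && config$mode == "synthetic") {
    vde_series <- c(config$model$vde0, weighted$weighted_vde)
  }
  shifts <- if (!is.null(vde_series) && length(vde_series) >= 2) {
    incremental_shifts(vde_series)
  } else if (nrow(weighted) >= 2) {
    incremental_shifts(weighted$weighted_vde)
  } else {
    numeric(0)
  }

  regression <- NULL
  if (!is.null(config$binding_file)) {
    binding <- readr::read_tsv(config$binding_file,
      show_col_types = FALSE, progress = FALSE
    )
    if (is.null(vde_series)) {
      stop("binding regression needs a vde_series starting at n = 0",
        call. = FALSE
      )
    }
    regression <- wbe_vde_regression(binding, vde_series)
  }

  summary <- list(
    mode = config$mode,
    seed = config$seed,
    temperature_K = config$temperature,
    cluster_cutoff_A = config$cluster_cutoff,
    population_threshold = config$population_threshold,
    hbond_criteria = list(
      d_max_A = config$hbond_d_max,
      angle_min_deg = config$hbond_angle_min
    ),
    weighted = weighted,
    incremental_vde_shifts = shifts,
    regression = if (!is.null(regression)) {
      list(
        slope = regression$slope, intercept = regression$intercept,
        r_squared = regression$r_squared
      )
    } else {
      NULL
    },
    site_occupancy = purrr::map(
      occupancies,
      ~ as.data.frame(.x[, c("site", "weighted_count", "fraction")])
    )
  )

  out <- list(
    thermo_tables = thermo_tables,
    representatives = representatives_by_n,
    site_occupancy = occupancies,
    weighted = weighted,
    shifts = shifts,
    regression = regression,
    summary = summary,
    log = log_lines
  )

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(thermo_tables)) {
      readr::write_tsv(
        format_thermo_table(thermo_tables[[nm]]),
        file.path(config$output_dir, sprintf("thermo_n%s.tsv", nm))
      )
    }
    for (nm in names(occupancies)) {
      readr::write_tsv(
        occupancies[[nm]],
        file.path(config$output_dir, sprintf("sites_n%s.tsv", nm))
      )
    }
    jsonlite::write_json(summary,
      file.path(config$output_dir, "summary.json"),
      auto_unbox = TRUE, digits = 10, pretty = TRUE
    )
    writeLines(log_lines, file.path(config$output_dir, "run.log"))
    return(invisible(out))
  }
  out
}
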