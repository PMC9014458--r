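#' Geometric hydrogen-bond detection
#'
#' Finds all donor-H...acceptor triplets with donor-acceptor distance
#' `d(D...A) <= d_max` and angle `angle(D-H...A) >= angle_min`. Donors are
#' N/O atoms carrying a covalently bonded hydrogen (same fragment, within
#' 1.2 Angstrom); acceptors are N/O atoms. Pairs within the same fragment
#' are excluded — only solute-water and water-water bonds are reported.
#'
#' @param conf A [conformer()]. Every water fragment must carry its two
#'   hydrogens; a water oxygen with no covalent hydrogen is a tagging error.
#' @param d_max Donor-acceptor distance cutoff (Angstrom), default 3.5.
#' @param angle_min Minimum D-H...A angle (degrees), default 140.
#' @return Tibble with one row per hydrogen bond: `donor`, `hydrogen`,
#'   `acceptor` (atom row indices), `donor_fragment`, `acceptor_fragment`,
#'   `acceptor_site` (atom site tag of the acceptor), `d_da` (Angstrom),
#'   `angle_dha` (degrees).
#' @export
detect_hbonds <- function(conf, d_max = 3.5, angle_min = 140) {
  atoms <- conf$atoms
  xyz <- coords_matrix(conf)
  n <- nrow(atoms)
  d <- as.matrix(stats::dist(xyz))
  heavy_no <- which(atoms$element %in% c("N", "O"))
  hydro <- which(atoms$element == "H")

  # covalent D-H pairs (same fragment, within 1.2 A)
  donors <- list()
  for (h in hydro) {
    cand <- heavy_no[atoms$fragment_id[heavy_no] == atoms$fragment_id[h] &
      d[h, heavy_no] <= 1.2]
    if (length(cand) > 0) {
      dd <- cand[which.min(d[h, cand])]
      donors[[length(donors) + 1L]] <- c(donor = dd, hydrogen = h)
    }
  }
  # every water oxygen must be a donor twice
  for (w in seq_len(conf$n_waters)) {
    o <- which(atoms$fragment_id == w & atoms$element == "O")
    nh <- sum(vapply(donors, function(p) p[["donor"]] == o, logical(1)))
    if (nh < 2) {
      stop("water fragment ", w, " lacks covalent hydrogens on its oxygen",
        call. = FALSE
      )
    }
  }

  rows <- list()
  for (p in donors) {
    dd <- p[["donor"]]
    h <- p[["hydrogen"]]
    acc <- heavy_no[atoms$fragment_id[heavy_no] != atoms$fragment_id[dd] &
      d[dd, heavy_no] <= d_max]
    for (a in acc) {
      v1 <- xyz[dd, ] - xyz[h, ]
      v2 <- xyz[a, ] - xyz[h, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      if (ang >= angle_min) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          donor = dd, hydrogen = h, acceptor = a,
          donor_fragment = atoms$fragment_id[dd],
          acceptor_fragment = atoms$fragment_id[a],
          acceptor_site = atoms$site_tag[a],
          d_da = d[dd, a], angle_dha = ang
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      donor = integer(0), hydrogen = integer(0), acceptor = integer(0),
      donor_fragment = integer(0), acceptor_fragment = integer(0),
      acceptor_site = character(0), d_da = numeric(0), angle_dha = numeric(0)
    ))
  }
  dplyr::bind_rows(rows)
}

#' Classify the hydration site of one water molecule
#'
#' Maps each hydrogen bond the water makes (as donor or acceptor) to a
#' hydration-site label: bonds to solute atoms use the partner atom's site
#' tag (`AMINE_N10`, `PHOSPHATE`, `PURINE_RING` for ring N and carbonyl O,
#' `RIBOSE_OH`), bonds to another water are `WATER_WATER`. The primary site
#' is chosen by the priority AMINE_N10 > PHOSPHATE > PURINE_RING >
#' RIBOSE_OH > WATER_WATER; a water with no hydrogen bond is `NONE`.
#'
#' @param conf A [conformer()].
#' @param water_id Water fragment id (1-based).
#' @param hbonds Result of [detect_hbonds()] on `conf` (computed if
#'   missing).
#' @param ... Passed to [detect_hbonds()] when `hbonds` is missing.
#' @return List with `sites` (character multiset, one entry per hydrogen
#'   bond of this water) and `primary` (single label).
#' @export
classify_water_site <- function(conf, water_id, hbonds = NULL, ...) {
  if (water_id < 1 || water_id > conf$n_waters) {
    stop("unknown water_id: ", water_id, call. = FALSE)
  }
  if (is.null(hbonds)) hbonds <- detect_hbonds(conf, ...)
  mine <- hbonds[hbonds$donor_fragment == water_id |
    hbonds$acceptor_fragment == water_id, ]
  if (nrow(mine) == 0) {
    return(list(sites = character(0), primary = "NONE"))
  }
  site_of_bond <- function(k) {
    row <- mine[k, ]
    partner_frag <- if (row$donor_fragment == water_id) {
      row$acceptor_fragment
    } else {
      row$donor_fragment
    }
    if (partner_frag >= 1L) {
      return("WATER_WATER")
    }
    partner_atom <- if (row$donor_fragment == water_id) row$acceptor else row$donor
    unname(SITE_OF_TAG[conf$atoms$site_tag[partner_atom]])
  }
  sites <- vapply(seq_len(nrow(mine)), site_of_bond, character(1))
  named <- sites[sites != "NONE"]
  primary <- if (length(named) == 0) {
    "NONE"
  } else {
    named[order(match(named, HYDRATION_SITES))][1]
  }
  list(sites = sites, primary = primary)
}

#' Per-water site table for a conformer
#'
#' @param conf A [conformer()].
#' @param ... Passed to [detect_hbonds()].
#' @return Tibble with `water_id`, `primary_site`, `n_hbonds`, `sites`
#'   (list-column of the full multiset).
#' @export
water_site_table <- function(conf, ...) {
  hb <- detect_hbonds(conf, ...)
  purrr::map_dfr(seq_len(conf$n_waters), function(w) {
    cls <- classify_water_site(conf, w, hbonds = hb)
    tibble::tibble(
      water_id = w,
      primary_site = cls$primary,
      n_hbonds = length(cls$sites),
      sites = list(cls$sites)
    )
  })
}

#' Population-weighted hydration-site occupancy
#'
#' For each representative conformer, every water contributes its
#' equilibrium fraction `x_m` to the weighted count of its primary site.
#' The weighted counts therefore sum to `sum_conformers x_m * n_waters`.
#'
#' @param representatives List of [conformer()] objects (e.g. from
#'   [select_representatives()]).
#' @param thermo A data frame with `label` and `x_m` matching the
#'   representatives' labels (e.g. a [build_thermo_table()] result).
#' @param ... Hydrogen-bond criteria passed to [detect_hbonds()].
#' @return Tibble (class `site_occupancy`) with one row per site:
#'   `site`, `weighted_count`, `fraction` (of the total weighted water
#'   count).
#' @export
site_occupancy <- function(representatives, thermo, ...) {
  labels <- vapply(representatives, function(c) c$label, character(1))
  if (!all(labels %in% thermo$label)) {
    stop(
      "representative label(s) missing from thermo records: ",
      paste(setdiff(labels, thermo$label), collapse = ", "),
      call. = FALSE
    )
  }
  weights <- thermo$x_m[match(labels, thermo$label)]
  counts <- stats::setNames(numeric(length(HYDRATION_SITES)), HYDRATION_SITES)
  for (k in seq_along(representatives)) {
    conf <- representatives[[k]]
    if (conf$n_waters == 0) next
    st <- water_site_table(conf, ...)
    for (s in st$primary_site) counts[s] <- counts[s] + weights[k]
  }
  total <- sum(counts)
  out <- tibble::tibble(
    site = names(counts),
    weighted_count = unname(counts),
    fraction = if (total > 0) unname(counts) / total else 0
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$weighted_count))
  class(out) <- c("site_occupancy", class(out))
  out
}
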