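#' Parameters for the toy microsolvation model
#'
#' A desk-scale stand-in for the simulation and electronic-structure engines:
#' rigid point-charge waters around a rigid dianion with two unit-negative
#' sites (a deprotonated-amine-like nitrogen and a phosphate-like oxygen)
#' separated by `site_separation`. Interactions are Coulomb
#' (332.0637 q_i q_j / r, kcal/mol) between all intermolecular atom pairs
#' plus a single Lennard-Jones term between heavy (non-H) atom pairs.
#' Restricting LJ to heavy atoms keeps a single (sigma, epsilon) pair while
#' still letting hydrogens reach hydrogen-bonding distances.
#'
#' @param n_waters Number of water molecules.
#' @param temperature Kelvin.
#' @param mc_steps Metropolis Monte Carlo steps.
#' @param burn_in Steps discarded before recording (default `mc_steps / 5`).
#' @param stride Record every `stride`-th post-burn-in step.
#' @param max_translation Maximum local translation per move (Angstrom).
#' @param max_rotation Maximum local rotation per move (degrees).
#' @param p_jump Probability of a long-range jump move (uniform reposition
#'   inside the sampling sphere with uniform orientation); keeps basins
#'   separated by many kT mutually reachable.
#' @param sample_radius Hard-wall confinement radius (Angstrom) for water
#'   oxygens, centred on the solute centroid; default solute extent + 6.
#' @param water_charges Numeric `c(q_O, q_H)` in e.
#' @param lj_sigma,lj_epsilon Lennard-Jones parameters (Angstrom, kcal/mol).
#' @param site_separation Distance between the two charged solute sites
#'   (Angstrom).
#' @param solute_sites Data frame of solute atoms (`element`, `x`, `y`, `z`,
#'   `charge`, `site_tag`); default [default_solute_sites()].
#' @param seed Integer seed; identical seeds give bit-identical
#'   trajectories.
#' @return List of class `toy_model_params`.
#' @export
toy_model_params <- function(n_waters = 1,
                             temperature = 298.15,
                             mc_steps = 20000,
                             burn_in = NULL,
                             stride = 50,
                             max_translation = 0.3,
                             max_rotation = 30,
                             p_jump = 0.1,
                             sample_radius = NULL,
                             water_charges = c(-0.834, 0.417),
                             lj_sigma = 3.0,
                             lj_epsilon = 0.15,
                             site_separation = 8,
                             solute_sites = default_solute_sites(site_separation),
                             seed = 1L) {
  if (mc_steps <= 0) stop("mc_steps must be > 0", call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  if (lj_sigma <= 0) stop("lj_sigma must be > 0", call. = FALSE)
  if (lj_epsilon < 0) stop("lj_epsilon must be >= 0", call. = FALSE)
  if (is.null(burn_in)) burn_in <- floor(mc_steps / 5)
  structure(
    list(
      n_waters = as.integer(n_waters), temperature = temperature,
      mc_steps = as.integer(mc_steps), burn_in = as.integer(burn_in),
      stride = as.integer(stride),
      max_translation = max_translation, max_rotation = max_rotation,
      p_jump = p_jump, sample_radius = sample_radius,
      water_charges = water_charges,
      lj_sigma = lj_sigma, lj_epsilon = lj_epsilon,
      site_separation = site_separation,
      solute_sites = tibble::as_tibble(solute_sites),
      seed = as.integer(seed)
    ),
    class = "toy_model_params"
  )
}

#' @rdname toy_model_params
#' @export
default_solute_sites <- function(site_separation = 8) {
  tibble::tibble(
    element = c("N", "O", "N", "O", "O"),
    x = c(0, 1.4, 2.6, 5.0, site_separation),
    y = c(0, -1.2, 0.8, 1.8, 0),
    z = c(0, 0, 0, 0.5, 0),
    charge = c(-1, 0, 0, 0, -1),
    site_tag = c(
      "AMINE_N10", "PURINE_O11", "PURINE_RING_N", "RIBOSE_OH",
      "PHOSPHATE_O"
    )
  )
}

#' Build the rigid toy dianion
#'
#' @param params A [toy_model_params()].
#' @return A [conformer()] with `fragment_id = 0` and total charge -2. At
#'   least two solute sites must carry charge; the default carries exactly
#'   two unit-negative sites tagged `AMINE_N10` and `PHOSPHATE_O`.
#' @export
build_toy_solute <- function(params = toy_model_params()) {
  sites <- params$solute_sites
  if (nrow(sites) == 0) stop("solute_sites is empty", call. = FALSE)
  if (sum(sites$charge != 0) < 2) {
    stop("toy solute needs at least two charged sites", call. = FALSE)
  }
  atoms <- tibble::tibble(
    element = sites$element,
    x = sites$x, y = sites$y, z = sites$z,
    fragment_id = 0L,
    site_tag = sites$site_tag,
    charge = sites$charge
  )
  conformer(atoms,
    label = "toy_solute",
    total_charge = as.integer(round(sum(sites$charge)))
  )
}

#' Toy intermolecular energy
#'
#' `E = sum over intermolecular pairs [ 332.0637 q_i q_j / r_ij ] +
#' sum over intermolecular heavy-atom pairs [ 4 eps ((sigma/r)^12 -
#' (sigma/r)^6) ]` in kcal/mol. Intramolecular pairs never contribute
#' (fragments are rigid).
#'
#' @param conf A [conformer()] whose atoms carry a `charge` column, or a
#'   plain atom tibble with `element`, `x`, `y`, `z`, `fragment_id`,
#'   `charge` (handy for point-charge fixtures that are not waters).
#' @param params A [toy_model_params()] (supplies sigma and epsilon).
#' @return Energy in kcal/mol; 0 for a configuration with a single fragment.
#' @export
toy_energy <- function(conf, params = toy_model_params()) {
  atoms <- if (inherits(conf, "conformer")) conf$atoms else tibble::as_tibble(conf)
  if (!"charge" %in% names(atoms)) atoms$charge <- 0
  xyz <- unname(as.matrix(atoms[, c("x", "y", "z")]))
  n <- nrow(atoms)
  if (n < 2) {
    return(0)
  }
  d <- as.matrix(stats::dist(xyz))
  inter <- outer(atoms$fragment_id, atoms$fragment_id, `!=`)
  if (any(d[inter] < 1e-6)) {
    stop("overlapping atoms (r < 1e-6 A) in different fragments",
      call. = FALSE
    )
  }
  q <- atoms$charge
  coul <- COULOMB_KCAL * outer(q, q) / ifelse(d > 0, d, Inf)
  heavy <- atoms$element != "H"
  ljmask <- inter & outer(heavy, heavy)
  sr6 <- (params$lj_sigma / ifelse(d > 0, d, Inf))^6
  lj <- 4 * params$lj_epsilon * (sr6^2 - sr6)
  sum(coul[inter]) / 2 + sum(lj[ljmask]) / 2
}

# Energy of one water (rows `wrows`) against all atoms of other fragments.
# Used for Metropolis deltas; same functional form as toy_energy.
water_interaction_energy <- function(xyz, q, heavy, frag, wrows, params) {
  others <- which(frag != frag[wrows[1]])
  e <- 0
  for (i in wrows) {
    dv <- sweep(xyz[others, , drop = FALSE], 2, xyz[i, ])
    r <- sqrt(rowSums(dv^2))
    if (any(r < 1e-6)) {
      return(Inf)
    }
    e <- e + COULOMB_KCAL * q[i] * sum(q[others] / r)
    if (heavy[i]) {
      hsel <- heavy[others]
      if (any(hsel)) {
        sr6 <- (params$lj_sigma / r[hsel])^6
        e <- e + 4 * params$lj_epsilon * sum(sr6^2 - sr6)
      }
    }
  }
  e
}

rotation_about <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  c <- cos(th)
  s <- sin(th)
  x <- a[1]
  y <- a[2]
  z <- a[3]
  matrix(c(
    c + x^2 * (1 - c), x * y * (1 - c) - z * s, x * z * (1 - c) + y * s,
    y * x * (1 - c) + z * s, c + y^2 * (1 - c), y * z * (1 - c) - x * s,
    z * x * (1 - c) - y * s, z * y * (1 - c) + x * s, c + z^2 * (1 - c)
  ), 3, 3, byrow = TRUE)
}

# Uniform random rotation matrix (random unit quaternion).
random_rotation <- function() {
  qv <- stats::rnorm(4)
  qv <- qv / sqrt(sum(qv^2))
  w <- qv[1]
  x <- qv[2]
  y <- qv[3]
  z <- qv[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Rotation taking +z onto the unit vector `v`.
align_z_to <- function(v) {
  v <- v / sqrt(sum(v^2))
  z <- c(0, 0, 1)
  axis <- c(
    z[2] * v[3] - z[3] * v[2],
    z[3] * v[1] - z[1] * v[3],
    z[1] * v[2] - z[2] * v[1]
  )
  s <- sqrt(sum(axis^2))
  if (s < 1e-12) {
    if (v[3] > 0) {
      return(diag(3))
    }
    return(rotation_about(c(1, 0, 0), 180))
  }
  rotation_about(axis, atan2(s, sum(z * v)) * 180 / pi)
}

# Spin a water's hydrogens about its own H-O-H bisector axis (through the
# oxygen) by `angle_rad`.
rotate_water_about_bisector <- function(wat, angle_rad) {
  o <- as.numeric(wat[1, c("x", "y", "z")])
  h <- as.matrix(wat[2:3, c("x", "y", "z")])
  axis <- colMeans(h) - o
  rot <- rotation_about(axis, angle_rad * 180 / pi)
  hr <- sweep(sweep(h, 2, o) %*% t(rot), 2, o, `+`)
  wat$x[2:3] <- hr[, 1]
  wat$y[2:3] <- hr[, 2]
  wat$z[2:3] <- hr[, 3]
  wat
}

# Place a rigid water with its H-O-H bisector (hydrogens-first direction)
# along `h_dir`, oxygen at `o_pos`.
place_water <- function(o_pos, h_dir = c(0, 0, 1), fragment_id = 1L,
                        q_o = -0.834, q_h = 0.417) {
  w <- water_template(q_o, q_h)
  rot <- align_z_to(h_dir)
  xyz <- as.matrix(w[, c("x", "y", "z")]) %*% t(rot)
  w$x <- xyz[, 1] + o_pos[1]
  w$y <- xyz[, 2] + o_pos[2]
  w$z <- xyz[, 3] + o_pos[3]
  w$fragment_id <- as.integer(fragment_id)
  w
}

#' Sample water configurations by Metropolis Monte Carlo
#'
#' Rigid-body moves of each water (local translation up to
#' `max_translation`, local rotation up to `max_rotation` about the oxygen,
#' and occasional uniform jump moves inside a hard-wall sampling sphere)
#' accepted with the Metropolis criterion at `params$temperature`. The
#' solute is held fixed. Identical seeds give bit-identical trajectories.
#'
#' Waters start adjacent to the most negative solute sites (hydrogens
#' pointing at the site), so low-temperature runs relax into the deepest
#' basin without needing rare uphill moves.
#'
#' @param solute A [conformer()], e.g. [build_toy_solute()].
#' @param params A [toy_model_params()].
#' @return An [ensemble()] of recorded frames (labels `frame_0001`, ...)
#'   with attributes `acceptance_rate` and `energies` (recorded-frame
#'   energies, kcal/mol). A run with zero accepted moves attaches a
#'   `sampling_warning` attribute instead of failing.
#' @export
sample_configurations <- function(solute, params = toy_model_params()) {
  stopifnot(inherits(solute, "conformer"))
  withr::local_seed(params$seed)
  nw <- params$n_waters
  qo <- params$water_charges[1]
  qh <- params$water_charges[2]
  sol_atoms <- solute$atoms
  centroid <- colMeans(as.matrix(sol_atoms[, c("x", "y", "z")]))
  extent <- max(sqrt(rowSums(sweep(
    as.matrix(sol_atoms[, c("x", "y", "z")]), 2, centroid
  )^2)))
  radius <- if (is.null(params$sample_radius)) extent + 6 else params$sample_radius

  # initial placement: one water per charged site, most negative first
  charged <- order(sol_atoms$charge)
  charged <- charged[sol_atoms$charge[charged] < 0]
  atoms <- sol_atoms
  for (w in seq_len(nw)) {
    site <- charged[(w - 1L) %% length(charged) + 1L]
    site_pos <- as.numeric(sol_atoms[site, c("x", "y", "z")])
    away <- site_pos - centroid
    if (sqrt(sum(away^2)) < 1e-9) away <- c(0, 0, 1)
    away <- away / sqrt(sum(away^2))
    o_pos <- site_pos + 3.0 * away + 0.4 * (w - 1L) * c(0, 1, 0)
    wat <- place_water(o_pos, h_dir = site_pos - o_pos,
      fragment_id = w, q_o = qo, q_h = qh
    )
    atoms <- dplyr::bind_rows(atoms, wat)
  }

  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  q <- atoms$charge
  heavy <- atoms$element != "H"
  frag <- atoms$fragment_id
  wrows_of <- lapply(seq_len(nw), function(w) which(frag == w))
  beta <- 1 / (R_KCAL * params$temperature)

  frames <- list()
  energies <- numeric(0)
  accepted <- 0L
  frame_i <- 0L
  for (step in seq_len(params$mc_steps)) {
    w <- if (nw == 1) 1L else sample.int(nw, 1)
    rows <- wrows_of[[w]]
    old <- xyz[rows, , drop = FALSE]
    e_old <- water_interaction_energy(xyz, q, heavy, frag, rows, params)
    if (stats::runif(1) < params$p_jump) {
      if (length(charged) >= 2 && stats::runif(1) < 0.5) {
        # basin-exchange move: point inversion through the midpoint of two
        # charged sites maps a configuration bound at one site onto the
        # mirror-equivalent one at the other (an involution, hence a
        # symmetric proposal; water is achiral, so the inverted rigid body
        # is a valid placement of the same molecule)
        ij <- sample(charged, 2)
        mid <- as.numeric(sol_atoms[ij[1], c("x", "y", "z")]) +
          as.numeric(sol_atoms[ij[2], c("x", "y", "z")])
        new <- sweep(-old, 2, mid, `+`)
        if (sum((new[1, ] - centroid)^2) > radius^2) new <- NULL # hard wall
      } else {
        # uniform reposition in the sphere, uniform orientation (symmetric)
        repeat {
          pos <- stats::runif(3, -radius, radius)
          if (sum(pos^2) <= radius^2) break
        }
        o_new <- centroid + pos
        rot <- random_rotation()
        new <- sweep(sweep(old, 2, old[1, ]) %*% t(rot), 2, o_new, `+`)
      }
    } else {
      shift <- stats::runif(3, -params$max_translation, params$max_translation)
      ang <- stats::runif(1, -params$max_rotation, params$max_rotation)
      axis <- stats::rnorm(3)
      rot <- rotation_about(axis, ang)
      o_new <- old[1, ] + shift
      new <- sweep(sweep(old, 2, old[1, ]) %*% t(rot), 2, o_new, `+`)
      if (sum((o_new - centroid)^2) > radius^2) new <- NULL # hard wall
    }
    if (!is.null(new)) {
      xyz[rows, ] <- new
      e_new <- water_interaction_energy(xyz, q, heavy, frag, rows, params)
      if (is.finite(e_new) &&
        (e_new <= e_old || stats::runif(1) < exp(-beta * (e_new - e_old)))) {
        accepted <- accepted + 1L
      } else {
        xyz[rows, ] <- old
      }
    }
    if (step > params$burn_in &&
      (step - params$burn_in) %% params$stride == 0L) {
      frame_i <- frame_i + 1L
      fr <- atoms
      fr$x <- xyz[, 1]
      fr$y <- xyz[, 2]
      fr$z <- xyz[, 3]
      conf <- conformer(fr,
        label = sprintf("frame_%04d", frame_i),
        total_charge = solute$total_charge
      )
      frames[[frame_i]] <- conf
      energies[frame_i] <- toy_energy(conf, params)
    }
  }
  ens <- ensemble(frames, temperature = params$temperature)
  attr(ens, "acceptance_rate") <- accepted / params$mc_steps
  attr(ens, "energies") <- energies
  if (accepted == 0L) {
    attr(ens, "sampling_warning") <- "no Monte Carlo moves were accepted"
  }
  ens
}

#' Ground-truth detachment-energy model for synthetic ensembles
#'
#' Encodes the physics the pipeline must recover: each water raises the
#' vertical detachment energy of the dianion by a site-dependent increment
#' (solvation stabilises the remaining charge), and geometry relaxation of
#' the detached state lowers the adiabatic value by a fixed offset.
#'
#' @param vde0 Bare-dianion VDE (eV).
#' @param site_increments Named numeric, eV per water occupying each
#'   hydration site; names must be hydration-site labels.
#' @param noise_sd Gaussian noise added to each conformer VDE (eV).
#' @param relaxation_offset ADE = VDE - offset (eV, >= 0).
#' @param seed Seed for the noise stream (independent of the sampler's).
#' @return List of class `observable_model`.
#' @export
observable_model <- function(vde0 = 1.30,
                             site_increments = c(
                               AMINE_N10 = 0.50, PHOSPHATE = 0.25,
                               PURINE_RING = 0.15, RIBOSE_OH = 0.10,
                               WATER_WATER = 0.10
                             ),
                             noise_sd = 0,
                             relaxation_offset = 0.35,
                             seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  bad <- setdiff(names(site_increments), setdiff(HYDRATION_SITES, "NONE"))
  if (length(bad) > 0) {
    stop("unknown site tag(s) in site_increments: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      vde0 = vde0, site_increments = site_increments,
      noise_sd = noise_sd, relaxation_offset = relaxation_offset,
      seed = as.integer(seed)
    ),
    class = "observable_model"
  )
}

#' Assign synthetic detachment energies to representative conformers
#'
#' `VDE = vde0 + sum over waters of site_increments[primary site] + noise`,
#' `ADE = VDE - relaxation_offset`. The noise-free value and the per-site
#' water counts are kept in the output as ground truth for recovery tests.
#'
#' @param representatives List of [conformer()] objects.
#' @param model An [observable_model()].
#' @param d_max,angle_min Hydrogen-bond criteria for the site assignment.
#' @return Tibble with `label`, `n_waters`, `vde`, `ade`, `vde_true` and one
#'   `n_<site>` count column per hydration site.
#' @export
assign_observables <- function(representatives, model = observable_model(),
                               d_max = 3.5, angle_min = 140) {
  withr::local_seed(model$seed)
  purrr::map_dfr(representatives, function(conf) {
    st <- water_site_table(conf, d_max = d_max, angle_min = angle_min)
    inc <- 0
    counts <- stats::setNames(
      integer(length(HYDRATION_SITES)), HYDRATION_SITES
    )
    if (nrow(st) > 0) {
      for (s in st$primary_site) {
        counts[s] <- counts[s] + 1L
        if (s != "NONE") inc <- inc + model$site_increments[[s]]
      }
    }
    vde_true <- model$vde0 + inc
    vde <- vde_true + if (model$noise_sd > 0) {
      stats::rnorm(1, 0, model$noise_sd)
    } else {
      0
    }
    out <- tibble::tibble(
      label = conf$label, n_waters = conf$n_waters,
      vde = vde, ade = vde - model$relaxation_offset,
      vde_true = vde_true
    )
    for (s in names(counts)) out[[paste0("n_", tolower(s))]] <- counts[[s]]
    out
  })
}
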