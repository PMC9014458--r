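# Shared fixtures and independent oracles, all built in code.

R_KCAL <- 0.0019872

ensemble_labels_of <- function(ens) {
  vapply(ens, function(c) c$label, character(1))
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
    byrow = TRUE
  )
}

euler_zyz <- function(a, b, c) {
  ry <- function(th) {
    matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3,
      byrow = TRUE
    )
  }
  rz <- function(th) {
    matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
      byrow = TRUE
    )
  }
  rz(a) %*% ry(b) %*% rz(c)
}

# Apply one global rigid motion (rotation in degrees about `axis` through the
# origin, then translation) to every atom of a conformer.
rigid_motion <- function(conf, angle = 37, axis = c(0, 0, 1),
                         shift = c(1, 2, 3)) {
  rot <- microsolv:::rotation_about(axis, angle)
  xyz <- as.matrix(conf$atoms[, c("x", "y", "z")]) %*% t(rot)
  conf$atoms$x <- xyz[, 1] + shift[1]
  conf$atoms$y <- xyz[, 2] + shift[2]
  conf$atoms$z <- xyz[, 3] + shift[3]
  conf
}

# A water placed with oxygen at `o_pos`, hydrogens-bisector along `h_dir`.
water_at <- function(o_pos, h_dir = c(0, 0, 1), fragment_id = 1L) {
  microsolv:::place_water(o_pos, h_dir = h_dir, fragment_id = fragment_id)
}

# A water donating a textbook-linear hydrogen bond: oxygen at `o_pos`, one
# O-H bond exactly on the O -> target axis (the bisector is tilted off that
# axis by half the H-O-H angle).
water_donating_to <- function(target, o_pos, fragment_id = 1L) {
  half_deg <- 104.52 / 2
  u <- target - o_pos
  u <- u / sqrt(sum(u^2))
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  a <- a - sum(a * u) * u
  a <- a / sqrt(sum(a^2))
  bis <- as.numeric(microsolv:::rotation_about(a, half_deg) %*% u)
  wat <- water_at(o_pos, h_dir = bis, fragment_id = fragment_id)
  # spin about the bisector until the first O-H bond lies on the O->target axis
  d1 <- as.numeric(wat[2, c("x", "y", "z")]) - o_pos
  perp <- function(v) v - sum(v * bis) * bis
  p1 <- perp(d1)
  pu <- perp(u)
  crossp <- c(
    p1[2] * pu[3] - p1[3] * pu[2],
    p1[3] * pu[1] - p1[1] * pu[3],
    p1[1] * pu[2] - p1[2] * pu[1]
  )
  twist <- atan2(sum(crossp * bis), sum(p1 * pu))
  microsolv:::rotate_water_about_bisector(wat, twist)
}

# Toy solute whose two charged sites are exactly equivalent under point
# inversion through their midpoint: the two hydration basins have identical
# free energies, so the stationary basin occupancy is exactly 1/2 each.
symmetric_sites <- function(separation = 8) {
  tibble::tibble(
    element = c("N", "C", "C", "O"),
    x = c(0, separation / 2, separation / 2, separation),
    y = c(0, 1.5, -1.5, 0),
    z = 0,
    charge = c(-1, 0, 0, -1),
    site_tag = c("AMINE_N10", "OTHER", "OTHER", "PHOSPHATE_O")
  )
}

# Asymmetric variant: the phosphate-like site binds much more weakly, so the
# amine basin is the unique deep well.
asymmetric_sites <- function(separation = 8, weak_charge = -0.4) {
  s <- symmetric_sites(separation)
  s$charge[s$site_tag == "PHOSPHATE_O"] <- weak_charge
  s
}

# Which basin holds the water oxygen of a 1-water frame (TRUE = site A at
# the origin).
in_basin_a <- function(conf, a = c(0, 0, 0), b = c(8, 0, 0)) {
  o <- as.numeric(
    conf$atoms[conf$atoms$element == "O" & conf$atoms$fragment_id == 1L,
      c("x", "y", "z")
    ]
  )
  sum((o - a)^2) < sum((o - b)^2)
}

# Independent Coulomb + heavy-atom Lennard-Jones energy, written directly
# from the pair formula (oracle for toy_energy and for the grid search).
pair_energy_oracle <- function(atoms, sigma, eps) {
  n <- nrow(atoms)
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (atoms$fragment_id[i] == atoms$fragment_id[j]) next
      r <- sqrt((atoms$x[i] - atoms$x[j])^2 + (atoms$y[i] - atoms$y[j])^2 +
        (atoms$z[i] - atoms$z[j])^2)
      e <- e + 332.0637 * atoms$charge[i] * atoms$charge[j] / r
      if (atoms$element[i] != "H" && atoms$element[j] != "H") {
        sr6 <- (sigma / r)^6
        e <- e + 4 * eps * (sr6^2 - sr6)
      }
    }
  }
  e
}

# Brute-force reimplementation of neighbour-count clustering: recomputes all
# neighbour counts from scratch every round.
daura_bruteforce <- function(mat, cutoff) {
  n <- nrow(mat)
  remaining <- seq_len(n)
  cluster_of <- integer(n)
  reps <- integer(0)
  k <- 0L
  while (length(remaining) > 0) {
    counts <- sapply(remaining, function(i) {
      sum(mat[i, remaining] <= cutoff)
    })
    founder <- remaining[which.max(counts)]
    members <- remaining[mat[founder, remaining] <= cutoff]
    k <- k + 1L
    cluster_of[members] <- k
    reps[k] <- founder
    remaining <- setdiff(remaining, members)
  }
  list(cluster_of = cluster_of, representatives = reps)
}

# Exhaustive-permutation RMSD oracle: minimum over all water relabellings of
# the identity-mode RMSD.
perms_of <- function(n) {
  if (n == 1) {
    return(list(1L))
  }
  out <- list()
  for (p in perms_of(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

permute_waters <- function(conf, perm) {
  atoms <- conf$atoms
  sol <- atoms[atoms$fragment_id == 0L, ]
  wats <- lapply(seq_along(perm), function(i) {
    w <- atoms[atoms$fragment_id == perm[i], ]
    w$fragment_id <- i
    w
  })
  conformer(dplyr::bind_rows(c(list(sol), wats)),
    label = conf$label, total_charge = conf$total_charge
  )
}

rmsd_exhaustive <- function(ref, mob) {
  min(vapply(perms_of(ref$n_waters), function(p) {
    microsolv:::pair_rmsd(ref, permute_waters(mob, p),
      permutation_mode = "identity"
    )
  }, numeric(1)))
}

# A random microsolvated frame around a fixed solute (no MC; used where only
# geometry, not Boltzmann statistics, matters).
random_frame <- function(solute, n_waters, label = "rand") {
  atoms <- solute$atoms
  for (w in seq_len(n_waters)) {
    pos <- runif(3, -6, 6) + c(4, 0, 0)
    dir <- rnorm(3)
    atoms <- dplyr::bind_rows(atoms, water_at(pos, dir, fragment_id = w))
  }
  conformer(atoms, label = label, total_charge = solute$total_charge)
}

# Hierarchically refined rotation-grid search: the independent oracle for
# the Kabsch minimal RMSD.
grid_min_rmsd <- function(p, q, levels = 9, n_per_axis = 13) {
  p0 <- sweep(p, 2, colMeans(p))
  q0 <- sweep(q, 2, colMeans(q))
  rmsd_of <- function(a, b, c) {
    r <- euler_zyz(a, b, c)
    sqrt(mean(rowSums((q0 %*% t(r) - p0)^2)))
  }
  center <- c(0, 0, 0)
  half <- pi
  best <- Inf
  for (lev in seq_len(levels)) {
    gr <- seq(-half, half, length.out = n_per_axis)
    vals <- expand.grid(a = center[1] + gr, b = center[2] + gr, c = center[3] + gr)
    r <- mapply(rmsd_of, vals$a, vals$b, vals$c)
    i <- which.min(r)
    if (r[i] < best) {
      best <- r[i]
      center <- as.numeric(vals[i, ])
    }
    half <- half * 3.2 / (n_per_axis - 1) # keep > 3 grid spacings in view
  }
  best
}
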