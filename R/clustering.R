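#' Kabsch least-squares superposition
#'
#' Computes the optimal (proper) rotation and translation mapping the
#' selected atoms of `mobile` onto those of `reference`, and the resulting
#' RMSD over the selection.
#'
#' @param reference,mobile [conformer()] objects.
#' @param selection Predicate taking the atom tibble and returning a logical
#'   vector; defaults to heavy atoms of the solute. Selections must pick the
#'   same number (>= 3) of non-collinear atoms in both conformers.
#' @return List with `rotation` (3x3, det +1), `translation` (length-3) and
#'   `rmsd` (Angstrom). Mobile coordinates map as `x %*% t(R) + t`.
#' @export
kabsch_superpose <- function(reference, mobile,
                             selection = select_solute_heavy) {
  p <- coords_matrix(reference, which(selection(reference$atoms)))
  q <- coords_matrix(mobile, which(selection(mobile$atoms)))
  fit <- kabsch_fit(p, q)
  fit
}

# Core Kabsch on two coordinate matrices (reference p, mobile q).
kabsch_fit <- function(p, q) {
  if (nrow(p) != nrow(q)) {
    stop("selections have different atom counts", call. = FALSE)
  }
  if (nrow(p) < 3) stop("need at least 3 selected atoms", call. = FALSE)
  cp <- colMeans(p)
  cq <- colMeans(q)
  p0 <- sweep(p, 2, cp)
  q0 <- sweep(q, 2, cq)
  dsv <- svd(p0)$d # planar selections are fine; only rank <= 1 is degenerate
  if (dsv[2] < 1e-8 * max(dsv[1], 1e-12)) {
    stop("collinear (rank-deficient) selection", call. = FALSE)
  }
  h <- crossprod(q0, p0) # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  s <- diag(c(1, 1, d))
  rot <- sv$v %*% s %*% t(sv$u)
  qr_ <- q0 %*% t(rot)
  rmsd <- sqrt(mean(rowSums((qr_ - p0)^2)))
  list(
    rotation = rot,
    translation = as.numeric(cp - cq %*% t(rot)),
    rmsd = rmsd
  )
}

apply_transform <- function(m, fit) {
  sweep(m %*% t(fit$rotation), 2, fit$translation, `+`)
}

#' Atom selection helpers
#'
#' `select_solute_heavy()` picks non-hydrogen solute atoms (the superposition
#' set); `select_heavy()` picks all non-hydrogen atoms (the default RMSD
#' set, so each water contributes its oxygen).
#'
#' @param atoms Conformer atom tibble.
#' @return Logical vector over atoms.
#' @export
select_solute_heavy <- function(atoms) {
  atoms$element != "H" & atoms$fragment_id == 0L
}

#' @rdname select_solute_heavy
#' @export
select_heavy <- function(atoms) atoms$element != "H"

# Hungarian algorithm (O(n^3), potentials + augmenting paths) for the
# minimum-cost square assignment problem. Returns for each row the assigned
# column. Used to match indistinguishable water molecules between frames.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 1) {
    return(1L)
  }
  # Potentials u, v; p[j+1] is the row assigned to column j (0 = none).
  # Indices are shifted by one so the virtual row/column 0 lives at slot 1.
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1L]) next
        cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
        if (cur < minv[j + 1L]) {
          minv[j + 1L] <- cur
          way[j + 1L] <- j0
        }
        if (minv[j + 1L] < delta) {
          delta <- minv[j + 1L]
          j1 <- j
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) {
    if (p[j + 1L] > 0L) assignment[p[j + 1L]] <- j
  }
  assignment
}

# Precompute the coordinate blocks pair comparisons need: the superposition
# set (solute heavy atoms), the RMSD evaluation set, water oxygens, and for
# each water its row indices within the evaluation set.
precompute_rmsd_frame <- function(conf, selection) {
  atoms <- conf$atoms
  sel_idx <- which(selection(atoms))
  nw <- conf$n_waters
  wat_rows <- lapply(seq_len(nw), function(w) {
    which(atoms$fragment_id[sel_idx] == w)
  })
  fit <- coords_matrix(conf, which(select_solute_heavy(atoms)))
  if (nrow(fit) < 3) {
    stop("need at least 3 solute heavy atoms for superposition", call. = FALSE)
  }
  dsv <- svd(sweep(fit, 2, colMeans(fit)))$d
  if (dsv[2] < 1e-8 * max(dsv[1], 1e-12)) {
    stop("collinear (rank-deficient) superposition selection", call. = FALSE)
  }
  list(
    fit = fit,
    fit_center = colMeans(fit),
    fit0 = sweep(fit, 2, colMeans(fit)),
    sel = coords_matrix(conf, sel_idx),
    wat_o = coords_matrix(
      conf, which(atoms$element == "O" & atoms$fragment_id >= 1L)
    ),
    wat_rows = wat_rows,
    n_waters = nw
  )
}

# Pair RMSD on precomputed frames. Assumes frames share atom ordering (the
# ensemble invariant).
pair_rmsd_pre <- function(ref, mob, permutation_mode) {
  # 3x3 SVD only; rank/size checks were done per frame at precompute time
  h <- crossprod(mob$fit0, ref$fit0)
  sv <- svd(h)
  rot <- sv$v %*% diag(c(1, 1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$u)
  fit <- list(
    rotation = rot,
    translation = as.numeric(ref$fit_center - mob$fit_center %*% t(rot))
  )
  b <- apply_transform(mob$sel, fit)
  if (permutation_mode == "water_optimal" && ref$n_waters > 1) {
    mo <- apply_transform(mob$wat_o, fit)
    nw <- ref$n_waters
    cost <- matrix(0, nw, nw)
    for (i in seq_len(nw)) {
      cost[i, ] <- colSums((t(mo) - ref$wat_o[i, ])^2)
    }
    asg <- solve_assignment(cost) # reference water i <- mobile water asg[i]
    b2 <- b
    for (i in seq_len(nw)) {
      b2[ref$wat_rows[[i]], ] <- b[mob$wat_rows[[asg[i]]], , drop = FALSE]
    }
    b <- b2
  }
  sqrt(mean(rowSums((ref$sel - b)^2)))
}

# RMSD between two conformers: fit on solute heavy atoms, optionally relabel
# waters by minimum-cost O-O assignment, then RMSD over `selection` atoms.
pair_rmsd <- function(reference, mobile,
                      selection = select_heavy,
                      permutation_mode = c("water_optimal", "identity")) {
  permutation_mode <- match.arg(permutation_mode)
  pair_rmsd_pre(
    precompute_rmsd_frame(reference, selection),
    precompute_rmsd_frame(mobile, selection),
    permutation_mode
  )
}

#' Pairwise minimal RMSD matrix for an ensemble
#'
#' Frames are superposed pairwise on solute heavy atoms (waters contribute to
#' the RMSD but not to the fit). In `water_optimal` mode (the default),
#' chemically indistinguishable water molecules are matched between the two
#' frames by minimum-cost assignment on water-oxygen distances before the
#' RMSD is evaluated, so relabelling identical solvent molecules costs
#' nothing.
#'
#' @param ens An [ensemble()].
#' @param selection Atom predicate for the RMSD evaluation set; default all
#'   heavy atoms.
#' @param permutation_mode `"water_optimal"` (default) or `"identity"`.
#' @return Object of class `rmsd_matrix`: a symmetric numeric matrix
#'   (Angstrom) with frame labels as dimnames and attributes `selection` and
#'   `permutation_mode`.
#' @export
rmsd_matrix <- function(ens, selection = select_heavy,
                        permutation_mode = c("water_optimal", "identity")) {
  permutation_mode <- match.arg(permutation_mode)
  n <- length(ens)
  m <- matrix(0, n, n)
  labels <- ensemble_labels(ens)
  pre <- lapply(unclass(ens), precompute_rmsd_frame, selection = selection)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        val <- tryCatch(
          pair_rmsd_pre(pre[[i]], pre[[j]], permutation_mode),
          error = function(e) {
            stop("RMSD failed for frame pair (", labels[i], ", ", labels[j],
              "): ", conditionMessage(e),
              call. = FALSE
            )
          }
        )
        m[i, j] <- m[j, i] <- val
      }
    }
  }
  dimnames(m) <- list(labels, labels)
  structure(m,
    selection = deparse(substitute(selection)),
    permutation_mode = permutation_mode,
    class = c("rmsd_matrix", "matrix", "array")
  )
}

#' Daura neighbour-count clustering
#'
#' The classic GROMOS conformer-clustering scheme: iteratively, the frame
#' with the most neighbours within `cutoff` founds a cluster containing
#' itself and those neighbours; cluster members are removed and the step
#' repeats until no frames remain. The founder frame is the cluster
#' representative. Ties in neighbour count are broken by the lowest original
#' frame index.
#'
#' @param mat An [rmsd_matrix()] (or plain symmetric matrix, Angstrom).
#' @param cutoff RMSD cutoff in Angstrom (> 0).
#' @return Object of class `cluster_assignment`: a list with `cluster_of`
#'   (integer vector, frame -> cluster), `representatives` (frame index per
#'   cluster), `cluster_sizes` (non-increasing in discovery order except for
#'   equal-size ties), `cutoff` and `frame_labels`.
#' @export
cluster_daura <- function(mat, cutoff = 1.0) {
  if (length(mat) == 0 || nrow(mat) == 0) {
    stop("empty RMSD matrix", call. = FALSE)
  }
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  n <- nrow(mat)
  labels <- rownames(mat)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  remaining <- rep(TRUE, n)
  cluster_of <- integer(n)
  reps <- integer(0)
  sizes <- integer(0)
  k <- 0L
  while (any(remaining)) {
    idx <- which(remaining)
    counts <- vapply(idx, function(i) {
      sum(mat[i, idx] <= cutoff) # includes self
    }, integer(1))
    founder <- idx[which.max(counts)] # which.max -> lowest index on ties
    members <- idx[mat[founder, idx] <= cutoff]
    k <- k + 1L
    cluster_of[members] <- k
    reps[k] <- founder
    sizes[k] <- length(members)
    remaining[members] <- FALSE
  }
  structure(
    list(
      cluster_of = cluster_of,
      representatives = reps,
      cluster_sizes = sizes,
      cutoff = cutoff,
      frame_labels = labels
    ),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(
    "<cluster_assignment> ", length(x$cluster_sizes), " cluster(s) over ",
    length(x$cluster_of), " frames at cutoff ", x$cutoff, " A; sizes: ",
    paste(x$cluster_sizes, collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a cluster assignment
#'
#' @param x A `cluster_assignment`.
#' @param ... Unused.
#' @return Tibble with `frame_label`, `cluster_id`, `is_representative`.
#' @method tidy cluster_assignment
#' @export
tidy.cluster_assignment <- function(x, ...) {
  tibble::tibble(
    frame_label = x$frame_labels,
    cluster_id = x$cluster_of,
    is_representative = seq_along(x$cluster_of) %in% x$representatives
  )
}

#' Extract representative conformers, largest cluster first
#'
#' Returns the founder frame of each cluster, ordered by descending cluster
#' size (ties broken by lower original frame index). Each representative's
#' label is suffixed with `|size=<cluster size>` and the conformer gains
#' `cluster_id` and `cluster_size` attributes.
#'
#' @param assignment A [cluster_daura()] result.
#' @param ens The [ensemble()] it was computed from.
#' @return List of [conformer()] objects.
#' @export
select_representatives <- function(assignment, ens) {
  if (max(assignment$representatives) > length(ens)) {
    stop("assignment refers to frames not present in the ensemble",
      call. = FALSE
    )
  }
  ord <- order(-assignment$cluster_sizes, assignment$representatives)
  purrr::map(ord, function(k) {
    conf <- ens[[assignment$representatives[k]]]
    conf$label <- sprintf("%s|size=%d", conf$label, assignment$cluster_sizes[k])
    attr(conf, "cluster_id") <- k
    attr(conf, "cluster_size") <- assignment$cluster_sizes[k]
    conf
  })
}
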