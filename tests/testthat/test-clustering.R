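test_that("Kabsch superposition recovers rigid motions and matches a rotation-grid oracle", {
  sol <- build_toy_solute()
  self <- kabsch_superpose(sol, sol)
  expect_lt(self$rmsd, 1e-10)
  expect_equal(det(self$rotation), 1, tolerance = 1e-9)

  moved <- rigid_motion(sol, angle = 37, axis = c(0, 0, 1), shift = c(1, 2, 3))
  fit <- kabsch_superpose(sol, moved)
  expect_lt(fit$rmsd, 1e-9)

  # two hand-built non-congruent 4-atom sets vs hierarchical rotation grid
  p <- matrix(c(0, 0, 0, 2, 0, 0, 0, 1.5, 0, 0.5, 0.5, 1.2), 4, 3, byrow = TRUE)
  q <- matrix(c(0.1, 0, 0, 1.8, 0.3, 0, -0.2, 1.4, 0.2, 0.7, 0.4, 1.0),
    4, 3,
    byrow = TRUE
  )
  fit2 <- microsolv:::kabsch_fit(p, q)
  expect_equal(fit2$rmsd, grid_min_rmsd(p, q), tolerance = 1e-8)
})

test_that("degenerate superposition selections are rejected", {
  line <- tibble::tibble(
    element = "C", x = c(0, 1, 2, 3), y = 0, z = 0, fragment_id = 0L
  )
  lc <- conformer(line, "line")
  expect_error(kabsch_superpose(lc, lc), "collinear")
  two <- conformer(line[1:2, ], "two")
  expect_error(kabsch_superpose(two, two), "at least 3")
})

test_that("RMSD matrix is zero for duplicated frames and invariant under one global rigid motion", {
  sol <- build_toy_solute()
  set.seed(1)
  confs <- lapply(1:4, function(i) random_frame(sol, 2, paste0("f", i)))
  dup <- ensemble(list(
    confs[[1]],
    rigid_motion(confs[[1]], 10, c(1, 1, 0), c(0.3, 0, 0)) |>
      (\(x) {
        x$label <- "f1b"
        x
      })(),
    confs[[1]] |> (\(x) {
      x$label <- "f1c"
      x
    })()
  ))
  m <- rmsd_matrix(dup)
  expect_true(all(m < 1e-9))

  ens <- ensemble(confs)
  m0 <- rmsd_matrix(ens)
  moved <- ensemble(lapply(confs, rigid_motion, angle = 63, axis = c(1, 2, 3)))
  m1 <- rmsd_matrix(moved)
  expect_equal(unclass(m0), unclass(m1),
    tolerance = 1e-8, ignore_attr = TRUE
  )
  expect_true(isSymmetric(unclass(m0)))
  expect_true(all(diag(m0) == 0))
})

test_that("water-optimal mode zeroes label swaps and equals the exhaustive permutation minimum", {
  sol <- build_toy_solute()
  set.seed(2)
  base <- random_frame(sol, 3, "base")
  swapped <- permute_waters(base, c(2L, 1L, 3L))
  swapped$label <- "swapped"
  ens <- ensemble(list(base, swapped))
  m_id <- rmsd_matrix(ens, permutation_mode = "identity")
  m_wo <- rmsd_matrix(ens, permutation_mode = "water_optimal")
  expect_gt(m_id[1, 2], 0.1)
  expect_lt(m_wo[1, 2], 1e-9)

  # exhaustive oracle over <= 4 waters, 50 random pairs
  for (k in 1:50) {
    nw <- sample(2:4, 1)
    a <- random_frame(sol, nw, "a")
    b <- random_frame(sol, nw, "b")
    wo <- microsolv:::pair_rmsd(a, b, permutation_mode = "water_optimal")
    id <- microsolv:::pair_rmsd(a, b, permutation_mode = "identity")
    expect_lte(wo, id + 1e-12)
    expect_equal(wo, rmsd_exhaustive(a, b), tolerance = 1e-10)
  }
})

test_that("neighbour-count clustering reproduces a hand-traced partition", {
  # two tight triples (0.5 A internal) bridged by one 0.9 A pair (3-4);
  # everything else 2.0 A. Manual trace at cutoff 1.0: frame 3 ties frame 4
  # with 4 neighbours, founds {1,2,3,4}; frame 5 then founds {5,6}.
  m <- matrix(2, 6, 6)
  m[1:3, 1:3] <- 0.5
  m[4:6, 4:6] <- 0.5
  m[3, 4] <- m[4, 3] <- 0.9
  diag(m) <- 0
  asg <- cluster_daura(m, cutoff = 1.0)
  expect_identical(asg$cluster_of, c(1L, 1L, 1L, 1L, 2L, 2L))
  expect_identical(asg$representatives, c(3L, 5L))
  expect_identical(asg$cluster_sizes, c(4L, 2L))
})

test_that("clustering edge cases: one big cluster, all singletons, empty input", {
  m <- matrix(0.2, 5, 5)
  diag(m) <- 0
  one <- cluster_daura(m, 1.0)
  expect_identical(one$cluster_sizes, 5L)

  m2 <- matrix(3, 5, 5)
  diag(m2) <- 0
  all_single <- cluster_daura(m2, 1.0)
  expect_length(all_single$cluster_sizes, 5)
  expect_true(all(all_single$cluster_sizes == 1L))

  expect_error(cluster_daura(matrix(numeric(0), 0, 0), 1.0), "empty")
  expect_error(cluster_daura(m, cutoff = 0), "> 0")
})

test_that("clustering equals a brute-force reimplementation and always yields a partition", {
  set.seed(3)
  for (k in 1:40) {
    n <- sample(2:8, 1)
    d <- matrix(runif(n * n, 0, 2), n, n)
    d <- (d + t(d)) / 2
    diag(d) <- 0
    cutoff <- runif(1, 0.3, 1.5)
    got <- cluster_daura(d, cutoff)
    ref <- daura_bruteforce(d, cutoff)
    expect_identical(got$cluster_of, ref$cluster_of)
    expect_identical(got$representatives, ref$representatives)
    # partition: every frame in exactly one cluster, representative inside
    expect_true(all(got$cluster_of >= 1L))
    expect_equal(sum(got$cluster_sizes), n)
    for (c in seq_along(got$representatives)) {
      expect_identical(got$cluster_of[got$representatives[c]], c)
    }
  }
})

test_that("representatives come out largest-cluster-first with index tie-breaks", {
  sol <- build_toy_solute()
  set.seed(4)
  confs <- lapply(1:6, function(i) random_frame(sol, 1, paste0("f", i)))
  ens <- ensemble(confs)
  m <- matrix(2, 6, 6)
  m[1:3, 1:3] <- 0.5 # custom matrix stands in for geometry
  m[4:6, 4:6] <- 0.5
  diag(m) <- 0
  dimnames(m) <- list(ensemble_labels_of(ens), ensemble_labels_of(ens))
  asg <- cluster_daura(m, 1.0)
  reps <- select_representatives(asg, ens)
  expect_length(reps, 2)
  # equal sizes (3, 3): lower original frame index first
  expect_match(reps[[1]]$label, "^f1\\|size=3$")
  expect_match(reps[[2]]$label, "^f4\\|size=3$")

  single <- cluster_daura(matrix(0, 1, 1), 1.0)
  expect_length(select_representatives(single, ens[1]), 1)

  bad <- asg
  bad$representatives <- c(3L, 99L)
  expect_error(select_representatives(bad, ens), "not present")
})
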