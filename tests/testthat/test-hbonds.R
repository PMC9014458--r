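# geometry helpers: a donor water with one O-H bond pointing exactly at +x
half_hoh <- 104.52 / 2 * pi / 180
donor_water_along_x <- function(o_pos = c(0, 0, 0), fragment_id = 1L) {
  water_at(o_pos, h_dir = c(cos(half_hoh), 0, sin(half_hoh)), fragment_id)
}

test_that("hydrogen bonds obey the distance and angle criteria on constructed dimers", {
  # donor O at origin, O-H along +x, acceptor water O at 2.8 A on +x:
  # d(D..A) = 2.8, angle(D-H..A) = 180 -> exactly one bond
  dimer <- conformer(
    dplyr::bind_rows(
      donor_water_along_x(fragment_id = 1L),
      water_at(c(2.8, 0, 0), h_dir = c(1, 0, 0), fragment_id = 2L)
    ),
    label = "dimer"
  )
  hb <- detect_hbonds(dimer)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$d_da, 2.8, tolerance = 1e-9)
  expect_equal(hb$angle_dha, 180, tolerance = 1e-6)
  expect_identical(hb$acceptor_site, "OTHER")

  # same dimer at 6.0 A separation: beyond the 3.5 A cutoff
  far <- conformer(
    dplyr::bind_rows(
      donor_water_along_x(fragment_id = 1L),
      water_at(c(6, 0, 0), h_dir = c(1, 0, 0), fragment_id = 2L)
    ),
    label = "far"
  )
  expect_equal(nrow(detect_hbonds(far)), 0)

  # acceptor placed perpendicular to the O-H bond at the hydrogen, out of
  # the water plane: the D-H..A angle is exactly 90 degrees at d(D..A) = 2.8
  h1 <- 0.9572 * c(1, 0, 0) # the O-H bond donor_water_along_x puts on +x
  perp_dir <- c(0, 1, 0)
  a_pos <- h1 + sqrt(2.8^2 - 0.9572^2) * perp_dir
  bent <- conformer(
    dplyr::bind_rows(
      donor_water_along_x(fragment_id = 1L),
      water_at(a_pos, h_dir = perp_dir, fragment_id = 2L)
    ),
    label = "bent"
  )
  hb_bent <- detect_hbonds(bent)
  expect_false(any(hb_bent$donor_fragment == 1)) # the 90-degree geometry fails
  expect_false(any(abs(hb_bent$angle_dha - 90) < 1))
})

test_that("detection is rigid-motion invariant and monotone in the criteria", {
  sol <- build_toy_solute()
  set.seed(20)
  for (k in 1:10) {
    conf <- random_frame(sol, 2)
    hb <- detect_hbonds(conf)
    moved <- rigid_motion(conf, angle = runif(1, 0, 180), axis = rnorm(3), shift = rnorm(3))
    hb2 <- detect_hbonds(moved)
    expect_equal(nrow(hb), nrow(hb2))
    if (nrow(hb) > 0) {
      expect_equal(hb$d_da, hb2$d_da, tolerance = 1e-9)
      expect_equal(hb$angle_dha, hb2$angle_dha, tolerance = 1e-6)
    }
    # tighter criteria can only remove bonds
    expect_lte(nrow(detect_hbonds(conf, d_max = 3.0)), nrow(hb))
    expect_lte(nrow(detect_hbonds(conf, angle_min = 160)), nrow(hb))
  }
})

test_that("water sites map to the tagged partner atom with the documented priority", {
  # one water donating one H to an amine-like N and the other to a carbonyl
  # O tagged as part of the purine ring (the three-water bridge motif)
  # the water bisector points +z, so its O-H bonds run along
  # (+-sin(half), 0, cos(half)); acceptors sit 2.8 A out on those axes
  n10 <- 2.8 * c(sin(half_hoh), 0, cos(half_hoh))
  o11 <- 2.8 * c(-sin(half_hoh), 0, cos(half_hoh))
  solute <- tibble::tibble(
    element = c("N", "O"),
    x = c(n10[1], o11[1]), y = 0, z = c(n10[3], o11[3]),
    fragment_id = 0L, site_tag = c("AMINE_N10", "PURINE_O11")
  )
  bridge <- conformer(
    dplyr::bind_rows(solute, water_at(c(0, 0, 0), h_dir = c(0, 0, 1))),
    label = "bridge", total_charge = -2L
  )
  cls <- classify_water_site(bridge, 1)
  expect_setequal(cls$sites, c("AMINE_N10", "PURINE_RING"))
  expect_identical(cls$primary, "AMINE_N10")

  # isolated water far from everything
  lone <- conformer(
    dplyr::bind_rows(solute, water_at(c(0, 0, -10))),
    label = "lone", total_charge = -2L
  )
  expect_identical(classify_water_site(lone, 1)$primary, "NONE")
  expect_error(classify_water_site(lone, 5), "unknown water_id")

  # single donation to the amine nitrogen only: the water O sits 2.8 A from
  # the N with one O-H bond on the O..N axis
  amine_only <- conformer(
    dplyr::bind_rows(solute[1, ], donor_water_along_x(o_pos = n10 - c(2.8, 0, 0))),
    label = "amine", total_charge = -2L
  )
  expect_identical(classify_water_site(amine_only, 1)$primary, "AMINE_N10")
})

test_that("site occupancies are population-weighted water counts", {
  solute <- tibble::tibble(
    element = c("N", "C", "O"), x = c(0, 4, 8), y = c(0, 1, 0), z = 0,
    fragment_id = 0L, site_tag = c("AMINE_N10", "OTHER", "PHOSPHATE_O")
  )
  on_amine <- conformer(
    dplyr::bind_rows(solute, donor_water_along_x(o_pos = c(-2.8, 0, 0))),
    label = "a", total_charge = -2L
  )
  on_phos <- conformer(
    dplyr::bind_rows(solute, water_donating_to(c(8, 0, 0), o_pos = c(8, 0, 2.8))),
    label = "b", total_charge = -2L
  )
  # single conformer, x_m = 1
  occ1 <- site_occupancy(
    list(on_amine),
    tibble::tibble(label = "a", x_m = 1)
  )
  expect_equal(occ1$weighted_count[occ1$site == "AMINE_N10"], 1.0)

  # hand-weighted two-conformer mixture
  occ <- site_occupancy(
    list(on_amine, on_phos),
    tibble::tibble(label = c("a", "b"), x_m = c(0.7, 0.3))
  )
  expect_equal(occ$weighted_count[occ$site == "AMINE_N10"], 0.7)
  expect_equal(occ$weighted_count[occ$site == "PHOSPHATE"], 0.3)
  # total weighted count = sum over conformers of x_m * n_waters
  expect_equal(sum(occ$weighted_count), 0.7 * 1 + 0.3 * 1, tolerance = 1e-9)

  expect_error(
    site_occupancy(list(on_amine), tibble::tibble(label = "zz", x_m = 1)),
    "missing"
  )
})
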