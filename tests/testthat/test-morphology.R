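test_that("fixture geometry follows the cylinder formulas and shell fraction", {
  m <- make_fixture("single", radius_um = 10, length_um = 20)
  g <- m$geometry
  expect_equal(nrow(g), 1L)
  expect_equal(g$area_cm2, 2 * pi * 10 * 20 * 1e-8)
  expect_equal(g$vol_o_cm3, 0.15 * g$vol_i_cm3)
  expect_equal(g$dist_um, 0)

  # membrane area of a multi-section cable equals the sum of 2*pi*r*L
  mb <- make_fixture("ball_and_stick", nseg = 3L, stick_length_um = 300,
                     stick_radius_um = 1.2)
  by_hand <- 2 * pi * 10 * 20 * 1e-8 + 3 * (2 * pi * 1.2 * 100 * 1e-8)
  expect_equal(sum(mb$geometry$area_cm2), by_hand, tolerance = 1e-12)
})

test_that("ball-and-stick path distances use segment midpoints", {
  m <- make_fixture("ball_and_stick", stick_length_um = 400, nseg = 8L)
  d <- m$geometry$dist_um
  expect_equal(d[2], 25)
  expect_gte(d[9], 375)
  expect_lte(d[9], 400)
})

test_that("branched fixture is a rooted tree with the requested leaves", {
  m <- make_fixture("branched", daughters = 2L)
  g <- m$geometry
  expect_equal(sum(is.na(g$parent)), 1L)
  expect_true(all(g$parent[-1] < g$id[-1]))      # topological order, no cycles
  leaves <- setdiff(g$id, g$parent[!is.na(g$parent)])
  expect_equal(length(leaves), 2L)
})

test_that("path distance is additive along every fixture tree", {
  for (kind in c("ball_and_stick", "branched", "pyramidal")) {
    g <- make_fixture(kind)$geometry
    for (i in seq_len(nrow(g))[-1]) {
      p <- g$parent[i]
      lp <- if (g$type[p] == 1L) 0 else g$length_um[p]
      expect_equal(g$dist_um[i], g$dist_um[p] + (lp + g$length_um[i]) / 2)
    }
  }
})

test_that("every compartment receives a region label", {
  for (kind in c("single", "ball_and_stick", "branched", "pyramidal")) {
    g <- make_fixture(kind)$geometry
    expect_true(all(g$region %in% ionshift:::REGIONS))
  }
  # the CA1 fixture exercises every synapse-density class
  g <- make_fixture("pyramidal")$geometry
  expect_setequal(unique(g$region), ionshift:::REGIONS)
})

test_that("refine conserves area and volumes and preserves densities", {
  m <- attach_mechanisms(make_fixture("pyramidal"))
  expect_identical(refine(m, 1), m)
  m2 <- refine(m, 2)
  g <- m$geometry; g2 <- m2$geometry
  nsoma <- sum(g$type == 1L)
  expect_equal(nrow(g2), nsoma + 2L * (nrow(g) - nsoma))
  expect_equal(sum(g2$area_cm2), sum(g$area_cm2), tolerance = 1e-12)
  expect_equal(sum(g2$vol_i_cm3), sum(g$vol_i_cm3), tolerance = 1e-12)
  expect_equal(sum(g2$vol_o_cm3), sum(g$vol_o_cm3), tolerance = 1e-12)
  # per-area densities preserved, so total synaptic conductance is conserved
  expect_equal(sum(m2$mech$gaba_gbar * g2$area_cm2),
               sum(m$mech$gaba_gbar * g$area_cm2), tolerance = 1e-12)
  m4 <- refine(m, 4)
  expect_equal(sum(m4$geometry$vol_i_cm3), sum(g$vol_i_cm3), tolerance = 1e-12)
})

test_that("SWC files round-trip through write_swc/read_swc", {
  m <- make_fixture("branched")
  path <- withr::local_tempfile(fileext = ".swc")
  write_swc(m, path)
  m2 <- read_swc(path)
  expect_equal(nrow(m2$geometry), nrow(m$geometry))
  expect_equal(sort(m2$geometry$radius_um), sort(m$geometry$radius_um),
               tolerance = 1e-6)
  expect_equal(sum(m2$geometry$area_cm2), sum(m$geometry$area_cm2),
               tolerance = 1e-6)
})

test_that("SWC validation names the offending node", {
  bad_radius <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 10 -1", "2 4 20 0 0 0 1"), bad_radius)
  expect_error(read_swc(bad_radius), "node 2.*radius")

  orphan <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 10 -1", "2 4 20 0 0 1 9"), orphan)
  expect_error(read_swc(orphan), "node 2.*missing parent")

  two_roots <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 10 -1", "2 4 20 0 0 1 -1"), two_roots)
  expect_error(read_swc(two_roots), "exactly one root")
})

test_that("a single-point soma becomes an equal-area equivalent cylinder", {
  path <- withr::local_tempfile(fileext = ".swc")
  writeLines("1 1 0 0 0 8 -1", path)
  g <- read_swc(path)$geometry
  expect_equal(nrow(g), 1L)
  # sphere area 4*pi*r^2 equals cylinder 2*pi*r*L with L = 2r
  expect_equal(g$area_cm2, 4 * pi * 8^2 * 1e-8)
})

test_that("an axon is appended to the soma per the axon spec", {
  m <- make_fixture("ball_and_stick")
  n0 <- nrow(m$geometry)
  spec <- default_axon_spec()
  m2 <- attach_axon(m, spec)
  g2 <- m2$geometry
  expect_equal(nrow(g2), n0 + spec$n_initial + spec$n_cable)
  ax <- which(g2$type == 2L)
  expect_equal(g2$parent[ax[1]], 1L)
  expect_true(all(g2$region[ax] == "axon"))
  # initial segment tapers
  r_init <- g2$radius_um[ax[seq_len(spec$n_initial)]]
  expect_true(all(diff(r_init) <= 0))
})

test_that("degenerate and invalid geometries are rejected", {
  expect_error(new_ion_model(10, -1, NA, 1), "positive")
  expect_error(new_ion_model(c(10, 10), c(1, 1), c(NA, 3), c(1, 4)),
               "topological")
  expect_error(make_fixture("unknown_kind"))
})
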