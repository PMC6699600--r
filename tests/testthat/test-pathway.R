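test_that("probe_radius is the minimal gap to any vdW sphere", {
  one <- new_frame(data.frame(
    id = 1L, name = "C", resname = "UNK", resid = 1L, chain = "A",
    element = "C", x = 0, y = 0, z = 0, vdw = 0.15, is_water = FALSE))
  expect_equal(probe_radius(c(0, 0, 0.5), one), 0.35)
  one$atoms$vdw <- 0.17
  expect_equal(probe_radius(c(0, 0, 0), one), -0.17)

  # ring of 24 atoms, radius 0.5 nm, r = 0.12: brute-force oracle
  phi <- 2 * pi * (0:23) / 24
  ring <- new_frame(data.frame(
    id = 1:24, name = "C", resname = "UNK", resid = 1L, chain = "A",
    element = "C", x = 0.5 * cos(phi), y = 0.5 * sin(phi), z = 0,
    vdw = 0.12, is_water = FALSE))
  oracle <- min(sqrt((0.5 * cos(phi))^2 + (0.5 * sin(phi))^2) - 0.12)
  expect_equal(probe_radius(c(0, 0, 0), ring), oracle)
  expect_equal(probe_radius(c(0, 0, 0), ring), 0.38)

  # waters never enter the hard-sphere set
  wet <- one
  wet$atoms <- rbind(wet$atoms, transform(wet$atoms, id = 2L, z = 0.3,
                                          resname = "HOH", is_water = TRUE))
  expect_equal(probe_radius(c(0, 0, 0.5), wet), probe_radius(c(0, 0, 0.5), one))
})

test_that("in-plane optimization converges to the cylinder axis", {
  fx <- fixture_pore("cylinder")
  e_u <- c(1, 0, 0); e_w <- c(0, 1, 0)

  on_axis <- optimize_probe_in_plane(fx$frame, c(0, 0, 0.4), e_u, e_w, 100L)
  expect_lt(sqrt(sum(on_axis$point[1:2]^2)), 1e-4)
  expect_equal(on_axis$point[3L], 0.4)            # stays in the plane
  expect_equal(on_axis$radius, 0.38, tolerance = 1e-3)

  off <- optimize_probe_in_plane(fx$frame, c(0.2, 0, 0.4), e_u, e_w, 100L)
  expect_lt(sqrt(sum(off$point[1:2]^2)), 1e-3)

  # n_iter = 0 returns the seed unchanged
  id <- optimize_probe_in_plane(fx$frame, c(0.2, 0, 0.4), e_u, e_w, 0L)
  expect_equal(id$point, c(0.2, 0, 0.4))
  expect_equal(id$radius, probe_radius(c(0.2, 0, 0.4), fx$frame))
})

test_that("the optimizer never worsens the seed's probe radius", {
  fx <- fixture_pore("hourglass")
  set.seed(42)
  for (k in 1:20) {
    seed_pt <- c(runif(1, -0.1, 0.1), runif(1, -0.1, 0.1), runif(1, -1.5, 1.5))
    for (n_iter in c(1L, 5L, 100L)) {
      opt <- optimize_probe_in_plane(fx$frame, seed_pt, c(1, 0, 0), c(0, 1, 0),
                                     n_iter)
      expect_gte(opt$radius, probe_radius(seed_pt, fx$frame) - 1e-12)
    }
  }
})

test_that("pathway sweep recovers fixture radii and obeys step geometry", {
  geo <- geometry_of("cylinder")
  tr <- geo$trace
  interior <- abs(tr$points[, 3L]) < 1.8
  expect_lt(max(abs(tr$radii[interior] - 0.38)), 1e-3)
  expect_true(all(tr$radii <= 1.0))

  # consecutive displacement along e_v is exactly the probe step
  dz <- diff(tr$points[, 3L])
  expect_lt(max(abs(dz - 0.1)), 1e-9)

  waist <- geometry_of("hourglass")$trace
  expect_equal(min(waist$radii), 0.08, tolerance = 1e-2)
})

test_that("halving the probe step changes the radius profile only minimally", {
  g <- seq(-1.8, 1.8, by = 0.05)
  r1 <- radius_function(geometry_of("cylinder", probe_step = 0.1)$spline,
                        grid = g)
  r2 <- radius_function(geometry_of("cylinder", probe_step = 0.05)$spline,
                        grid = g)
  expect_lt(max(abs(r1$value - r2$value)), 1e-3)
})

test_that("an initial point outside the pore is rejected", {
  fx <- fixture_pore("cylinder")
  expect_error(
    find_pathway(fx$frame, pathway_config(init_point = c(4, 4, 0))),
    "initial point outside pore")
})

test_that("mirroring the structure mirrors the trace", {
  fx <- fixture_pore("funnel")
  tr <- find_pathway(fx$frame, pathway_config())
  mirrored <- fx$frame
  mirrored$atoms$z <- -mirrored$atoms$z
  tr_m <- find_pathway(mirrored, pathway_config())
  expect_equal(length(tr_m$radii), length(tr$radii))
  expect_lt(max(abs(rev(tr_m$radii) - tr$radii)), 1e-6)
  expect_lt(max(abs(rev(-tr_m$points[, 3L]) - tr$points[, 3L])), 1e-6)
})
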