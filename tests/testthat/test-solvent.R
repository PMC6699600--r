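test_that("Gaussian KDE has the exact single-kernel limit and normalization", {
  p1 <- kde_1d(0, bandwidth = 0.1)
  expect_equal(max(p1$value), 1 / (0.1 * sqrt(2 * pi)), tolerance = 1e-12)
  expect_equal(p1$s[which.max(p1$value)], 0)

  # N identical samples give the same profile as one
  pN <- kde_1d(rep(0, 50), bandwidth = 0.1)
  expect_equal(pN$value, p1$value)

  # integrates to 1 over samples +/- 5h
  set.seed(8)
  x <- rnorm(2000, sd = 0.7)
  p <- kde_1d(x, bandwidth = 0.14)
  ds <- diff(p$s)[1L]
  integral <- sum((p$value[-1L] + p$value[-length(p$value)]) / 2) * ds
  expect_equal(integral, 1, tolerance = 1e-6)

  expect_error(kde_1d(numeric(0)), "at least one sample")
})

test_that("a moderate bandwidth beats extreme ones on a bimodal density", {
  set.seed(3)
  x <- c(rnorm(5000, -1.5, 0.5), rnorm(5000, 1.5, 0.5))
  truth <- function(s) 0.5 * dnorm(s, -1.5, 0.5) + 0.5 * dnorm(s, 1.5, 0.5)
  l2 <- vapply(c(0.01, 0.14, 2.0), function(h) {
    p <- kde_1d(x, h, range = c(-5, 5), spacing = 0.01)
    sqrt(sum((p$value - truth(p$s))^2) * 0.01)
  }, numeric(1L))
  expect_lt(l2[2L], l2[1L])
  expect_lt(l2[2L], l2[3L])
})

test_that("AMISE bandwidth follows the normal reference rule", {
  set.seed(21)
  x <- rnorm(50000)
  h <- amise_bandwidth(x)
  expect_equal(h, 1.06 * sd(x) * length(x)^(-1 / 5), tolerance = 1e-12)
  expect_equal(h, 1.06 * 50000^(-1 / 5), tolerance = 0.01)  # sigma ~ 1

  # scale equivariance and the N^(-1/5) rate
  expect_equal(amise_bandwidth(2 * x), 2 * h)
  x4 <- rnorm(200000)
  expect_equal(amise_bandwidth(x4) / h, 4^(-1 / 5), tolerance = 0.01)

  expect_error(amise_bandwidth(rep(1, 10)), "distinct")
})

test_that("number density has the uniform limit and radius scaling", {
  s <- seq(0, 4, length.out = 81L)
  L <- 4
  P <- new_profile(s, rep(1 / L, 81L), "density")
  attr(P, "n_samples") <- 1000L
  R <- new_profile(s, rep(0.4, 81L), "radius")
  n <- number_density(P, R)
  expect_equal(n$value, rep(1000 / (pi * 0.4^2 * L), 81L))

  R2 <- new_profile(s, rep(0.8, 81L), "radius")
  expect_equal(number_density(P, R2)$value, n$value / 4)

  R_bad <- new_profile(s, c(rep(0.4, 80L), 0), "radius")
  expect_error(number_density(P, R_bad), "positive")
})

test_that("waters at bulk density are recovered from fixture placement", {
  fx <- fixture_pore("cylinder", length = 8, radius = 1.0)
  R_true <- fx$oracle$radius(0)
  N <- round(33.37 * pi * R_true^2 * 8)
  fr <- place_waters(fx, N, seed = 19)
  w <- fr$atoms[fr$atoms$is_water, ]
  z <- seq(-4.7, 4.7, by = 0.1)              # analytic centerline suffices
  tr <- synthetic_trace(cbind(0, 0, z), rep(R_true, length(z)),
                        p0 = c(0, 0, 0))     # s = z
  sp <- fit_centerline(tr)
  sw <- to_curvilinear(sp, as.matrix(w[, c("x", "y", "z")]))$s
  g <- seq(sp$s_min - sp$s_offset, sp$s_max - sp$s_offset, length.out = 189L)
  P <- kde_1d(sw, 0.14, range = range(g), spacing = g[2L] - g[1L])
  n <- number_density(P, new_profile(g, rep(R_true, length(g)), "radius"))
  interior <- abs(n$s) <= 3
  expect_equal(mean(n$value[interior]), 33.37, tolerance = 0.05)
})

test_that("Boltzmann inversion has exact uniform and e-fold limits", {
  s <- seq(-4, 4, length.out = 161L)
  R <- new_profile(s, rep(0.4, 161L), "radius")

  # P proportional to R^2 everywhere: G identically zero
  P0 <- new_profile(s, rep(1 / 8, 161L), "density")
  G0 <- free_energy(P0, R, N = 1e6)
  expect_lt(max(abs(G0$value)), 1e-12)

  # interior density lowered by exp(-1): barrier of exactly kB*T
  val <- rep(1, 161L); val[abs(s) < 1] <- exp(-1)
  val <- val / (sum(val) * (s[2L] - s[1L]))
  P1 <- new_profile(s, val, "density")
  G1 <- free_energy(P1, R, temperature = 298.15, N = 1e6,
                    bulk_band = list(c(-4, -3), c(3, 4)))
  kT <- 0.008314462618 * 298.15
  expect_equal(max(G1$value), kT, tolerance = 1e-9)
  expect_equal(kT, 2.4790, tolerance = 1e-4)

  # bulk convention: mean over the bulk band is zero by construction
  bulk <- (G1$s <= -3) | (G1$s >= 3)
  expect_lt(abs(mean(G1$value[bulk])), 1e-9)

  # dehydrated flagging: zero-density points are flagged, not singular
  val2 <- val; val2[abs(s) < 0.5] <- 0
  P2 <- new_profile(s, val2, "density")
  G2 <- free_energy(P2, R, N = 1e4, bulk_band = list(c(-4, -3), c(3, 4)))
  expect_true(any(attr(G2, "dehydrated")))
  expect_true(all(is.finite(G2$value)))
  expect_error(free_energy(P2, R, N = 1e4, bulk_band = c(-0.4, 0.4)),
               "dehydrated")
})

test_that("a known free-energy barrier is recovered from sampled positions", {
  # draw positions directly from the Boltzmann density along s
  kT <- 0.008314462618 * 298.15
  Gfun <- function(s) 5 * exp(-s^2 / (2 * 0.8^2))
  set.seed(4)
  n_kept <- 0L; samples <- numeric(0)
  while (length(samples) < 5e4) {
    z <- runif(1e5, -4, 4)
    keep <- runif(1e5) < exp(-(Gfun(z) - 0) / kT)
    samples <- c(samples, z[keep])
  }
  samples <- samples[1:5e4]
  g <- seq(-4, 4, length.out = 201L)
  P <- kde_1d(samples, 0.14, range = c(-4, 4), spacing = g[2L] - g[1L])
  R <- new_profile(P$s, rep(1, length(P$s)), "radius")
  G <- free_energy(P, R, bulk_band = list(c(-3.5, -2.5), c(2.5, 3.5)))
  expect_equal(max(G$value[abs(G$s) <= 2]), 5, tolerance = 0.1)
})

test_that("bandwidth controls the density/energy trade-off monotonically", {
  # constant-radius pore with a deep hydrophobic barrier: no steric
  # constriction, so the 1/R^2 factor cannot confound the density minimum
  geo <- geometry_of("cylinder", length = 16)
  fr <- place_waters(geo$fixture, 3e4,
                     target_G = function(z) 12 * exp(-z^2 / (2 * 0.8^2)),
                     seed = 5)
  w <- fr$atoms[fr$atoms$is_water, ]
  sw <- to_curvilinear(geo$spline, as.matrix(w[, c("x", "y", "z")]))$s
  g <- seq(-7.8, 7.79, by = 0.05)
  rp <- radius_function(geo$spline, grid = g)
  interior <- abs(g) <= 4
  stats <- vapply(c(0.05, 0.14, 0.34, 1.0), function(h) {
    P <- kde_1d(sw, h, range = range(g), spacing = g[2L] - g[1L])
    n <- number_density(P, rp)
    G <- free_energy(P, rp, bulk_band = list(c(-7.5, -6), c(6, 7.5)))
    c(min(n$value[interior]), max(G$value[interior]))
  }, numeric(2L))
  expect_true(all(diff(stats[1L, ]) >= 0))   # min density non-decreasing in h
  expect_true(all(diff(stats[2L, ]) <= 0))   # barrier non-increasing in h
})

test_that("de-wetted segments are detected by length and density threshold", {
  s <- seq(0, 8, length.out = 161L)
  flat <- new_profile(s, rep(33, 161L), "number_density")
  expect_length(detect_dewetted(flat), 0L)

  dry <- rep(33, 161L); dry[s >= 3 & s <= 4.2] <- 0
  p <- new_profile(s, dry, "number_density")
  iv <- detect_dewetted(p, fraction_of_bulk = 0.2, min_length = 0.5)
  expect_length(iv, 1L)
  expect_equal(iv[[1L]][2L] - iv[[1L]][1L], 1.2, tolerance = 0.06)

  two <- rep(33, 161L)
  two[s >= 2 & s <= 2.3] <- 0; two[s >= 5 & s <= 5.3] <- 0
  expect_length(detect_dewetted(new_profile(s, two, "number_density"),
                                fraction_of_bulk = 0.2, min_length = 0.5), 0L)
})
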