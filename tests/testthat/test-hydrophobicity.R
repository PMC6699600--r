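test_that("scale normalization is two-sided and preserves the natural zero", {
  sc <- normalize_scale(c(A = 2, B = -4, C = 0))
  expect_equal(unname(sc$normalized), c(1, -1, 0))

  # transfer-free-energy orientation: hydrophobic at negative raw values
  sc2 <- normalize_scale(c(TRP = -1.85, LYS = 0.99, GLY = 0.01),
                         higher_is_hydrophobic = FALSE)
  expect_equal(unname(sc2$normalized["TRP"]), 1)
  expect_equal(unname(sc2$normalized["LYS"]), -1)

  expect_error(normalize_scale(c(A = 0, B = 0)), "zero")
})

test_that("every bundled scale spans exactly [-1, +1] over the 20 residues", {
  scales <- list_scales()
  expect_setequal(scales, c("hessa", "kyte_doolittle",
                            "wimley_white_interface", "wimley_white_octanol"))
  for (name in scales) {
    sc <- load_scale(name)
    expect_length(sc$normalized, 20L)
    expect_equal(max(sc$normalized), 1)
    expect_equal(min(sc$normalized), -1)
    # sign pattern preserved relative to the (oriented) raw values
    oriented <- if (sc$higher_is_hydrophobic) sc$raw else -sc$raw
    expect_equal(sign(sc$normalized), sign(oriented))
  }
  # the default scale ranks leucine hydrophobic and serine hydrophilic
  ww <- load_scale("wimley_white_interface")
  expect_gt(ww$normalized[["LEU"]], 0)
  expect_lt(ww$normalized[["SER"]], 0)
})

test_that("classification boundaries are inclusive", {
  z <- seq(-2, 2, by = 0.1)
  tr <- synthetic_trace(cbind(0, 0, z), rep(0.38, length(z)), p0 = c(0, 0, 0))
  sp <- fit_centerline(tr)
  rp <- radius_function(sp, tr)
  rho_edge <- 0.38 + 0.75     # exactly R(s) + R_thres
  atoms <- data.frame(
    id = 1:4,
    name = c("CA", "CB", "CA", "CB"),
    resname = "ALA", resid = c(1L, 1L, 2L, 2L), chain = "A",
    element = "C",
    x = c(rho_edge, rho_edge, 2, 2), y = 0, z = c(0, 0.4, 0, 0.4),
    vdw = 0.17, is_water = FALSE, stringsAsFactors = FALSE)
  frame <- new_frame(atoms)
  ann <- classify_residues(frame, sp, rp, R_thres = 0.75)
  # residue 1 sits exactly on the lining boundary, with rho_ca = rho_cog
  expect_true(ann$pore_lining[ann$resid == 1L])
  expect_true(ann$pore_facing[ann$resid == 1L])
  # residue 2 lies beyond the cutoff
  expect_false(ann$pore_lining[ann$resid == 2L])
})

test_that("fixture ground-truth classification is recovered exactly", {
  geo <- geometry_of("hourglass")
  fx <- geo$fixture
  expect_warning(
    ann <- classify_residues(fx$frame, geo$spline, geo$radius,
                             R_thres = 0.75, scale = load_scale()),
    "alpha-carbon")
  keys <- paste0(ann$chain, ":", ann$resid)
  expect_setequal(keys[ann$pore_facing], fx$facing_keys)
  expect_setequal(keys[ann$pore_lining],
                  c(fx$facing_keys, fx$lining_only_keys))
  expect_setequal(keys[!ann$pore_lining], fx$decoy_keys)
  # pore-facing implies pore-lining
  expect_true(all(ann$pore_lining[ann$pore_facing]))

  # classification is independent of atom ordering
  shuffled <- fx$frame
  set.seed(2)
  shuffled$atoms <- shuffled$atoms[sample.int(nrow(shuffled$atoms)), ]
  suppressWarnings(
    ann2 <- classify_residues(shuffled, geo$spline, geo$radius,
                              R_thres = 0.75))
  ord <- order(ann$chain, ann$resid)
  ord2 <- order(ann2$chain, ann2$resid)
  expect_equal(ann2$pore_facing[ord2], ann$pore_facing[ord])
  expect_equal(ann2$pore_lining[ord2], ann$pore_lining[ord])
})

test_that("the smoothed hydrophobicity profile behaves like a kernel average", {
  grid <- seq(-3, 3, by = 0.05)
  one <- data.frame(chain = "A", resid = 1L, resname = "LEU",
                    s_cog = 0, rho_cog = 0.5, s_ca = 0, rho_ca = 0.7,
                    pore_lining = TRUE, pore_facing = TRUE,
                    hydrophobicity = 0.8)
  H <- hydrophobicity_profile(one, grid, lambda = 0.225)
  at0 <- H$value[which.min(abs(H$s))]
  expect_equal(at0, 0.8, tolerance = 0.02)
  expect_true(all(H$value <= at0 + 1e-12))
  # decays to zero far from any residue
  expect_lt(max(abs(H$value[abs(H$s) > 2])), 0.01)

  # constant values give (nearly) the constant near the residues
  many <- do.call(rbind, lapply(1:9, function(i) {
    r <- one; r$resid <- i; r$s_cog <- -1 + 0.25 * (i - 1); r
  }))
  many$hydrophobicity <- 0.6
  Hc <- hydrophobicity_profile(many, grid, lambda = 0.225)
  near <- abs(Hc$s) <= 0.9
  expect_equal(Hc$value[near], rep(0.6, sum(near)), tolerance = 0.01)

  # antisymmetric pair: exact zero at the midpoint, bounded by [min, max]
  pair <- do.call(rbind, list(one, one))
  pair$resid <- 1:2; pair$s_cog <- c(0, 1)
  pair$hydrophobicity <- c(1, -1)
  Hp <- hydrophobicity_profile(pair, seq(-1, 2, by = 0.1), lambda = 0.225)
  expect_equal(Hp$value[Hp$s == 0.5], 0, tolerance = 1e-12)
  expect_true(all(Hp$value >= -1 - 1e-12 & Hp$value <= 1 + 1e-12))

  expect_error(hydrophobicity_profile(one[0L, ], grid), "pore-facing")
})

test_that("the hydrophobic waist keeps its sign pattern across smoothing spans", {
  geo <- geometry_of("hourglass")
  suppressWarnings(
    ann <- classify_residues(geo$fixture$frame, geo$spline, geo$radius,
                             scale = load_scale()))
  for (lambda in c(0.1, 0.225, 0.5)) {
    H <- hydrophobicity_profile(ann, geo$radius$s, lambda = lambda)
    expect_gt(H$value[which.min(abs(H$s - 0.1))], 0)  # leucine waist ring
    expect_lt(H$value[which.min(abs(H$s - 1.5))], 0)  # serine flank
  }
})

test_that("the cylindrical de-wetting free energy follows the wetting balance", {
  gamma <- 0.05
  # 90 degrees: length-independent
  expect_equal(dewetting_free_energy(0.5, 1, gamma, pi / 2),
               2 * pi * 0.5^2 * gamma)
  expect_equal(dewetting_free_energy(0.5, 7, gamma, pi / 2),
               2 * pi * 0.5^2 * gamma)
  # hydrophilic wall: liquid favored, linear growth in L
  d1 <- dewetting_free_energy(0.5, 1, gamma, 0)
  d2 <- dewetting_free_energy(0.5, 2, gamma, 0)
  d3 <- dewetting_free_energy(0.5, 3, gamma, 0)
  expect_gt(d1, 0)
  expect_equal(d3 - d2, d2 - d1, tolerance = 1e-12)
  # direct arithmetic oracle
  expect_equal(dewetting_free_energy(0.5, 1.0, 0.05, 2 * pi / 3),
               2 * pi * 0.5 * 0.05 * (0.5 + 1.0 * cos(2 * pi / 3)))
})
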