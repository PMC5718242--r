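# dose_analysis: curves, reference parameters, beam-quality energies and
# the misalignment metric set, against analytic fixtures and brute-force
# oracles.

test_that("extract_pdd reproduces a separable depth function and normalizes to 100", {
  fx <- generate_fixture("analytic_pdd", list(output = "grid", r100 = 12,
                                              r50 = 25, rp = 33))
  pdd <- extract_pdd(fx, aperture = 10)
  expect_equal(max(pdd$percent), 100)
  ref <- generate_fixture("analytic_pdd", list(r100 = 12, r50 = 25, rp = 33,
                                               depth_max = 70))
  # central-aperture curve of a separable grid equals the 1D generator
  expect_equal(pdd$percent, ref$percent, tolerance = 1e-6)
})

test_that("wider apertures give a shallower curve on a diverging cone beam", {
  # cone beam: fixed axial dose, lateral spread growing with depth, so a
  # wide aperture collects relatively more dose at depth
  dims <- c(60, 80, 80); voxel <- 0.5
  x <- (seq_len(dims[1]) - 0.5) * voxel
  y <- (seq_len(dims[2]) - 0.5) * voxel - 20
  sig <- 2 + 0.2 * x
  vals <- vapply(seq_along(x), function(i) {
    outer(exp(-y^2 / (2 * sig[i]^2)), exp(-y^2 / (2 * sig[i]^2)))
  }, matrix(0, dims[2], dims[3]))
  g <- new_dose_grid(aperm(vals, c(3, 1, 2)), voxel = voxel, n_histories = 1L)
  narrow <- extract_pdd(g, aperture = 2)
  wide <- extract_pdd(g, aperture = 40)
  # narrow aperture: flat at 100 everywhere; wide: rises with depth, so its
  # shallow values sit below the narrow curve
  expect_lt(wide$percent[1], narrow$percent[1])
})

test_that("reference points are exact on a piecewise-linear toy curve", {
  x <- seq(0, 25, by = 0.5)
  pct <- ifelse(x <= 10, 50 + 5 * x, pmax(100 - 10 * (x - 10), 0))
  curve <- depth_dose_curve(x, pct)
  rp <- reference_points(curve, smooth = FALSE)
  expect_equal(rp$R100, 10)
  expect_equal(rp$R50, 15)
  expect_equal(rp$R30, 17)
  expect_equal(rp$Rp, 20, tolerance = 1e-6)
  expect_error(
    reference_points(depth_dose_curve(x, rep(c(100, 99), length.out = length(x))),
                     smooth = FALSE),
    "never falls")
})

test_that("reference points recover analytic fixture parameters (fine-scan oracle)", {
  for (r50 in c(20.8, 34.8)) {
    fx <- generate_fixture("analytic_pdd",
                           list(r100 = 0.43 * r50, r50 = r50, rp = 1.3 * r50))
    rp <- reference_points(fx, smooth = FALSE)
    # brute-force oracle: 1e4-point scan of the same generator
    fine <- generate_fixture("analytic_pdd",
                             list(r100 = 0.43 * r50, r50 = r50, rp = 1.3 * r50,
                                  step = 70 / 1e4))
    scan_r50 <- fine$depth[max(which(fine$percent >= 50))]
    expect_lt(abs(rp$R50 - r50), 0.25)
    expect_lt(abs(rp$R50 - scan_r50), 0.25)
    expect_lt(abs(rp$Rp - 1.3 * r50), 0.6)
    # ordering invariant over the crossing-based points; Rp beyond R30
    v <- unlist(rp)[1:5]
    expect_true(all(diff(v) > 0))
    expect_gt(rp$Rp, rp$R30)
  }
})

test_that("beam-quality relations reproduce unit cases and reject bad input", {
  expect_equal(mean_energy_from_r50(10), 2.33)
  expect_equal(most_probable_energy_from_rp(0), 0.22)
  expect_error(mean_energy_from_r50(0), "positive")
  expect_error(most_probable_energy_from_rp(-1), "non-negative")
})

test_that("lateral profiles are symmetric for symmetric grids and match the generator", {
  fx <- generate_fixture("flat_profile", list(width = 100, asymmetry_pct = 0))
  expect_equal(fx$percent, rev(fx$percent), tolerance = 1e-9)
  m <- profile_metrics(fx)
  expect_equal(m$symmetry, 100, tolerance = 1e-6)
  expect_equal(m$homogeneity, 100, tolerance = 0.02)
  expect_equal(m$field_size, 10, tolerance = 0.02)
})

test_that("profile extraction from a grid recovers a delta-like beam", {
  dims <- c(20, 60, 60)
  vals <- array(0, dims)
  vals[, 30:31, 30:31] <- 1 # narrow column on the axis
  g <- new_dose_grid(vals, voxel = 0.5, n_histories = 1L)
  p <- extract_profile(g, depth = 2.5, strip = 2)
  expect_equal(sum(p$raw > 0), 2)
  expect_true(all(abs(p$offset[p$raw > 0]) <= 0.5))
})

test_that("profile metrics follow the adopted ratio definitions", {
  # one asymmetric pair: D(+y) = 100, D(-y) = 98 inside the flattened region
  off <- seq(-60, 60, by = 1)
  v <- ifelse(abs(off) <= 51.25, 100, 0)
  v[off == -30] <- 98
  p <- lateral_profile(off, v)
  m <- profile_metrics(p)
  expect_equal(m$symmetry, 100 * 100 / 98, tolerance = 1e-6)
  expect_equal(m$field_size, 10.25, tolerance = 0.06) # 102.5 mm at 50%
  expect_error(profile_metrics(lateral_profile(off, rep(100, length(off)))),
               "50%")
})

test_that("shielding factor follows its definition and is scale invariant", {
  expect_equal(shielding_factor(0, 5), 100)
  expect_equal(shielding_factor(5, 5), 0)
  expect_equal(shielding_factor(1, 25), 96)
  expect_equal(shielding_factor(1, 25), shielding_factor(7 * 1, 7 * 25))
  expect_error(shielding_factor(1, 0), "Dnd is zero")
})

test_that("backscatter factor is 1 for identical curves and recovers a built-in bump", {
  x <- seq(0.25, 50, by = 0.5)
  base <- 100 / (1 + exp((x - 35) / 2))
  a <- depth_dose_curve(x, base)
  bsf0 <- backscatter_factor(a, a, disc_depth = 24.5)
  expect_true(all(abs(bsf0$bsf - 1) < 1e-12))
  # 20% enhancement in the 5 mm before the disc face
  bump <- base * ifelse(x >= 19.5 & x < 24.5, 1.2, 1)
  b <- depth_dose_curve(x, bump)
  bsf <- backscatter_factor(b, a, disc_depth = 24.5)
  expect_equal(bsf$bsf_max, 1.2, tolerance = 1e-9)
  broken <- a; broken$raw <- NULL
  expect_error(backscatter_factor(broken, a, 24.5), "unnormalized")
})

test_that("maximum leakage dose scales with prescription and matches a window-scan oracle", {
  fx <- generate_fixture("disc_leak", list(background = 0.5, amp = 8,
                                           sigma = 1.5, center = c(30, 5, -3)))
  d <- to_dose(fx)
  mask <- array(FALSE, dim(d)); mask[seq(41, 80), , ] <- TRUE # x > 20 mm
  r100 <- max(d)
  mld23 <- max_leakage_dose(d, mask, 23, r100, window_mm = 1, voxel = 0.5)
  mld21 <- max_leakage_dose(d, mask, 21, r100, window_mm = 1, voxel = 0.5)
  expect_equal(mld21 / mld23, 21 / 23, tolerance = 1e-12)
  # uniform leakage with prescription anchored at the same level -> 23 Gy
  du <- array(2, dim = c(10, 10, 10))
  mu <- array(TRUE, dim = dim(du))
  expect_equal(max_leakage_dose(du, mu, 23, 2), 23)
  # brute-force 2x2x2 window scan oracle
  w <- 2; dd <- dim(d); best <- -Inf
  for (i in 41:(dd[1] - 1)) for (j in seq(1, dd[2] - 1, by = 1)) {
    for (k in seq(1, dd[3] - 1, by = 1)) {
      best <- max(best, mean(d[i:(i + 1), j:(j + 1), k:(k + 1)]))
    }
  }
  expect_equal(mld23, 23 / r100 * best, tolerance = 1e-12)
})

test_that("DVH is monotone, starts at 1 and counts underdosed volume correctly", {
  du <- array(2, dim = c(8, 8, 8))
  mask <- array(TRUE, dim(du))
  v <- dvh(du, mask)
  expect_equal(v$volume_fraction[1], 1)
  expect_equal(v$underdosed_fraction_80, 0)
  # half at 100%, half at 50%
  dh <- du; dh[1:4, , ] <- 1
  v2 <- dvh(dh, mask)
  expect_equal(v2$underdosed_fraction_80, 50)
  expect_true(all(diff(v2$volume_fraction) <= 0))
  # random grid vs sort-based brute force
  set.seed(12)
  dr <- array(runif(512), dim = c(8, 8, 8))
  v3 <- dvh(dr, mask, n_bins = 64)
  brute <- vapply(v3$dose, function(L) sum(sort(dr) >= L) / 512, numeric(1))
  brute[1] <- 1
  expect_equal(v3$volume_fraction, brute)
  expect_error(dvh(du, array(FALSE, dim(du))), "empty")
  # central-plane variant counts only z = 0 voxels
  vz <- dvh(dh, mask, plane = "z0")
  expect_equal(vz$underdosed_fraction_80, 50)
})

test_that("rebin_grid block-averages preserving the mean", {
  a <- array(seq_len(4 * 4 * 4), dim = c(4, 4, 4))
  r <- rebin_grid(a, 2)
  expect_equal(dim(r), c(2, 2, 2))
  expect_equal(mean(r), mean(a))
  expect_equal(r[1, 1, 1], mean(a[1:2, 1:2, 1:2]))
})

test_that("film misalignment recovers top-hat offsets exactly", {
  f0 <- generate_fixture("film_tophat", list(radius = 30, offset = c(0, 0)))
  expect_lt(film_misalignment(f0)$offset_mm, 1e-9)
  f345 <- generate_fixture("film_tophat", list(radius = 30, offset = c(3, 4)))
  res <- film_misalignment(f345)
  expect_equal(res$offset_mm, 5, tolerance = 0.05)
  expect_equal(res$radius_mm, 30, tolerance = 0.5)
  dark <- film_map(matrix(0, 5, 5), y = 1:5, z = 1:5)
  expect_error(film_misalignment(dark), "no 50% isodose")
})
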