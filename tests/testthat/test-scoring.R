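# scoring: deposits, dose conversion, regions, batch uncertainty.

empty_grid <- function(dims = c(20, 20, 20), voxel = 0.5) {
  new_dose_grid(array(0, dim = dims), voxel = voxel, n_histories = 1L)
}

test_that("deposit uses half-open voxel bins and an outside tally", {
  g <- empty_grid()
  # exactly on the face between voxels 2 and 3 along x -> higher-index voxel
  g <- deposit(g, c(1.0, -4.9, -4.9), 1)
  expect_equal(g$values[3, 1, 1], 1)
  expect_equal(g$values[2, 1, 1], 0)
  g <- deposit(g, c(1.0, -4.9, -4.9), 1)
  expect_equal(g$values[3, 1, 1], 2)
  out0 <- g$outside
  g <- deposit(g, c(50, 0, 0), 5) # beyond the 10 mm grid
  expect_equal(g$outside, out0 + 5)
  expect_error(deposit(g, c(1, 0, 0), -1), "negative")
})

test_that("to_dose converts energy to Gy using the voxel mass", {
  g <- empty_grid()
  g <- deposit(g, c(0.1, -4.9, -4.9), 1) # 1 MeV in one 0.5 mm water voxel
  d <- to_dose(g) # voxel mass 1.25e-4 g
  expect_equal(max(d), 1.2817413072e-06, tolerance = 1e-9)
  expect_equal(sum(d > 0), 1)
  expect_true(all(to_dose(empty_grid()) == 0))
})

test_that("equal energy gives lower dose in lead than in water voxels", {
  cfg <- fast_config(disc = list(enabled = TRUE, depth = 20))
  geom <- build_geometry(cfg)
  dims <- c(28, 60, 60)
  vals <- array(1, dim = dims) # 1 MeV everywhere
  g <- new_dose_grid(vals, voxel = 2.5, n_histories = 1L)
  d <- to_dose(g, geom)
  ix_water <- 4  # x ~ 8.75 mm
  ix_al <- 9     # x ~ 21.25 mm; disc spans 20..26 (Al 20-24, Pb 24-26)
  expect_equal(d[ix_water, 30, 30] / d[ix_al, 30, 30],
               get_material("aluminum")$density / get_material("water")$density,
               tolerance = 1e-3)
})

test_that("region_dose sums correctly and is additive over disjoint regions", {
  cfg <- fast_config(disc = list(enabled = FALSE, depth = 20))
  geom <- build_geometry(cfg)
  dims <- c(28, 60, 60)
  set.seed(4)
  g <- new_dose_grid(array(runif(prod(dims)), dim = dims), voxel = 2.5,
                     n_histories = 1L)
  tz <- region_mask(g, region_spec("treatment_zone", geom))
  nt <- region_mask(g, region_spec("normal_tissue", geom))
  expect_false(any(tz & nt)) # disjoint by construction
  # uniform dose over a region: N * d
  gu <- new_dose_grid(array(2, dim = dims), voxel = 2.5, n_histories = 1L)
  expect_equal(region_dose(gu, tz), 2 * sum(tz))
  # axis aperture: a 20 mm square column spans the full depth
  ax <- region_mask(g, region_spec("axis_aperture", geom, aperture = 20))
  expect_equal(sum(ax), dims[1] * 8 * 8) # 8 voxels of 2.5 mm per axis
  # additivity and brute-force agreement
  expect_equal(region_dose(g, tz) + region_dose(g, nt),
               region_dose(g, tz | nt))
  brute <- 0
  for (i in which(tz)) brute <- brute + g$values[i]
  expect_equal(region_dose(g, tz), brute)
  expect_error(region_dose(g, array(FALSE, dims)), "empty")
})

test_that("treatment + normal + rest partitions the detector", {
  run <- fast_run_nodisc()
  geom <- run$geometry
  tz <- region_mask(run$grid, region_spec("treatment_zone", geom))
  nt <- region_mask(run$grid, region_spec("normal_tissue", geom))
  rest <- !(tz | nt)
  expect_equal(region_dose(run$grid, tz) + region_dose(run$grid, nt) +
                 sum(run$grid$values[rest]),
               sum(run$grid$values))
})

test_that("batch uncertainty follows the batch-mean formula", {
  dims <- c(2, 2, 2)
  d <- 3
  vals <- array(d + 3 * d, dim = dims)           # two batches: d and 3d
  ssq <- array(d^2 + (3 * d)^2, dim = dims)
  g <- new_dose_grid(vals, voxel = 1, n_batches = 2L, batch_sumsq = ssq)
  u <- batch_uncertainty(g)
  expect_equal(unname(u[1, 1, 1]), 0.5) # SE/mean = d/(2d)
  # identical batches -> zero everywhere
  g2 <- new_dose_grid(array(2, dims), voxel = 1, n_batches = 2L,
                      batch_sumsq = array(2, dims))
  expect_true(all(batch_uncertainty(g2) == 0))
  expect_error(batch_uncertainty(new_dose_grid(array(1, dims), voxel = 1)),
               "2 batches")
})

test_that("Poisson-like batches match the analytic standard error within 10%", {
  set.seed(9)
  B <- 10L; lambda <- 100
  n_vox <- 4000
  batches <- matrix(rpois(n_vox * B, lambda), n_vox, B)
  vals <- array(rowSums(batches), dim = c(n_vox, 1, 1))
  ssq <- array(rowSums(batches^2), dim = c(n_vox, 1, 1))
  g <- new_dose_grid(vals, voxel = 1, n_batches = B, batch_sumsq = ssq)
  u <- batch_uncertainty(g)
  analytic <- sqrt(lambda / B) / lambda # SE of batch mean / mean
  expect_lt(abs(mean(u) - analytic) / analytic, 0.10)
})

test_that("grid + outside + escaped ties back to the injected energy", {
  run <- fast_run_nodisc()
  s <- run$stats
  expect_equal(sum(run$grid$values) + s$outside_mev + s$escaped_mev,
               s$injected_mev, tolerance = 1e-9)
})
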