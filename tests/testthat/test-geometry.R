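# geometry: beamline construction, point classification, exact boundary
# distances, disc pose transforms.

test_that("default geometry follows the coordinate convention", {
  g <- build_geometry(list())
  expect_equal(g$win_x0, -1000)       # source plane at x = -SSD
  expect_equal(g$phantom_depth, 200)  # phantom surface at x = 0
  expect_false(g$disc_enabled)
  expect_identical(locate(g, c(10, 0, 0))$region, "water")
  expect_identical(locate(g, c(-500, 55, 0))$region, "PMMA")
  expect_identical(locate(g, c(-500, 0, 0))$region, "air gap")
  expect_identical(locate(g, c(-999.99, 0, 0))$region, "window")
  expect_identical(locate(g, c(1e6, 0, 0))$region, "outside")
})

test_that("disc pose places layers correctly including the 180-degree flip", {
  g <- build_geometry(list(disc = list(enabled = TRUE, depth = 24.5)))
  # proximal face plane at x = 24.5
  expect_identical(locate(g, c(24.4, 0, 0))$region, "water")
  expect_identical(locate(g, c(24.6, 0, 0))$region, "disc-Al")
  # disc centre + 1 mm along the normal is in the lead layer (Al is 4 mm)
  expect_identical(locate(g, c(24.5 + 3 + 1, 0, 0))$region, "disc-Pb")
  gf <- build_geometry(list(disc = list(enabled = TRUE, depth = 24.5,
                                        flipped = TRUE)))
  expect_identical(locate(gf, c(24.5 + 3 + 1, 0, 0))$region, "disc-Al")
  # distal face
  expect_identical(locate(g, c(30.6, 0, 0))$region, "water")
  # radial extent: 60 mm (Al spans 24.5-28.5, Pb 28.5-30.5)
  expect_identical(locate(g, c(27, 59.9, 0))$region, "disc-Al")
  expect_identical(locate(g, c(29.5, 59.9, 0))$region, "disc-Pb")
  expect_identical(locate(g, c(29.5, 60.1, 0))$region, "water")
})

test_that("untilted disc occupies exactly depth..depth+6 within radius 60", {
  g <- build_geometry(list(disc = list(enabled = TRUE, depth = 20)))
  set.seed(1)
  pts <- cbind(runif(300, 15, 32), runif(300, -70, 70), runif(300, -70, 70))
  inside <- pts[, 1] >= 20 & pts[, 1] < 26 & pts[, 2]^2 + pts[, 3]^2 <= 60^2
  got <- apply(pts, 1, function(p) locate(g, p)$region)
  expect_identical(got %in% c("disc-Al", "disc-Pb"), unname(inside))
})

test_that("construction invariants are enforced", {
  expect_error(build_geometry(list(disc = list(enabled = TRUE, diameter = 90))),
               "must exceed the collimator")
  expect_error(build_geometry(list(disc = list(enabled = TRUE, depth = 199))),
               "does not fit")
  expect_error(build_geometry(list(disc = list(enabled = TRUE, tilt = 95))),
               "tilt")
  expect_error(build_geometry(list(geometry = list(collimator_x1 = 5))),
               "overlap")
})

test_that("distance_to_boundary is exact for planes and survives parallel rays", {
  g <- build_geometry(list(disc = list(enabled = TRUE, depth = 24.5)))
  # 5 mm above the flat disc face, heading +x
  expect_equal(distance_to_boundary(g, c(19.5, 0, 0), c(1, 0, 0)), 5,
               tolerance = 1e-9)
  # ray parallel to the disc faces: next boundary is the disc rim cylinder
  expect_equal(distance_to_boundary(g, c(27, 0, 0), c(0, 1, 0)), 60,
               tolerance = 1e-9)
  expect_error(distance_to_boundary(g, c(1e5, 0, 0), c(1, 0, 0)), "outside")
  expect_error(distance_to_boundary(g, c(1, 0, 0), c(2, 0, 0)), "unit vector")
})

test_that("tilted-disc boundary distances agree with a brute-force ray march", {
  g <- build_geometry(list(disc = list(enabled = TRUE, depth = 24.5,
                                       tilt = 30)))
  set.seed(7)
  h <- 2e-3 # march step, mm
  for (i in 1:20) {
    p <- c(runif(1, 18, 23), runif(1, -40, 40), runif(1, -40, 40))
    th <- runif(1, 0, pi); ph <- runif(1, 0, 2 * pi)
    d <- c(cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
    dist <- distance_to_boundary(g, p, d)
    reg0 <- locate(g, p)$region
    # march to the first region change within 4 mm
    steps <- seq(h, 4, by = h)
    regs <- vapply(steps, function(s) locate(g, p + s * d)$region, character(1))
    change <- which(regs != reg0)
    if (length(change)) {
      expect_lt(abs(dist - steps[change[1]]), 2 * h)
    } else {
      expect_gt(dist, 4 - 2 * h)
    }
  }
})

test_that("stepping just past the boundary changes (or keeps, at tangency) the region", {
  g <- build_geometry(list(disc = list(enabled = TRUE, depth = 24.5,
                                       lateral_shift = 10)))
  starts <- rbind(c(-999, 0, 0), c(-500, 0, 0), c(-5, 0, 0), c(1, 0, 0),
                  c(20, 10, 0), c(26, 10, 0), c(29, 10, 0))
  for (i in seq_len(nrow(starts))) {
    p <- starts[i, ]
    dist <- distance_to_boundary(g, p, c(1, 0, 0))
    before <- locate(g, p + (dist - 1e-7) * c(1, 0, 0))$region
    expect_identical(before, locate(g, p)$region)
  }
})

test_that("disc pose transform round-trips to 1e-9 mm", {
  g <- build_geometry(list(disc = list(enabled = TRUE, depth = 24.5,
                                       lateral_shift = 12, tilt = 17)))
  set.seed(3)
  pts <- matrix(runif(60, -80, 80), ncol = 3)
  back <- disc_to_world(g, world_to_disc(g, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
  # disc centre maps to the local origin
  expect_lt(max(abs(world_to_disc(g, c(24.5 + 3, 12, 0)))), 1e-12)
})

test_that("geometry_components lists the beamline in order", {
  g <- build_geometry(list(disc = list(enabled = TRUE, depth = 24.5)))
  comps <- geometry_components(g)
  expect_identical(comps$component[1], "exit window")
  expect_true("shielding disc" %in% comps$component)
  expect_true(all(diff(comps$x0_mm) >= 0))
})
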