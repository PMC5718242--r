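# Synthetic fixture generator: analytic stand-ins for Monte Carlo output so
# every analysis operation is testable without transport. Generator
# parameters are the ground truth the analysis must recover.

#' Generate a synthetic fixture
#'
#' Kinds:
#' * `analytic_pdd`: electron-like depth-dose curve (sinusoidal build-up to
#'   R100, logistic distal falloff through R50 with the tangent-intercept at
#'   `rp`, flat bremsstrahlung tail of `tail_pct`). Params: `r100`, `r50`,
#'   `rp` (mm), `tail_pct`, `surface_pct`, `depth_max`, `step`; `output`
#'   `"curve"` (default) or `"grid"` (separable 3D grid with a flat lateral
#'   plateau of `width` mm).
#' * `flat_profile`: flat-top lateral profile. Params: `width` (50% full
#'   width, mm), `asymmetry_pct` (linear tilt, % at the plateau edge),
#'   `penumbra` (mm), `noise` (relative SD), `step`.
#' * `disc_leak`: 3D grid of uniform `background` with a Gaussian hot spot
#'   (amplitude `amp`, SD `sigma` mm) at `center` (x, y, z mm); dims from
#'   `dims`/`voxel`.
#' * `film_tophat`: circular top-hat film map. Params: `radius` (mm),
#'   `offset` (y, z mm), `size` (film half-width), `spacing`, `noise`.
#'
#' @param kind fixture kind.
#' @param params named list of parameters (see above).
#' @param seed RNG seed (noise is deterministic given the seed).
#' @return A `depth_dose_curve`, `lateral_profile`, `dose_grid` or
#'   `film_map` depending on the kind.
#' @export
generate_fixture <- function(kind = c("analytic_pdd", "flat_profile",
                                      "disc_leak", "film_tophat"),
                             params = list(), seed = 1) {
  kind <- match.arg(kind)
  .with_seed(seed, switch(kind,
    analytic_pdd = .fx_analytic_pdd(params),
    flat_profile = .fx_flat_profile(params),
    disc_leak = .fx_disc_leak(params),
    film_tophat = .fx_film_tophat(params)))
}

.fx_defaults <- function(params, defaults) {
  bad <- setdiff(names(params), names(defaults))
  if (length(bad)) stop("unknown fixture parameter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  modifyList(defaults, params)
}

.analytic_pdd_values <- function(x, p) {
  tail_lvl <- p$tail_pct
  # logistic falloff; the midpoint x50 is adjusted (fixed point) so that the
  # NORMALIZED curve crosses exactly 50% at r50 despite the tail offset and
  # the <100% maximum at r100
  slope <- (50 - tail_lvl) / (p$rp - p$r50) # % per mm at the inflection
  k <- 4 * slope / (100 - tail_lvl)
  x50 <- p$r50
  for (i in 1:6) {
    s_max <- 1 / (1 + exp(k * (p$r100 - x50)))
    dmax <- (100 - tail_lvl) * s_max + tail_lvl
    target <- (dmax / 2 - tail_lvl) / (100 - tail_lvl) # S(r50) needed
    target <- min(max(target, 1e-9), 1 - 1e-9)
    x50 <- p$r50 - log(1 / target - 1) / k
  }
  fall <- 1 / (1 + exp(k * (x - x50)))
  build <- ifelse(x < p$r100,
                  p$surface_pct / 100 +
                    (1 - p$surface_pct / 100) * sin(pi / 2 * x / p$r100)^2, 1)
  (100 - tail_lvl) * build * fall + tail_lvl
}

.fx_analytic_pdd <- function(params) {
  p <- .fx_defaults(params, list(r100 = 15, r50 = 34.8, rp = 45.2,
                                 tail_pct = 1.5, surface_pct = 80,
                                 depth_max = 70, step = 0.5, output = "curve",
                                 width = 100, dims = c(140, 100, 100),
                                 voxel = 0.5))
  if (!(p$r100 < p$r50 && p$r50 < p$rp)) {
    stop("analytic_pdd requires r100 < r50 < rp", call. = FALSE)
  }
  if (p$output == "curve") {
    x <- seq(p$step / 2, p$depth_max, by = p$step)
    return(depth_dose_curve(x, .analytic_pdd_values(x, p), aperture = NA))
  }
  dims <- as.integer(p$dims)
  x <- (seq_len(dims[1]) - 0.5) * p$voxel
  y <- (seq_len(dims[2]) - 0.5) * p$voxel - dims[2] * p$voxel / 2
  z <- (seq_len(dims[3]) - 0.5) * p$voxel - dims[3] * p$voxel / 2
  ax <- .analytic_pdd_values(x, p)
  lat_y <- 1 / (1 + exp((abs(y) - p$width / 2) / 2))
  lat_z <- 1 / (1 + exp((abs(z) - p$width / 2) / 2))
  vals <- outer(ax, outer(lat_y, lat_z))
  new_dose_grid(array(vals, dim = dims), voxel = p$voxel, n_histories = 1L)
}

.fx_flat_profile <- function(params) {
  p <- .fx_defaults(params, list(width = 102.5, asymmetry_pct = 0,
                                 penumbra = 3, noise = 0, step = 0.5,
                                 half_span = 75))
  y <- seq(-p$half_span + p$step / 2, p$half_span - p$step / 2, by = p$step)
  edge <- 1 / (1 + exp((abs(y) - p$width / 2) / (p$penumbra / 4)))
  tilt <- 1 + p$asymmetry_pct / 100 * (y / (p$width / 2))
  v <- 100 * edge * tilt
  if (p$noise > 0) v <- v * (1 + rnorm(length(v), 0, p$noise))
  lateral_profile(y, pmax(v, 0))
}

.fx_disc_leak <- function(params) {
  p <- .fx_defaults(params, list(background = 1, amp = 10, sigma = 2,
                                 center = c(45, 10, 0), dims = c(80, 60, 60),
                                 voxel = 0.5, noise = 0))
  dims <- as.integer(p$dims)
  x <- (seq_len(dims[1]) - 0.5) * p$voxel
  y <- (seq_len(dims[2]) - 0.5) * p$voxel - dims[2] * p$voxel / 2
  z <- (seq_len(dims[3]) - 0.5) * p$voxel - dims[3] * p$voxel / 2
  gx <- exp(-(x - p$center[1])^2 / (2 * p$sigma^2))
  gy <- exp(-(y - p$center[2])^2 / (2 * p$sigma^2))
  gz <- exp(-(z - p$center[3])^2 / (2 * p$sigma^2))
  vals <- p$background + p$amp * outer(gx, outer(gy, gz))
  if (p$noise > 0) vals <- vals * (1 + rnorm(length(vals), 0, p$noise))
  new_dose_grid(array(pmax(vals, 0), dim = dims), voxel = p$voxel,
                n_histories = 1L)
}

.fx_film_tophat <- function(params) {
  p <- .fx_defaults(params, list(radius = 40, offset = c(0, 0), size = 60,
                                 spacing = 0.5, noise = 0, beam_center = NULL))
  y <- seq(-p$size + p$spacing / 2, p$size - p$spacing / 2, by = p$spacing)
  z <- y
  # film centre at origin; dose spot offset by `offset` relative to it
  r2 <- outer((y - p$offset[1])^2, (z - p$offset[2])^2, "+")
  map <- ifelse(r2 <= p$radius^2, 100, 2)
  if (p$noise > 0) map <- map * (1 + rnorm(length(map), 0, p$noise))
  film_map(pmax(map, 0), y = y, z = z, center = c(0, 0), radius = p$size)
}
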