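# Dosimetric metrics: depth-dose and lateral-profile curves with reference
# parameters, beam-quality energies (TRS-398 / AAPM report 32 relations),
# shielding factor, backscattering factor, maximum leakage dose, cumulative
# dose-volume histograms, and the film-style misalignment estimate.

.grid_values <- function(grid) {
  if (inherits(grid, "iort_run")) grid$grid else grid
}

#' Extract a percentage depth-dose curve
#'
#' Per-depth mean deposited energy over a centred square aperture,
#' normalized to 100 at the maximum. A 2 mm aperture emulates a diode
#' detector; the full 150 mm aperture integrates the whole sensitive area.
#'
#' @param grid a `dose_grid` (or `iort_run`).
#' @param aperture transverse averaging square side in mm.
#' @return A `depth_dose_curve` with `depth` (mm), `percent`, and the
#'   unnormalized `raw` means.
#' @export
extract_pdd <- function(grid, aperture = 150) {
  grid <- .grid_values(grid)
  stopifnot(inherits(grid, "dose_grid"))
  co <- .grid_coords(grid)
  if (aperture > diff(range(co$y)) + grid$voxel) {
    stop("aperture larger than the detector width", call. = FALSE)
  }
  sely <- abs(co$y) <= aperture / 2
  selz <- abs(co$z) <= aperture / 2
  raw <- apply(grid$values[, sely, selz, drop = FALSE], 1, mean)
  if (all(raw == 0)) stop("all-zero grid: no depth-dose curve", call. = FALSE)
  # raw values are per history so paired curves with different history
  # counts share a common absolute basis (needed by the backscatter ratio)
  if (!is.na(grid$n_histories)) raw <- raw / grid$n_histories
  out <- list(depth = co$x, percent = 100 * raw / max(raw), raw = raw,
              aperture = aperture)
  class(out) <- "depth_dose_curve"
  out
}

#' Construct a depth-dose curve from vectors
#'
#' @param depth ascending depths in mm.
#' @param dose dose values (any scale; normalized internally).
#' @param aperture averaging aperture in mm (metadata).
#' @return A `depth_dose_curve`.
#' @export
depth_dose_curve <- function(depth, dose, aperture = NA_real_) {
  stopifnot(length(depth) == length(dose), all(diff(depth) > 0), all(dose >= 0))
  out <- list(depth = depth, percent = 100 * dose / max(dose), raw = dose,
              aperture = aperture)
  class(out) <- "depth_dose_curve"
  out
}

#' @export
print.depth_dose_curve <- function(x, ...) {
  cat(sprintf("<depth_dose_curve> %d depths [%g, %g] mm, aperture %g mm\n",
              length(x$depth), min(x$depth), max(x$depth), x$aperture))
  invisible(x)
}

#' @export
as.data.frame.depth_dose_curve <- function(x, ...) {
  data.frame(depth_mm = x$depth, percent_dose = x$percent)
}

.smooth3 <- function(v) {
  n <- length(v)
  if (n < 3) return(v)
  (c(v[1], v[-n]) + v + c(v[-1], v[n])) / 3
}

# centred running mean of odd width w with shrinking edge windows
.smooth_run <- function(v, w) {
  if (w <= 1) return(v)
  n <- length(v)
  h <- (w - 1) %/% 2
  vapply(seq_len(n), function(i) {
    mean(v[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

# distal crossing of `level` percent by linear interpolation
.distal_crossing <- function(depth, pct, imax, level) {
  idx <- which(pct[imax:length(pct)] <= level)
  if (!length(idx)) {
    stop(sprintf("depth-dose curve never falls to %g%% of maximum", level),
         call. = FALSE)
  }
  j <- imax + idx[1] - 1
  if (j == 1) return(depth[1])
  x0 <- depth[j - 1]; x1 <- depth[j]
  y0 <- pct[j - 1]; y1 <- pct[j]
  if (y0 == y1) return(x1)
  x0 + (y0 - level) / (y0 - y1) * (x1 - x0)
}

#' Depth-dose reference parameters
#'
#' R100 is the depth of maximum; Rx the distal depth where the curve crosses
#' x% of the maximum (linear interpolation); Rp the practical range: the
#' intercept of the tangent at the steepest distal point with the line
#' fitted through the bremsstrahlung tail (last 10% of depths).
#'
#' @param curve a `depth_dose_curve`.
#' @param smooth apply a centred moving average first (recommended for
#'   Monte Carlo curves; disable for analytic fixtures).
#' @param smooth_window odd width of the moving average in samples (3 by
#'   default; wider windows stabilise R100 on noisy flat plateaus).
#' @return A `pdd_reference_points` list with R100, R90, R50, R30, R10, Rp (mm).
#' @export
reference_points <- function(curve, smooth = TRUE, smooth_window = 3) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  pct <- if (smooth) .smooth_run(curve$percent, smooth_window) else curve$percent
  pct <- 100 * pct / max(pct)
  depth <- curve$depth
  imax <- which.max(pct)
  r100 <- depth[imax]
  rx <- vapply(c(90, 50, 30, 10), function(L)
    .distal_crossing(depth, pct, imax, L), numeric(1))

  # practical range: tangent at the steepest point of the distal falloff
  # (search restricted to the 80%..20% crossing window for noise immunity)
  r80 <- .distal_crossing(depth, pct, imax, 80)
  r20 <- .distal_crossing(depth, pct, imax, 20)
  distal <- which(depth >= r80 & depth <= r20)
  if (length(distal) < 2) distal <- imax:length(pct)
  slopes <- diff(pct[distal]) / diff(depth[distal])
  if (!length(slopes) || min(slopes) >= 0) {
    stop("no distal falloff: cannot extract Rp", call. = FALSE)
  }
  k <- which.min(slopes)
  m <- slopes[k]
  xs <- (depth[distal][k] + depth[distal][k + 1]) / 2
  ys <- (pct[distal][k] + pct[distal][k + 1]) / 2
  ntail <- max(3, ceiling(0.1 * length(depth)))
  ti <- seq(length(depth) - ntail + 1, length(depth))
  ty <- pct[ti]; tx <- depth[ti]
  keep <- ty <= max(3 * median(ty), median(ty) + 2) # drop rare photon spikes
  if (sum(keep) >= 2) { ty <- ty[keep]; tx <- tx[keep] }
  tail_fit <- lm(ty ~ tx)
  a <- coef(tail_fit)[1]; b <- coef(tail_fit)[2]
  if (!is.finite(b)) b <- 0
  if (b > 0) { b <- 0; a <- median(ty) } # tail must not rise
  rp <- (a - ys + m * xs) / (m - b)

  out <- list(R100 = r100, R90 = rx[1], R50 = rx[2], R30 = rx[3], R10 = rx[4],
              Rp = unname(rp))
  class(out) <- "pdd_reference_points"
  # Rp sits near (and for gentle sigmoids slightly proximal to) R10, so the
  # ordering check covers the crossing-based points only
  ord <- unlist(out)[1:5]
  if (any(diff(ord) < 0)) {
    warning("reference points are not strictly ordered: ",
            paste(sprintf("%s=%.2f", names(ord), ord), collapse = ", "))
  }
  out
}

#' @export
print.pdd_reference_points <- function(x, ...) {
  cat(sprintf("R100=%.2f R90=%.2f R50=%.2f R30=%.2f R10=%.2f Rp=%.2f mm\n",
              x$R100, x$R90, x$R50, x$R30, x$R10, x$Rp))
  invisible(x)
}

#' Mean electron energy at the phantom surface from R50
#'
#' TRS-398 relation: `E0bar = 2.33 * R50` with R50 in cm.
#'
#' @param r50 half-value depth in mm.
#' @return Mean energy in MeV.
#' @export
mean_energy_from_r50 <- function(r50) {
  if (any(r50 <= 0)) stop("R50 must be positive", call. = FALSE)
  2.33 * r50 / 10
}

#' Most probable electron energy at the phantom surface from Rp
#'
#' AAPM report 32 relation: `E0p = 0.22 + 1.98 Rp + 0.0025 Rp^2` with Rp in cm.
#'
#' @param rp practical range in mm.
#' @return Most probable energy in MeV.
#' @export
most_probable_energy_from_rp <- function(rp) {
  if (any(rp < 0)) stop("Rp must be non-negative", call. = FALSE)
  rp_cm <- rp / 10
  0.22 + 1.98 * rp_cm + 0.0025 * rp_cm^2
}

#' Extract a lateral dose profile at fixed depth
#'
#' Dose versus transverse offset at the given depth, averaged over a depth
#' slab of `slab` mm and a centred strip of width `strip` along the other
#' transverse axis, normalized to 100 on the central axis (plateau mean over
#' |offset| <= 5 mm, for statistical stability).
#'
#' @param grid a `dose_grid` (or `iort_run`).
#' @param depth depth in mm (must lie inside the detector).
#' @param axis `"y"` or `"z"`.
#' @param strip averaging strip width in mm along the other transverse axis.
#' @param slab depth averaging window in mm.
#' @return A `lateral_profile` with `offset` (mm), `percent`, `raw`.
#' @export
extract_profile <- function(grid, depth, axis = c("y", "z"), strip = 20,
                            slab = 2) {
  axis <- match.arg(axis)
  grid <- .grid_values(grid)
  co <- .grid_coords(grid)
  if (depth < min(co$x) - grid$voxel / 2 || depth > max(co$x) + grid$voxel / 2) {
    stop("depth outside the detector", call. = FALSE)
  }
  selx <- abs(co$x - depth) <= max(slab / 2, grid$voxel / 2)
  vol <- grid$values[selx, , , drop = FALSE]
  if (axis == "y") {
    sel <- abs(co$z) <= strip / 2
    raw <- apply(vol[, , sel, drop = FALSE], 2, mean)
    offset <- co$y
  } else {
    sel <- abs(co$y) <= strip / 2
    raw <- apply(vol[, sel, , drop = FALSE], 3, mean)
    offset <- co$z
  }
  if (all(raw == 0)) stop("all-zero slab: no profile", call. = FALSE)
  centre <- mean(raw[abs(offset) <= 5])
  if (!is.finite(centre) || centre <= 0) centre <- max(raw)
  out <- list(offset = offset, percent = 100 * raw / centre, raw = raw,
              depth = depth, axis = axis)
  class(out) <- "lateral_profile"
  out
}

#' Construct a lateral profile from vectors
#' @param offset ascending transverse offsets (mm).
#' @param dose dose values; normalized to the central axis.
#' @return A `lateral_profile`.
#' @export
lateral_profile <- function(offset, dose) {
  stopifnot(length(offset) == length(dose), all(diff(offset) > 0))
  centre <- mean(dose[which(rank(abs(offset), ties.method = "first") <= 2)])
  out <- list(offset = offset, percent = 100 * dose / centre, raw = dose,
              depth = NA_real_, axis = NA_character_)
  class(out) <- "lateral_profile"
  out
}

.profile_crossing <- function(offset, pct, level, side) {
  imax <- which.max(pct)
  if (side == "left") {
    idx <- rev(which(pct[1:imax] <= level))
    if (!length(idx)) stop("profile does not fall to 50% on the left side",
                           call. = FALSE)
    j <- idx[1]
    x0 <- offset[j]; x1 <- offset[j + 1]; y0 <- pct[j]; y1 <- pct[j + 1]
  } else {
    idx <- which(pct[imax:length(pct)] <= level)
    if (!length(idx)) stop("profile does not fall to 50% on the right side",
                           call. = FALSE)
    j <- imax + idx[1] - 1
    x0 <- offset[j - 1]; x1 <- offset[j]; y0 <- pct[j - 1]; y1 <- pct[j]
  }
  if (y0 == y1) return(x1)
  x0 + (y0 - level) / (y0 - y1) * (x1 - x0)
}

#' Lateral-profile metrics: field size, symmetry, homogeneity
#'
#' Field size is the distance between the 50% crossings. Within the
#' flattened region (|offset| <= 0.8 * field_size / 2), symmetry is
#' `100 * max over y of max(D(y), D(-y)) / min(D(y), D(-y))` and
#' homogeneity is `100 * Dmax / Dmin` (IEC-style ratio definitions).
#'
#' @param profile a `lateral_profile`.
#' @return A `profile_metrics` list: `field_size` (cm), `symmetry` (%),
#'   `homogeneity` (%).
#' @export
profile_metrics <- function(profile) {
  stopifnot(inherits(profile, "lateral_profile"))
  off <- profile$offset; pct <- profile$percent
  left <- .profile_crossing(off, pct, 50, "left")
  right <- .profile_crossing(off, pct, 50, "right")
  fs <- right - left
  flat <- 0.8 * fs / 2
  centre <- (left + right) / 2
  sel <- which(abs(off - centre) <= flat)
  if (length(sel) < 3) stop("flattened region too small", call. = FALSE)
  dmax <- max(pct[sel]); dmin <- min(pct[sel])
  homogeneity <- 100 * dmax / dmin
  pos <- off[off >= centre & (off - centre) <= flat]
  dplus <- approx(off, pct, xout = pos)$y
  dminus <- approx(off, pct, xout = 2 * centre - pos)$y
  ratio <- pmax(dplus, dminus) / pmin(dplus, dminus)
  symmetry <- 100 * max(ratio, na.rm = TRUE)
  out <- list(field_size = fs / 10, symmetry = symmetry,
              homogeneity = homogeneity)
  class(out) <- "profile_metrics"
  out
}

#' @export
print.profile_metrics <- function(x, ...) {
  cat(sprintf("field size %.2f cm, symmetry %.2f%%, homogeneity %.2f%%\n",
              x$field_size, x$symmetry, x$homogeneity))
  invisible(x)
}

#' Shielding factor
#'
#' `SF = 100 * (1 - Dd / Dnd)`: the percentage of normal-tissue dose removed
#' by the disc, from integrated doses over the identical normal-tissue
#' region with (`Dd`) and without (`Dnd`) the disc.
#'
#' @param dose_with_disc,dose_without_disc region integrals (same units).
#' @return SF in percent.
#' @export
shielding_factor <- function(dose_with_disc, dose_without_disc) {
  if (dose_without_disc <= 0) {
    stop("shielding factor undefined: reference dose Dnd is zero", call. = FALSE)
  }
  100 * (1 - dose_with_disc / dose_without_disc)
}

#' Backscattering factor
#'
#' Ratio of depth-dose values with and without the disc at the same depth,
#' proximal to the disc. Both curves are compared on their unnormalized
#' (`raw`) scale so the ratio reflects the absolute dose change; the with-
#' disc curve is interpolated onto the without-disc depth grid.
#'
#' @param pdd_with,pdd_without `depth_dose_curve`s from paired runs.
#' @param disc_depth proximal disc face depth in mm.
#' @param window depth window (mm) before the disc face over which
#'   `bsf_max` is taken.
#' @return list with `depth`, `bsf` (pointwise ratio proximal to the disc)
#'   and `bsf_max`.
#' @export
backscatter_factor <- function(pdd_with, pdd_without, disc_depth, window = 5) {
  stopifnot(inherits(pdd_with, "depth_dose_curve"),
            inherits(pdd_without, "depth_dose_curve"))
  if (is.null(pdd_with$raw) || is.null(pdd_without$raw)) {
    stop("backscatter factor needs unnormalized curves (shared basis)",
         call. = FALSE)
  }
  # exclude any depth bin partially covered by the disc (a straddling voxel
  # mixes dense in-disc deposits into the "proximal" dose)
  spacing <- median(diff(pdd_without$depth))
  sel <- pdd_without$depth <= disc_depth - spacing / 2
  if (!any(sel)) stop("no depths proximal to the disc", call. = FALSE)
  depth <- pdd_without$depth[sel]
  with_raw <- approx(pdd_with$depth, pdd_with$raw, xout = depth, rule = 2)$y
  ratio <- with_raw / pdd_without$raw[sel]
  near <- depth >= disc_depth - window
  if (!any(near)) near <- rep(TRUE, length(depth))
  list(depth = depth, bsf = ratio, bsf_max = max(ratio[near]))
}

#' Maximum leakage dose
#'
#' Maximum window-averaged dose over the normal-tissue region, scaled so the
#' axial dose at R100 equals the prescription. The averaging window is a
#' cube of side `window_mm` (default 1 mm, i.e. 2x2x2 voxels at 0.5 mm);
#' only windows fully inside the region count.
#'
#' @param dose 3D dose array (e.g. from [to_dose()]).
#' @param mask logical region array (normal tissue).
#' @param prescription prescribed dose in Gy at R100 (23 by default, 21 for
#'   the reduced protocol).
#' @param r100_axis_dose axial dose at R100 on the same scale as `dose`.
#' @param window_mm averaging cube side in mm.
#' @param voxel voxel size in mm.
#' @return MLD in Gy.
#' @export
max_leakage_dose <- function(dose, mask, prescription, r100_axis_dose,
                             window_mm = 1, voxel = 0.5) {
  if (r100_axis_dose <= 0) stop("R100 axis dose must be positive", call. = FALSE)
  if (!any(mask)) stop("empty normal-tissue region", call. = FALSE)
  w <- max(1L, as.integer(round(window_mm / voxel)))
  ws <- .window_sum(dose, w)
  wm <- .window_sum(mask + 0, w)
  valid <- wm >= w^3 - 1e-9
  if (!any(valid)) stop("region smaller than the averaging window", call. = FALSE)
  mld_rel <- max(ws[valid]) / w^3
  prescription / r100_axis_dose * mld_rel
}

#' Block-average a 3D grid
#'
#' Averages `f^3` blocks of voxels (dimensions are truncated to a multiple
#' of `f`).
#'
#' @param a 3D array.
#' @param f integer rebin factor.
#' @return 3D array of dimensions `floor(dim(a) / f)`.
#' @export
rebin_grid <- function(a, f) {
  f <- as.integer(f)
  stopifnot(f >= 1, length(dim(a)) == 3)
  if (f == 1) return(a)
  d <- dim(a) %/% f * f
  a <- a[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
  dim(a) <- c(f, d[1] %/% f, f, d[2] %/% f, f, d[3] %/% f)
  out <- apply(a, c(2, 4, 6), sum) / f^3
  out
}

# sum over all w^3 windows (anchor = lowest corner); returns array of
# dim(dims - w + 1)
.window_sum <- function(a, w) {
  d <- dim(a)
  out <- array(0, d - w + 1L)
  for (i in 0:(w - 1)) for (j in 0:(w - 1)) for (k in 0:(w - 1)) {
    out <- out + a[(1 + i):(d[1] - w + 1 + i),
                   (1 + j):(d[2] - w + 1 + j),
                   (1 + k):(d[3] - w + 1 + k), drop = FALSE]
  }
  out
}

#' Cumulative dose-volume histogram
#'
#' Fraction of the region receiving at least each dose level, plus the
#' underdosed fraction (share of the region below 80% of the region
#' maximum).
#'
#' @param dose 3D dose array.
#' @param mask logical region array.
#' @param n_bins number of dose levels.
#' @param plane `NULL` for the full volume, or `"z0"` to restrict to the
#'   central z plane (the 2D map convention used for tilt studies).
#' @param rebin integer block-averaging factor applied to dose and mask
#'   before the histogram (voxels of `rebin * voxel` per side). Monte Carlo
#'   grids at desk-scale statistics need `rebin >= 4` for a stable maximum;
#'   1 (no rebinning) is exact for analytic fixtures.
#' @param max_stat reference "maximum dose" for the underdosed fraction:
#'   `"max"` (literal, exact for analytic fixtures) or `"p98"` (98th
#'   percentile near-maximum, robust on noisy Monte Carlo grids).
#' @return list with `dose`, `volume_fraction` (non-increasing, starts at 1)
#'   and `underdosed_fraction_80` (percent).
#' @export
dvh <- function(dose, mask, n_bins = 200, plane = NULL, rebin = 1,
                max_stat = c("max", "p98")) {
  max_stat <- match.arg(max_stat)
  if (!any(mask)) stop("empty region for DVH", call. = FALSE)
  if (!is.null(plane)) {
    stopifnot(plane == "z0")
    kz <- ceiling(dim(dose)[3] / 2)
    sel <- array(FALSE, dim(dose)); sel[, , kz] <- TRUE
    mask <- mask & sel
  }
  if (rebin > 1) {
    dose <- rebin_grid(dose, rebin)
    # a coarse voxel belongs to the region if most of its children do
    mask <- rebin_grid(mask + 0, rebin) > 0.5
    if (!any(mask)) stop("empty region for DVH after rebinning", call. = FALSE)
  }
  vals <- dose[mask]
  dmax <- max(vals)
  if (dmax <= 0) stop("region receives no dose", call. = FALSE)
  dref <- if (max_stat == "max") dmax else unname(quantile(vals, 0.98))
  levels <- seq(0, dmax, length.out = n_bins)
  vf <- vapply(levels, function(L) mean(vals >= L), numeric(1))
  vf[1] <- 1
  list(dose = levels, volume_fraction = vf,
       underdosed_fraction_80 = 100 * mean(vals < 0.8 * dref))
}

#' Extract a simulated film map at the disc proximal face
#'
#' The film is the detector slice just up-beam of the disc proximal plane,
#' cropped to the disc footprint (the film is pasted on the disc and moves
#' with it).
#'
#' @param run an `iort_run` (or `dose_grid` plus an explicit geometry).
#' @param geometry optional `geometry_model` override.
#' @return A `film_map`: dose matrix over (y, z), axis coordinates, film
#'   centre in world coordinates, and half-width.
#' @export
extract_film <- function(run, geometry = NULL) {
  grid <- .grid_values(run)
  if (is.null(geometry)) geometry <- run$geometry
  stopifnot(inherits(geometry, "geometry_model"))
  d <- geometry$config$disc
  co <- .grid_coords(grid)
  ix <- max(1, floor(d$depth / grid$voxel))
  centre <- c(d$lateral_shift, 0)
  r <- d$diameter / 2
  sely <- abs(co$y - centre[1]) <= r
  selz <- abs(co$z - centre[2]) <= r
  film_map(grid$values[ix, sely, selz], y = co$y[sely], z = co$z[selz],
           center = centre, radius = r)
}

#' Construct a film map
#'
#' @param map dose matrix over (y, z).
#' @param y,z axis coordinates in mm.
#' @param center film-border centre (y, z) in mm.
#' @param radius film half-width in mm.
#' @return A `film_map`.
#' @export
film_map <- function(map, y, z, center = c(0, 0), radius = max(abs(y))) {
  stopifnot(is.matrix(map), nrow(map) == length(y), ncol(map) == length(z))
  f <- list(map = map, y = y, z = z, center = center, radius = radius)
  class(f) <- "film_map"
  f
}

#' Film-based disc misalignment estimate
#'
#' Thresholds the film at 50% of its (near-)maximum, takes the centroid of
#' the super-threshold region, and reports its distance from the film-border
#' centre, plus the equivalent-circle radius of the region.
#'
#' @param film a `film_map`.
#' @param rebin integer block-averaging factor applied to the film before
#'   thresholding (use >= 4 for noisy Monte Carlo films; 1 is exact for
#'   analytic films).
#' @param max_stat `"max"` (exact) or `"p99"` (99th-percentile reference,
#'   robust against isolated hot pixels on Monte Carlo films).
#' @return list with `offset_mm`, `centroid` (y, z, world mm), `radius_mm`.
#' @export
film_misalignment <- function(film, rebin = 1, max_stat = c("max", "p99")) {
  stopifnot(inherits(film, "film_map"))
  max_stat <- match.arg(max_stat)
  map <- film$map; yy <- film$y; zz <- film$z
  if (rebin > 1) {
    f <- as.integer(rebin)
    d <- dim(map) %/% f * f
    map <- map[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
    dim(map) <- c(f, d[1] %/% f, f, d[2] %/% f)
    map <- apply(map, c(2, 4), mean)
    yy <- colMeans(matrix(yy[seq_len(d[1])], f))
    zz <- colMeans(matrix(zz[seq_len(d[2])], f))
  }
  ref <- if (max_stat == "max") max(map) else unname(quantile(map, 0.99))
  if (ref <= 0) stop("no 50% isodose region on the film", call. = FALSE)
  sel <- map >= 0.5 * ref
  if (!any(sel)) stop("no 50% isodose region on the film", call. = FALSE)
  idx <- which(sel, arr.ind = TRUE)
  centroid <- c(mean(yy[idx[, 1]]), mean(zz[idx[, 2]]))
  dy <- diff(yy[1:2]); dz <- diff(zz[1:2])
  area <- nrow(idx) * dy * dz
  list(offset_mm = sqrt(sum((centroid - film$center)^2)),
       centroid = centroid, radius_mm = sqrt(area / pi))
}
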