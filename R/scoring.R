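# Voxelized energy scoring, dose conversion, batch uncertainty and region
# integrals. The grid covers the sensitive detector (default 70 x 150 x 150
# mm at 0.5 mm isotropic voxels), origin at the phantom-surface centre,
# half-open voxel intervals, centres at (i + 0.5) * voxel.

MEV_TO_J <- 1.602176634e-13

#' Construct a voxel dose grid
#'
#' @param values 3D array of deposited energy (MeV) per voxel (totals over
#'   all histories).
#' @param voxel isotropic voxel size in mm.
#' @param n_histories number of histories the totals refer to.
#' @param n_batches number of statistically independent batches.
#' @param batch_sumsq 3D array of per-batch sums of squares (for
#'   uncertainty), or NULL.
#' @param outside energy (MeV) deposited inside the world but outside the
#'   detector; `escaped` energy that left the world; `injected` total source
#'   energy.
#' @param escaped,injected see `outside`.
#' @return A `dose_grid`.
#' @export
new_dose_grid <- function(values, voxel, n_histories = NA_integer_,
                          n_batches = 1L, batch_sumsq = NULL, outside = 0,
                          escaped = 0, injected = NA_real_) {
  stopifnot(is.array(values), length(dim(values)) == 3, voxel > 0)
  if (any(values < 0)) stop("negative energy in dose grid", call. = FALSE)
  g <- list(values = values, voxel = voxel,
            origin = c(0, -dim(values)[2] * voxel / 2, -dim(values)[3] * voxel / 2),
            dims = dim(values), n_histories = n_histories,
            n_batches = n_batches, batch_sumsq = batch_sumsq,
            outside = outside, escaped = escaped, injected = injected)
  class(g) <- "dose_grid"
  g
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %d x %d x %d voxels @ %.3g mm; total %.4g MeV (%s histories, %d batches)\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel, sum(x$values),
              format(x$n_histories), x$n_batches))
  invisible(x)
}

# voxel centre coordinate vectors
.grid_coords <- function(grid) {
  list(x = (seq_len(grid$dims[1]) - 0.5) * grid$voxel + grid$origin[1],
       y = (seq_len(grid$dims[2]) - 0.5) * grid$voxel + grid$origin[2],
       z = (seq_len(grid$dims[3]) - 0.5) * grid$voxel + grid$origin[3])
}

#' Deposit energy into a grid (scoring primitive)
#'
#' Adds `energy` to the voxel containing `position` (half-open bins: a point
#' exactly on a voxel face belongs to the higher-index voxel). Positions
#' outside the detector increment the outside tally instead.
#'
#' @param grid a `dose_grid`.
#' @param position xyz in mm.
#' @param energy deposited energy in MeV (must be >= 0).
#' @return the updated `dose_grid`.
#' @export
deposit <- function(grid, position, energy) {
  stopifnot(inherits(grid, "dose_grid"))
  if (energy < 0) stop("negative energy deposit", call. = FALSE)
  idx <- floor((position - grid$origin) / grid$voxel) + 1
  if (all(idx >= 1) && all(idx <= grid$dims)) {
    grid$values[idx[1], idx[2], idx[3]] <- grid$values[idx[1], idx[2], idx[3]] + energy
  } else {
    grid$outside <- grid$outside + energy
  }
  grid
}

#' Convert deposited energy to absorbed dose
#'
#' Dose = energy / voxel mass, with the mass from the material at the voxel
#' centre (water everywhere unless a geometry with the disc enabled is
#' given). Returned values are Gy per history when `n_histories` is known,
#' otherwise Gy-total.
#'
#' @param grid a `dose_grid`.
#' @param geometry optional `geometry_model` for the density map.
#' @param per_history divide by the number of histories (default TRUE when
#'   known).
#' @return 3D array of dose values (Gy).
#' @export
to_dose <- function(grid, geometry = NULL, per_history = !is.na(grid$n_histories)) {
  rho <- .density_array(grid, geometry)
  if (any(rho <= 0, na.rm = TRUE)) stop("zero density in dose conversion", call. = FALSE)
  vox_cm3 <- (grid$voxel / 10)^3
  mass_kg <- rho * vox_cm3 / 1000
  dose <- grid$values * MEV_TO_J / mass_kg
  if (per_history) dose <- dose / grid$n_histories
  dose
}

.density_array <- function(grid, geometry) {
  if (is.null(geometry) || !geometry$disc_enabled) {
    return(array(get_material("water")$density, dim = grid$dims))
  }
  rho_by_region <- vapply(.region_materials, function(m) get_material(m)$density,
                          numeric(1))
  gs <- list(nx = grid$dims[1], ny = grid$dims[2], nz = grid$dims[3],
             voxel = grid$voxel)
  array(cpp_density_map(geometry, gs, unname(rho_by_region)), dim = grid$dims)
}

#' Define an analysis region
#'
#' Regions are predicates over voxel centres, fixed by the reference
#' (nominal, untilted) disc pose so that with/without-disc pairs integrate
#' over identical volumes:
#' * `treatment_zone`: cylinder of the collimator radius from the phantom
#'   surface to the disc proximal plane;
#' * `normal_tissue`: every detector voxel distal to the disc distal plane;
#' * `axis_aperture`: square column of side `aperture` centred on the axis.
#'
#' @param kind one of `"treatment_zone"`, `"normal_tissue"`, `"axis_aperture"`.
#' @param geometry a `geometry_model` (its config disc block supplies the
#'   reference pose even when the disc is disabled).
#' @param aperture side of the axis aperture square in mm.
#' @return A `region_spec`.
#' @export
region_spec <- function(kind = c("treatment_zone", "normal_tissue", "axis_aperture"),
                        geometry, aperture = 20) {
  kind <- match.arg(kind)
  stopifnot(inherits(geometry, "geometry_model"))
  d <- geometry$config$disc
  r <- list(kind = kind,
            disc_proximal = d$depth,
            disc_distal = d$depth + d$al_thickness + d$pb_thickness,
            collimator_radius = geometry$collimator_inner_diameter / 2,
            aperture = aperture)
  class(r) <- "region_spec"
  r
}

#' Logical mask of a region over a grid
#'
#' @param grid a `dose_grid`.
#' @param region a `region_spec`.
#' @return logical 3D array.
#' @export
region_mask <- function(grid, region) {
  stopifnot(inherits(grid, "dose_grid"), inherits(region, "region_spec"))
  co <- .grid_coords(grid)
  switch(region$kind,
    treatment_zone = {
      rad <- outer(co$y^2, co$z^2, "+") <= region$collimator_radius^2
      outer(co$x < region$disc_proximal, rad, "&")
    },
    normal_tissue = {
      array(co$x > region$disc_distal, dim = grid$dims)
    },
    axis_aperture = {
      a <- region$aperture / 2
      lat <- outer(abs(co$y) <= a, abs(co$z) <= a, "&")
      outer(rep(TRUE, grid$dims[1]), lat, "&")
    })
}

#' Integrated energy or dose over a region
#'
#' The Dd / Dnd integrand of the shielding factor: by default the sum of
#' deposited energy over the region (proportional to the integrated dose in
#' homogeneous water).
#'
#' @param grid a `dose_grid`.
#' @param region a `region_spec` (or a logical mask array).
#' @param what `"energy"` (MeV, default) or `"dose"` (Gy, water-equivalent).
#' @param geometry optional geometry for dose conversion.
#' @return scalar sum.
#' @export
region_dose <- function(grid, region, what = c("energy", "dose"),
                        geometry = NULL) {
  what <- match.arg(what)
  mask <- if (is.array(region)) region else region_mask(grid, region)
  if (!any(mask)) stop("empty analysis region", call. = FALSE)
  vals <- if (what == "energy") grid$values else to_dose(grid, geometry)
  sum(vals[mask])
}

#' Per-voxel relative batch uncertainty
#'
#' Standard error of the per-batch means divided by the mean, per voxel.
#' Voxels with zero mean are returned as NA.
#'
#' @param grid a `dose_grid` with at least two batches and batch sums of
#'   squares.
#' @return 3D array of relative standard errors.
#' @export
batch_uncertainty <- function(grid) {
  stopifnot(inherits(grid, "dose_grid"))
  B <- grid$n_batches
  if (B < 2 || is.null(grid$batch_sumsq)) {
    stop("batch uncertainty requires >= 2 batches with recorded sums of squares",
         call. = FALSE)
  }
  tot <- grid$values
  varb <- (grid$batch_sumsq - tot^2 / B) / (B - 1)
  varb[varb < 0] <- 0 # numerical noise
  se <- sqrt(varb / B)
  rel <- se / (tot / B)
  rel[tot <= 0] <- NA_real_
  rel
}
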