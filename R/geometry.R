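# Beamline geometry: titanium exit window, PMMA head / secondary collimator
# cylinders, water phantom, optional Al-Pb shielding disc under arbitrary
# pose. Coordinates: x = beam axis (0 at the phantom surface, positive
# downstream, source plane at x = -SSD); y, z transverse.

.region_labels <- c("air gap", "window", "PMMA", "water", "disc-Al", "disc-Pb")
.region_materials <- c("air", "titanium", "pmma", "water", "aluminum", "lead")

#' Build the simulated beamline geometry
#'
#' @param config a (possibly partial) run configuration; see
#'   [default_config()]. The `[disc]` block supplies the pose; with
#'   `enabled = false` the phantom is homogeneous water but the reference
#'   pose still defines the analysis region planes.
#' @return A `geometry_model`.
#' @export
build_geometry <- function(config = list()) {
  cfg <- validate_config(config)
  g <- cfg$geometry
  d <- cfg$disc
  ssd <- g$ssd
  win_x0 <- -ssd
  win_x1 <- -ssd + g$window_thickness
  collim_r <- g$collimator_inner_diameter / 2
  cyl <- rbind(
    c(g$head_x0, g$head_x1, g$head_inner_radius, g$head_inner_radius + g$head_wall),
    c(g$collimator_x0, g$collimator_x1, collim_r, collim_r + g$collimator_wall))
  colnames(cyl) <- c("x0", "x1", "rin", "rout")
  if (win_x1 > cyl[1, "x0"] || cyl[1, "x1"] > cyl[2, "x0"] || cyl[2, "x1"] > 0) {
    stop("geometry components overlap along the beam axis", call. = FALSE)
  }
  ph_depth <- 200; ph_half <- 100
  h <- d$al_thickness + d$pb_thickness
  if (d$enabled) {
    # lateral protrusion is tolerated (the disc is truncated at the phantom
    # wall, far outside the detector); the axial extent and centre must fit
    if (d$depth < 0 || d$depth + h > ph_depth ||
        abs(d$lateral_shift) > ph_half) {
      stop("disc does not fit inside the phantom at this pose", call. = FALSE)
    }
  }
  model <- list(
    ssd = ssd,
    collimator_inner_diameter = g$collimator_inner_diameter,
    win_x0 = win_x0, win_x1 = win_x1, win_r = g$window_radius,
    cylinders = cyl,
    phantom_depth = ph_depth, phantom_half = ph_half,
    world_x0 = win_x0 - 10, world_x1 = ph_depth,
    world_half_y = 160, world_half_z = 160,
    disc_enabled = d$enabled,
    disc_depth = d$depth, disc_shift = d$lateral_shift,
    disc_tilt_rad = d$tilt * pi / 180, disc_flipped = d$flipped,
    disc_al = d$al_thickness, disc_pb = d$pb_thickness,
    disc_radius = d$diameter / 2,
    config = cfg)
  class(model) <- "geometry_model"
  model
}

#' @export
print.geometry_model <- function(x, ...) {
  cat(sprintf("<geometry_model> SSD %g mm, collimator %g mm, phantom %gx%gx%g mm\n",
              x$ssd, x$collimator_inner_diameter, x$phantom_depth,
              2 * x$phantom_half, 2 * x$phantom_half))
  if (x$disc_enabled) {
    cat(sprintf("  disc: depth %g mm, shift %g mm, tilt %g deg, %s\n",
                x$disc_depth, x$disc_shift, x$disc_tilt_rad * 180 / pi,
                if (x$disc_flipped) "flipped (Pb face up-beam)" else "Al face up-beam"))
  } else cat("  disc: absent (homogeneous water phantom)\n")
  invisible(x)
}

#' Component table of a geometry model
#'
#' @param model a `geometry_model`.
#' @return data.frame of components (axial extents, radii, materials).
#' @export
geometry_components <- function(model) {
  stopifnot(inherits(model, "geometry_model"))
  comps <- data.frame(
    component = c("exit window", "head cylinder", "secondary collimator",
                  "water phantom"),
    material = c("titanium", "pmma", "pmma", "water"),
    x0_mm = c(model$win_x0, model$cylinders[1, "x0"], model$cylinders[2, "x0"], 0),
    x1_mm = c(model$win_x1, model$cylinders[1, "x1"], model$cylinders[2, "x1"],
              model$phantom_depth),
    rin_mm = c(0, model$cylinders[, "rin"], NA),
    rout_mm = c(model$win_r, model$cylinders[, "rout"], NA))
  if (model$disc_enabled) {
    comps <- rbind(comps, data.frame(
      component = "shielding disc", material = "aluminum+lead",
      x0_mm = model$disc_depth,
      x1_mm = model$disc_depth + model$disc_al + model$disc_pb,
      rin_mm = 0, rout_mm = model$disc_radius))
  }
  comps
}

#' Classify a point into a geometry region
#'
#' @param model a `geometry_model`.
#' @param point numeric xyz in mm.
#' @return list with `region` (one of air gap, window, PMMA, water, disc-Al,
#'   disc-Pb, outside) and `material` (a `material` record, or NULL outside).
#' @export
locate <- function(model, point) {
  stopifnot(inherits(model, "geometry_model"), length(point) == 3,
            all(is.finite(point)))
  reg <- cpp_locate(model, as.numeric(point))
  if (reg < 0) return(list(region = "outside", material = NULL))
  list(region = .region_labels[reg + 1],
       material = get_material(.region_materials[reg + 1]))
}

#' Exact distance to the nearest material boundary along a ray
#'
#' @param model a `geometry_model`.
#' @param point numeric xyz in mm (must be inside the world volume).
#' @param direction unit vector.
#' @return distance in mm.
#' @export
distance_to_boundary <- function(model, point, direction) {
  stopifnot(inherits(model, "geometry_model"), length(direction) == 3)
  n <- sqrt(sum(direction^2))
  if (abs(n - 1) > 1e-6) stop("direction must be a unit vector", call. = FALSE)
  cpp_distance_to_boundary(model, as.numeric(point), as.numeric(direction))
}

#' Disc pose coordinate transforms
#'
#' `world_to_disc()` maps world points into the disc-local frame (x along the
#' disc normal, origin at the disc centre); `disc_to_world()` is its inverse.
#'
#' @param model a `geometry_model` with the disc enabled.
#' @param points numeric vector xyz or an n x 3 matrix.
#' @return points in the other frame, same shape as the input.
#' @export
world_to_disc <- function(model, points) {
  .pose_xform(model, points, inverse = FALSE)
}

#' @rdname world_to_disc
#' @export
disc_to_world <- function(model, points) {
  .pose_xform(model, points, inverse = TRUE)
}

.pose_xform <- function(model, points, inverse) {
  stopifnot(inherits(model, "geometry_model"))
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  h <- model$disc_al + model$disc_pb
  centre <- c(model$disc_depth + h / 2, model$disc_shift, 0)
  t <- model$disc_tilt_rad
  R <- rbind(c(cos(t), sin(t), 0), c(-sin(t), cos(t), 0), c(0, 0, 1))
  out <- if (!inverse) {
    sweep(pts, 2, centre) %*% t(R)
  } else {
    sweep(pts %*% R, 2, centre, FUN = "+")
  }
  if (is.matrix(points)) out else drop(out)
}

# Engine-facing helpers: material tables in region order and settings list.
.engine_materials <- function(settings) {
  mats <- lapply(.region_materials, get_material)
  .build_material_tables(mats, settings)
}

.engine_settings <- function(cfg) {
  list(max_fractional_eloss = cfg$transport$max_fractional_eloss,
       push = 1e-5, brems_kcut = 0.05,
       brems = cfg$transport$brems, straggling = cfg$transport$straggling,
       scatter = cfg$transport$scatter, max_step = cfg$transport$max_step)
}

.engine_grid <- function(cfg) {
  dims <- as.integer(round(cfg$scoring$detector / cfg$scoring$voxel_size))
  list(nx = dims[1], ny = dims[2], nz = dims[3], voxel = cfg$scoring$voxel_size)
}
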