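# Run configuration: strict schema with explicit defaults, round-trippable
# through a small TOML-subset dialect ([section], key = value; numbers,
# booleans, quoted strings and flat arrays). Unknown keys are rejected.

#' Default run configuration
#'
#' Returns the fully materialized default configuration: Gaussian source at
#' the exit window, SSD 1000 mm, 100 mm collimator, 0.5 mm isotropic scoring
#' voxels over the 70 x 150 x 150 mm detector, Al(4)/Pb(2) 120 mm disc pose
#' block (disabled by default; its depth still defines the treatment /
#' normal-tissue region planes).
#'
#' @return A `run_config` list.
#' @export
default_config <- function() {
  cfg <- list(
    seed = 1L,
    source = list(
      preset = "", mean_energy = 10.1, sigma_e = 0.5, sigma_y = 1.0,
      sigma_z = 1.0, sigma_m = 6.0, n_histories = 20000),
    geometry = list(
      ssd = 1000, collimator_inner_diameter = 100,
      window_thickness = 0.06, window_radius = 40,
      head_x0 = -995, head_x1 = -900, head_inner_radius = 40, head_wall = 10,
      collimator_x0 = -900, collimator_x1 = -2, collimator_wall = 7),
    disc = list(
      enabled = FALSE, depth = 24.5, lateral_shift = 0, tilt = 0,
      flipped = FALSE, al_thickness = 4, pb_thickness = 2, diameter = 120),
    transport = list(
      max_step = 0.25, max_fractional_eloss = 0.05, brems = TRUE,
      straggling = TRUE, scatter = TRUE, batches = 10L),
    scoring = list(voxel_size = 0.5, detector = c(70, 150, 150)),
    analysis = list(aperture = 150, prescription = 23))
  class(cfg) <- "run_config"
  cfg
}

# Table 3 source presets (mean energy, energy/position/angular spreads).
.source_presets <- function() {
  list(
    "10MeV" = list(mean_energy = 10.1, sigma_e = 0.5, sigma_y = 1.0,
                   sigma_z = 1.0, sigma_m = 6.0),
    "8MeV" = list(mean_energy = 8.3, sigma_e = 0.5, sigma_y = 1.0,
                  sigma_z = 1.0, sigma_m = 6.0),
    "6MeV" = list(mean_energy = 6.3, sigma_e = 0.5, sigma_y = 1.0,
                  sigma_z = 1.0, sigma_m = 6.0),
    "4MeV" = list(mean_energy = 4.8, sigma_e = 0.5, sigma_y = 1.0,
                  sigma_z = 1.0, sigma_m = 6.0))
}

#' Source presets matching the tuned beam models
#'
#' @param name one of `"10MeV"`, `"8MeV"`, `"6MeV"`, `"4MeV"`.
#' @return Named list of Gaussian source parameters.
#' @export
source_preset <- function(name) {
  p <- .source_presets()[[name]]
  if (is.null(p)) {
    stop(sprintf("unknown source preset '%s'; available: %s", name,
                 paste(names(.source_presets()), collapse = ", ")),
         call. = FALSE)
  }
  p
}

#' Validate and materialize a (possibly partial) configuration
#'
#' Merges user values over [default_config()], applies any source preset,
#' rejects unknown keys and checks invariants (positive dimensions, disc
#' wider than the collimator, detector extent commensurate with the voxel
#' size, |tilt| <= 90 degrees).
#'
#' @param cfg named list of configuration sections.
#' @return A validated `run_config`.
#' @export
validate_config <- function(cfg = list()) {
  def <- unclass(default_config())
  cfg <- unclass(cfg)
  bad <- setdiff(names(cfg), names(def))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (sec in names(cfg)) {
    if (sec == "seed") next
    bad <- setdiff(names(cfg[[sec]]), names(def[[sec]]))
    if (length(bad)) {
      stop(sprintf("unknown key(s) in [%s]: %s", sec, paste(bad, collapse = ", ")),
           call. = FALSE)
    }
  }
  out <- modifyList(def, cfg)
  if (nzchar(out$source$preset)) {
    out$source <- modifyList(out$source, source_preset(out$source$preset))
  }
  s <- out$source
  if (s$mean_energy <= 0 || s$sigma_e < 0 || s$sigma_y < 0 || s$sigma_z < 0 ||
      s$sigma_m < 0 || out$source$n_histories < 1) {
    stop("invalid [source]: mean_energy > 0, sigmas >= 0, n_histories >= 1",
         call. = FALSE)
  }
  d <- out$disc
  if (d$al_thickness <= 0 || d$pb_thickness <= 0 || d$diameter <= 0)
    stop("invalid [disc]: thicknesses and diameter must be positive", call. = FALSE)
  if (abs(d$tilt) > 90) stop("invalid [disc]: |tilt| must be <= 90 degrees",
                             call. = FALSE)
  if (d$diameter <= out$geometry$collimator_inner_diameter) {
    stop(sprintf("disc diameter (%g mm) must exceed the collimator inner diameter (%g mm)",
                 d$diameter, out$geometry$collimator_inner_diameter), call. = FALSE)
  }
  sc <- out$scoring
  if (sc$voxel_size <= 0) stop("invalid [scoring]: voxel_size must be positive",
                               call. = FALSE)
  dims <- sc$detector / sc$voxel_size
  if (any(abs(dims - round(dims)) > 1e-9)) {
    stop("detector extent must be an integer number of voxels", call. = FALSE)
  }
  tr <- out$transport
  if (tr$max_step <= 0 || tr$max_fractional_eloss <= 0 ||
      tr$max_fractional_eloss >= 1 || tr$batches < 1) {
    stop("invalid [transport] settings", call. = FALSE)
  }
  out$seed <- as.integer(out$seed)
  out$transport$batches <- as.integer(out$transport$batches)
  out$source$n_histories <- as.integer(out$source$n_histories)
  class(out) <- "run_config"
  out
}

.parse_toml_value <- function(txt, where) {
  txt <- trimws(txt)
  if (txt %in% c("true", "false")) return(txt == "true")
  if (grepl('^".*"$', txt)) return(gsub('^"|"$', "", txt))
  if (grepl("^\\[.*\\]$", txt)) {
    inner <- trimws(gsub("^\\[|\\]$", "", txt))
    if (!nzchar(inner)) return(numeric(0))
    parts <- trimws(strsplit(inner, ",")[[1]])
    return(vapply(parts, function(p) .parse_toml_value(p, where), numeric(1),
                  USE.NAMES = FALSE))
  }
  val <- suppressWarnings(as.numeric(txt))
  if (is.na(val)) stop(sprintf("cannot parse value '%s' at %s", txt, where),
                       call. = FALSE)
  val
}

#' Read a run configuration file
#'
#' Parses the package's TOML-subset dialect and returns a fully validated
#' configuration with all defaults materialized.
#'
#' @param path path to the config file.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  cfg <- list()
  section <- NULL
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    where <- sprintf("%s:%d", path, i)
    if (grepl("^\\[[^]]+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(cfg[[section]])) cfg[[section]] <- list()
      next
    }
    if (!grepl("=", ln, fixed = TRUE)) stop("expected 'key = value' at ", where,
                                            call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- .parse_toml_value(sub("^[^=]*=", "", ln), where)
    if (is.null(section)) {
      cfg[[key]] <- val
    } else {
      cfg[[section]][[key]] <- val
    }
  }
  validate_config(cfg)
}

.format_toml_value <- function(v) {
  if (is.character(v)) return(sprintf('"%s"', v))
  if (is.logical(v)) return(if (v) "true" else "false")
  if (length(v) > 1) return(sprintf("[%s]", paste(format(v, digits = 15), collapse = ", ")))
  format(v, digits = 15)
}

#' Write a run configuration file
#'
#' @param cfg a `run_config` (validated first).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  out <- c(sprintf("seed = %d", cfg$seed))
  for (sec in setdiff(names(cfg), "seed")) {
    out <- c(out, "", sprintf("[%s]", sec))
    for (key in names(cfg[[sec]])) {
      out <- c(out, sprintf("%s = %s", key, .format_toml_value(cfg[[sec]][[key]])))
    }
  }
  writeLines(out, path)
  invisible(path)
}
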