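# Class-I condensed-history transport driver. Electrons lose energy
# continuously (Bethe collision + radiative term, optional Bohr straggling
# sampled from a matched-moment Gamma), scatter through Gaussian polar
# angles of SD given by Highland's formula, and emit discrete forward
# bremsstrahlung photons from the 1/k spectrum at a rate reproducing the
# radiative stopping power above a 50 keV emission cutoff; photons travel in
# single exponential flights and deposit on interaction (kerma
# approximation). Step length = min(material step cap, boundary distance,
# 5% fractional energy loss).

#' Particle state constructor
#'
#' @param kind `"electron"` or `"photon"`.
#' @param position xyz in mm.
#' @param direction unit vector.
#' @param energy kinetic energy in MeV.
#' @param alive logical.
#' @return A `particle_state`.
#' @export
particle_state <- function(kind = c("electron", "photon"), position, direction,
                           energy, alive = TRUE) {
  kind <- match.arg(kind)
  n <- sqrt(sum(direction^2))
  if (abs(n - 1) > 1e-9) stop("direction must be a unit vector", call. = FALSE)
  stopifnot(energy >= 0)
  s <- list(kind = kind, position = as.numeric(position),
            direction = as.numeric(direction), energy = energy, alive = alive)
  class(s) <- "particle_state"
  s
}

.step_args <- function(config) {
  cfg <- validate_config(config)
  geom <- build_geometry(cfg)
  settings <- .engine_settings(cfg)
  list(cfg = cfg, geom = geom, settings = settings,
       mats = .engine_materials(settings), grid = .engine_grid(cfg))
}

#' Advance an electron by one condensed-history step
#'
#' Exposes the engine's single-step kernel for testing and inspection: the
#' same compiled code path used by [run_simulation()].
#'
#' @param state a `particle_state` (electron).
#' @param config run configuration (geometry, transport settings).
#' @param seed RNG seed for this step.
#' @return list with the updated `state`, `deposited` energy (MeV),
#'   `escaped` energy, `step_mm`, and `photon` (a `particle_state` or NULL).
#' @export
step_electron <- function(state, config = list(), seed = 1) {
  stopifnot(inherits(state, "particle_state"), state$kind == "electron",
            state$alive)
  if (any(!is.finite(state$position)) || !is.finite(state$energy)) {
    stop("non-finite particle state: ", paste(state$position, collapse = ","),
         " E=", state$energy, call. = FALSE)
  }
  a <- .step_args(config)
  res <- cpp_step_electron(c(state$energy, state$position, state$direction),
                           a$geom, a$mats, a$settings, a$grid, seed)
  new_state <- particle_state("electron", res$position, res$direction,
                              max(res$energy, 0), alive = res$alive)
  photon <- NULL
  if (length(res$photon)) {
    photon <- particle_state("photon", res$photon$position,
                             res$photon$direction, res$photon$energy)
  }
  list(state = new_state, deposited = res$deposited, escaped = res$escaped,
       step_mm = res$step_mm, photon = photon)
}

#' Transport a photon to absorption or escape
#'
#' Samples the free path from the local exponential attenuation and deposits
#' the full energy at the interaction point (kerma approximation); escape
#' through the world boundary terminates without deposit.
#'
#' @inheritParams step_electron
#' @return list with `deposited_grid`, `deposited_outside`, `escaped`
#'   energies (MeV) and `deposit_voxel_center`.
#' @export
step_photon <- function(state, config = list(), seed = 1) {
  stopifnot(inherits(state, "particle_state"), state$kind == "photon")
  a <- .step_args(config)
  cpp_step_photon(c(state$energy, state$position, state$direction),
                  a$geom, a$mats, a$settings, a$grid, seed)
}

#' Run a full Monte Carlo simulation
#'
#' Samples primaries from the configured Gaussian source, transports all
#' electrons and secondary photons to cutoff or escape, and returns the
#' scored energy grid plus run statistics. Deterministic for a fixed seed
#' (single-threaded engine; per-batch RNG streams).
#'
#' @param config run configuration (see [default_config()]); may be a path
#'   to a config file.
#' @param n_histories optional override of `source$n_histories`.
#' @param seed optional override of the config seed.
#' @param primaries optional explicit primaries matrix (columns energy, x,
#'   y, z, dx, dy, dz) bypassing the source model; used for controlled
#'   transport experiments.
#' @return An `iort_run` list: `grid` (a `dose_grid`), `stats`, `geometry`,
#'   `config`.
#' @export
run_simulation <- function(config = list(), n_histories = NULL, seed = NULL,
                           primaries = NULL) {
  cfg <- if (is.character(config)) read_config(config) else validate_config(config)
  if (!is.null(n_histories)) cfg$source$n_histories <- as.integer(n_histories)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  geom <- build_geometry(cfg)
  settings <- .engine_settings(cfg)
  mats <- .engine_materials(settings)
  grid_spec <- .engine_grid(cfg)

  if (is.null(primaries)) {
    src <- beam_source(cfg$source$mean_energy, cfg$source$sigma_e,
                       cfg$source$sigma_y, cfg$source$sigma_z, cfg$source$sigma_m,
                       cfg$source$n_histories, cfg$seed)
    n <- cfg$source$n_histories
    prim <- sample_primaries(src, n, seed = cfg$seed,
                             source_x = geom$win_x0 - 1e-3,
                             energy_floor = get_material("air")$electron_energy_cutoff / 1000)
  } else {
    prim <- primaries
    n <- nrow(prim)
    cfg$source$n_histories <- as.integer(n)
  }
  nb <- min(cfg$transport$batches, n)
  batch <- sort(rep_len(seq_len(nb), n))

  res <- cpp_run_engine(prim, as.integer(batch), geom, mats, settings,
                        grid_spec, as.double(cfg$seed))

  dims <- c(grid_spec$nx, grid_spec$ny, grid_spec$nz)
  grid <- new_dose_grid(array(res$energy, dim = dims), grid_spec$voxel,
                        n_histories = n, n_batches = res$n_batches,
                        batch_sumsq = array(res$batch_sumsq, dim = dims),
                        outside = res$outside, escaped = res$escaped,
                        injected = res$injected)
  stats <- list(injected_mev = res$injected, deposited_mev = res$deposited,
                escaped_mev = res$escaped, outside_mev = res$outside,
                grid_mev = res$deposited - res$outside,
                energy_balance = (res$injected - res$deposited - res$escaped) /
                  max(res$injected, .Machine$double.eps),
                mean_primary_path_mm = res$primary_path_mm / n,
                n_histories = n, n_batches = res$n_batches, seed = cfg$seed)
  out <- list(grid = grid, stats = stats, geometry = geom, config = cfg)
  class(out) <- "iort_run"
  out
}

#' @export
print.iort_run <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<iort_run> %d histories, %d batches, seed %d\n", s$n_histories,
              s$n_batches, s$seed))
  cat(sprintf("  injected %.4g MeV; deposited %.4g (grid %.4g, outside %.4g); escaped %.4g\n",
              s$injected_mev, s$deposited_mev, s$grid_mev, s$outside_mev,
              s$escaped_mev))
  cat(sprintf("  energy balance: %.2e relative\n", s$energy_balance))
  invisible(x)
}
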