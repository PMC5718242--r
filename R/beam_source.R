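# Gaussian source model at the exit-window plane: energy ~ N(Ebar, sigma_E)
# truncated at the tracking cutoff, transverse position ~ N(0, sigma_Y/Z),
# polar angle about +x ~ |N(0, sigma_M)| with uniform azimuth. sigma_M is
# interpreted as the polar-angle standard deviation (the adopted reading of
# the angular "spread"); this interpretation is isolated here.

#' Construct a Gaussian beam source model
#'
#' @param mean_energy mean kinetic energy Ebar in MeV.
#' @param sigma_e energy spread (SD) in MeV.
#' @param sigma_y,sigma_z transverse position spreads (SD) in mm.
#' @param sigma_m angular spread (SD of the polar angle) in degrees.
#' @param n_histories default number of histories for runs using this model.
#' @param seed integer seed for reproducible sampling.
#' @return A `beam_source` object.
#' @export
beam_source <- function(mean_energy, sigma_e = 0.5, sigma_y = 1.0,
                        sigma_z = 1.0, sigma_m = 6.0, n_histories = 20000,
                        seed = 1L) {
  stopifnot(mean_energy > 0, sigma_e >= 0, sigma_y >= 0, sigma_z >= 0,
            sigma_m >= 0, n_histories >= 1)
  s <- list(mean_energy = mean_energy, sigma_e = sigma_e, sigma_y = sigma_y,
            sigma_z = sigma_z, sigma_m = sigma_m,
            n_histories = as.integer(n_histories), seed = as.integer(seed))
  class(s) <- "beam_source"
  s
}

#' @export
print.beam_source <- function(x, ...) {
  cat(sprintf("<beam_source> Ebar=%.3g MeV (sd %.3g), sigma_y/z=%.3g/%.3g mm, sigma_m=%.3g deg\n",
              x$mean_energy, x$sigma_e, x$sigma_y, x$sigma_z, x$sigma_m))
  invisible(x)
}

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Sample primary electrons from a source model
#'
#' @param model a `beam_source`.
#' @param n number of primaries.
#' @param seed integer seed (default: the model's seed).
#' @param source_x x-coordinate of the emission plane in mm (just upstream of
#'   the exit window for a full beamline run).
#' @param energy_floor energies below this (MeV) are resampled (tracking
#'   cutoff truncation).
#' @return n x 7 matrix with columns energy, x, y, z, dx, dy, dz; directions
#'   are unit vectors. Deterministic for a given seed.
#' @export
sample_primaries <- function(model, n, seed = model$seed,
                             source_x = -1000.001, energy_floor = 0.025) {
  stopifnot(inherits(model, "beam_source"), n >= 1)
  .with_seed(seed, {
    E <- rnorm(n, model$mean_energy, model$sigma_e)
    for (i in 1:100) {
      low <- E <= energy_floor
      if (!any(low)) break
      E[low] <- rnorm(sum(low), model$mean_energy, model$sigma_e)
    }
    E[E <= energy_floor] <- energy_floor * 1.01
    y <- rnorm(n, 0, model$sigma_y)
    z <- rnorm(n, 0, model$sigma_z)
    theta <- abs(rnorm(n, 0, model$sigma_m * pi / 180))
    phi <- runif(n, 0, 2 * pi)
    d <- cbind(cos(theta), sin(theta) * cos(phi), sin(theta) * sin(phi))
    out <- cbind(E, rep(source_x, n), y, z, d)
    colnames(out) <- c("energy", "x", "y", "z", "dx", "dy", "dz")
    out
  })
}
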