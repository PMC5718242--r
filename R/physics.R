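# Analytic electron/photon interaction surrogates.
#
# The transport engine does not use tabulated cross sections; it relies on
# documented closed forms evaluated here and cached as per-material lookup
# tables:
#   * collision stopping power: Bethe formula for electrons (Berger-Seltzer
#     form) with the Sternheimer-Peierls density-effect parameterisation,
#   * radiative stopping power: S_rad = S_col * Z_eff * E / 800 (classic
#     rule of thumb; within tens of percent of standard tabulations over
#     0.1-15 MeV, adequate for the leakage-level observables targeted here),
#   * multiple scattering: Highland's formula,
#   * photon attenuation: log-log interpolation of a small frozen mu/rho
#     table (standard compilations) times density.

E_WINDOW_MAX_MEV <- 15

.check_e_window <- function(m, E, floor_mev = m$electron_energy_cutoff / 1000) {
  if (any(!is.finite(E)) || any(E < floor_mev - 1e-12) || any(E > E_WINDOW_MAX_MEV)) {
    stop(sprintf("energy outside validity window [%.4g, %g] MeV for %s",
                 floor_mev, E_WINDOW_MAX_MEV, m$name), call. = FALSE)
  }
}

# Sternheimer-Peierls density-effect correction delta(beta*gamma).
.density_effect <- function(m, E) {
  mc2 <- ELECTRON_MASS_MEV
  gamma <- 1 + E / mc2
  bg <- sqrt(gamma^2 - 1)                      # beta*gamma
  x <- log10(bg)
  I <- m$mean_excitation_energy                # eV
  hwp <- 28.816 * sqrt(m$density * m$z_over_a) # plasma energy, eV
  cbar <- 2 * log(I / hwp) + 1
  if (I < 100) {
    x1 <- 2.0
    x0 <- if (cbar < 3.681) 0.2 else 0.326 * cbar - 1.0
  } else {
    x1 <- 3.0
    x0 <- if (cbar < 5.215) 0.2 else 0.326 * cbar - 1.5
  }
  a <- (cbar - 4.606 * x0) / (x1 - x0)^3
  delta <- ifelse(x >= x1, 4.606 * x - cbar,
           ifelse(x >= x0, 4.606 * x - cbar + a * (x1 - x)^3, 0))
  pmax(delta, 0)
}

#' Electron collision stopping power
#'
#' Bethe collision stopping power for electrons (Berger-Seltzer closed form)
#' with the Sternheimer-Peierls density-effect correction, in MeV/cm.
#'
#' @param m a `material` or material name.
#' @param E kinetic energy in MeV (vectorised). Valid from the material's
#'   electron cutoff up to 15 MeV.
#' @return Linear collision stopping power, MeV/cm.
#' @export
collision_stopping_power <- function(m, E) {
  m <- .as_material(m)
  .check_e_window(m, E)
  mc2 <- ELECTRON_MASS_MEV
  tau <- E / mc2
  gamma <- 1 + tau
  beta2 <- 1 - 1 / gamma^2
  Imc2 <- m$mean_excitation_energy * 1e-6 / mc2
  term_ln <- log(tau^2 * (tau + 2) / (2 * Imc2^2))
  Fm <- 1 - beta2 + (tau^2 / 8 - (2 * tau + 1) * log(2)) / (tau + 1)^2
  delta <- .density_effect(m, E)
  sp_mass <- 0.153536 / beta2 * m$z_over_a * (term_ln + Fm - delta)
  sp_mass * m$density
}

#' Electron radiative stopping power
#'
#' Approximated as `S_rad = S_col * Z_eff * E / 800` (E in MeV), the classic
#' radiative/collision ratio rule. Grows with both energy and effective Z.
#'
#' @inheritParams collision_stopping_power
#' @return Linear radiative stopping power, MeV/cm.
#' @export
radiative_stopping_power <- function(m, E) {
  m <- .as_material(m)
  collision_stopping_power(m, E) * m$effective_z * E / 800
}

#' Total (collision + radiative) stopping power in MeV/cm
#' @inheritParams collision_stopping_power
#' @export
total_stopping_power <- function(m, E) {
  collision_stopping_power(m, E) + radiative_stopping_power(m, E)
}

#' CSDA range
#'
#' Continuous-slowing-down range: numerical integral of the reciprocal total
#' stopping power from the material's electron cutoff up to `E`, on a fine
#' log-spaced grid (trapezoidal rule).
#'
#' @inheritParams collision_stopping_power
#' @param n_grid number of quadrature nodes.
#' @return Range in cm.
#' @export
csda_range <- function(m, E, n_grid = 2000) {
  m <- .as_material(m)
  .check_e_window(m, E)
  e0 <- m$electron_energy_cutoff / 1000
  vapply(E, function(e) {
    if (e <= e0 * (1 + 1e-12)) return(0)
    eg <- exp(seq(log(e0), log(e), length.out = n_grid))
    f <- 1 / total_stopping_power(m, eg)
    if (any(!is.finite(f))) stop("non-finite integrand in csda_range", call. = FALSE)
    sum(diff(eg) * (head(f, -1) + tail(f, -1)) / 2)
  }, numeric(1))
}

#' Highland multiple-scattering angle
#'
#' `theta0 = 13.6 MeV / (beta c p) * sqrt(t/X0) * (1 + 0.038 ln(t/X0))`,
#' with `t` the step thickness in g/cm^2; clamped at zero.
#'
#' @inheritParams collision_stopping_power
#' @param step step length in cm.
#' @return Polar scattering-angle standard deviation in radians.
#' @export
highland_sigma <- function(m, E, step) {
  m <- .as_material(m)
  .check_e_window(m, E)
  stopifnot(all(step >= 0))
  mc2 <- ELECTRON_MASS_MEV
  pc <- sqrt(E * (E + 2 * mc2))
  beta <- pc / (E + mc2)
  tx0 <- step * m$density / m$radiation_length
  th <- ifelse(tx0 > 0,
               13.6 / (beta * pc) * sqrt(tx0) * (1 + 0.038 * log(tx0)), 0)
  pmax(th, 0)
}

#' Total photon attenuation coefficient
#'
#' Log-log interpolation of the bundled photon mass-attenuation table
#' (frozen from standard compilations) times density.
#'
#' @param m a `material` or material name.
#' @param E photon energy in MeV; valid from the material's photon cutoff up
#'   to 15 MeV.
#' @return Linear attenuation coefficient, 1/cm.
#' @export
photon_attenuation <- function(m, E) {
  m <- .as_material(m)
  lo <- m$photon_energy_cutoff / 1000
  if (any(!is.finite(E)) || any(E < lo - 1e-12) || any(E > E_WINDOW_MAX_MEV)) {
    stop(sprintf("photon energy outside validity window [%.4g, %g] MeV",
                 lo, E_WINDOW_MAX_MEV), call. = FALSE)
  }
  .load_material_library()
  tab <- .iort$mu_table
  col <- if (!is.null(m$mu_like)) m$mu_like else m$name
  if (!col %in% names(tab)) {
    stop(sprintf("no photon attenuation data for material '%s'", m$name),
         call. = FALSE)
  }
  mu_rho <- exp(approx(log(tab$energy_mev), log(tab[[col]]), xout = log(E),
                       rule = 2)$y)
  mu_rho * m$density
}

# Per-material lookup tables handed to the compiled transport core.
# Energies log-spaced from just below the smallest cutoff to 15 MeV.
.build_material_tables <- function(materials, settings) {
  lapply(materials, function(m) {
    e0 <- 0.010
    eg <- exp(seq(log(e0), log(E_WINDOW_MAX_MEV), length.out = 300))
    eg_sp <- pmax(eg, m$electron_energy_cutoff / 1000)
    scol <- collision_stopping_power(m, eg_sp) / 10   # MeV/mm
    srad <- radiative_stopping_power(m, eg_sp) / 10
    eg_mu <- pmax(eg, m$photon_energy_cutoff / 1000)
    mu <- photon_attenuation(m, eg_mu) / 10           # 1/mm
    list(
      name = m$name,
      rho = m$density,
      x0_mm = m$radiation_length / m$density * 10,
      ecut = m$electron_energy_cutoff / 1000,
      gcut = m$photon_energy_cutoff / 1000,
      zeff = m$effective_z,
      omega_coef = sqrt(0.1569 * m$z_over_a * m$density), # Bohr, MeV/sqrt(cm)
      max_step_mm = min(100, settings$max_step / m$density),
      log_e0 = log(eg[1]),
      dlog = diff(log(eg[1:2])),
      scol = scol, srad = srad, mu = mu)
  })
}
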