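# Material library: frozen constants read from the CSV shipped in extdata.
# Densities, Z/A, mean excitation energies and radiation lengths are standard
# reference values; tracking cutoffs default to 25 keV (light media) and
# 12 keV (lead).

ELECTRON_MASS_MEV <- 0.51099895

.load_material_library <- function() {
  if (!is.null(.iort$materials)) return(invisible())
  path <- system.file("extdata", "materials.csv", package = "iortsim")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  mats <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    new_material(
      name = r$name, density = r$density_g_cm3, effective_z = r$effective_z,
      effective_a = r$effective_a_g_mol,
      mean_excitation_energy = r$mean_excitation_energy_ev,
      radiation_length = r$radiation_length_g_cm2,
      electron_energy_cutoff = r$electron_energy_cutoff_kev,
      photon_energy_cutoff = r$photon_energy_cutoff_kev)
  })
  names(mats) <- tab$name
  .iort$materials <- mats

  mu <- read.csv(system.file("extdata", "photon_mass_attenuation.csv",
                             package = "iortsim"), stringsAsFactors = FALSE)
  .iort$mu_table <- mu
  invisible()
}

#' Construct a material record
#'
#' @param name material name (lower-case key).
#' @param density mass density in g/cm^3.
#' @param effective_z,effective_a effective atomic number and mass (g/mol).
#' @param mean_excitation_energy mean excitation energy I in eV.
#' @param radiation_length radiation length X0 in g/cm^2.
#' @param electron_energy_cutoff,photon_energy_cutoff tracking cutoffs in keV.
#' @return An object of class `material`.
#' @export
new_material <- function(name, density, effective_z, effective_a,
                         mean_excitation_energy, radiation_length,
                         electron_energy_cutoff = 25,
                         photon_energy_cutoff = 10) {
  stopifnot(density > 0, radiation_length > 0,
            electron_energy_cutoff > 0, photon_energy_cutoff > 0)
  m <- list(name = tolower(name), density = density,
            effective_z = effective_z, effective_a = effective_a,
            z_over_a = effective_z / effective_a,
            mean_excitation_energy = mean_excitation_energy,
            radiation_length = radiation_length,
            electron_energy_cutoff = electron_energy_cutoff,
            photon_energy_cutoff = photon_energy_cutoff)
  class(m) <- "material"
  m
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material %s>  rho=%.4g g/cm3  Zeff=%.3g  I=%.4g eV  X0=%.4g g/cm2\n",
              x$name, x$density, x$effective_z, x$mean_excitation_energy,
              x$radiation_length))
  cat(sprintf("  cutoffs: e- %g keV, photon %g keV\n",
              x$electron_energy_cutoff, x$photon_energy_cutoff))
  invisible(x)
}

#' List the bundled material library
#'
#' @return Named list of `material` records (water, PMMA, air, aluminum,
#'   titanium, lead, plus any registered via [register_material()]).
#' @export
material_library <- function() {
  .load_material_library()
  .iort$materials
}

#' Look up a material by name
#'
#' @param name case-insensitive material name.
#' @return A `material` record.
#' @export
get_material <- function(name) {
  .load_material_library()
  key <- tolower(name)
  m <- .iort$materials[[key]]
  if (is.null(m)) {
    stop(sprintf("unknown material '%s'; available: %s", name,
                 paste(names(.iort$materials), collapse = ", ")),
         call. = FALSE)
  }
  m
}

#' Register a custom material
#'
#' Adds (or replaces) a material in the session library. Photon attenuation
#' for custom materials is interpolated from the bundled table by effective Z
#' unless a `mu_like` donor material is named.
#'
#' @inheritParams new_material
#' @param mu_like name of a bundled material whose photon mass-attenuation
#'   curve should be reused (default: nearest bundled effective Z).
#' @return The registered `material`, invisibly.
#' @export
register_material <- function(name, density, effective_z, effective_a,
                              mean_excitation_energy, radiation_length,
                              electron_energy_cutoff = 25,
                              photon_energy_cutoff = 10, mu_like = NULL) {
  .load_material_library()
  m <- new_material(name, density, effective_z, effective_a,
                    mean_excitation_energy, radiation_length,
                    electron_energy_cutoff, photon_energy_cutoff)
  if (is.null(mu_like)) {
    zs <- vapply(.iort$materials, `[[`, numeric(1), "effective_z")
    mu_like <- names(zs)[which.min(abs(zs - effective_z))]
  }
  stopifnot(mu_like %in% names(.iort$mu_table))
  m$mu_like <- mu_like
  .iort$materials[[m$name]] <- m
  invisible(m)
}

.as_material <- function(m) {
  if (inherits(m, "material")) m else get_material(m)
}
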