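#' Physical constants used throughout the package
#'
#' Fixed values of the Boltzmann constant and Avogadro's number, at the
#' precision conventionally quoted in light-scattering work.
#'
#' @format A named list with elements `boltzmann` (J/K) and `avogadro` (1/mol).
#' @export
os_constants <- list(
  boltzmann = 1.38e-23,
  avogadro  = 6.022e23
)

#' Solvent conditions for hydrodynamic calculations
#'
#' Bundles the temperature, viscosity and refractive index of the solvent.
#' Defaults correspond to an aqueous buffer at 25 degrees C: eta =
#' 8.872e-4 Pa s (the standard tabulated viscosity of water at 298.15 K)
#' and n = 1.33.
#'
#' @param temperature Absolute temperature in kelvin.
#' @param viscosity Dynamic viscosity in Pa s.
#' @param refractive_index Refractive index of the solution (dimensionless,
#'   >= 1).
#' @return An object of class `solvent_conditions`.
#' @export
solvent_conditions <- function(temperature = 298.15,
                               viscosity = 8.872e-4,
                               refractive_index = 1.33) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.numeric(viscosity), length(viscosity) == 1L,
            is.numeric(refractive_index), length(refractive_index) == 1L)
  if (temperature <= 0) stop("`temperature` must be > 0 K")
  if (viscosity <= 0) stop("`viscosity` must be > 0 Pa s")
  if (refractive_index < 1) stop("`refractive_index` must be >= 1")
  structure(list(temperature = temperature,
                 viscosity = viscosity,
                 refractive_index = refractive_index),
            class = "solvent_conditions")
}

#' Protein optical and mass parameters
#'
#' Monomer molar mass, refractive-index increment (dn/dc) and dry mass
#' density of the protein. Defaults describe a ~20 kDa small heat-shock
#' protein monomer: M_w = 20 000 g/mol, dn/dc = 0.185 mL/g (conventional
#' protein value), density 1.4 g/mL.
#'
#' @param monomer_molar_mass Monomer molar mass in g/mol.
#' @param refractive_index_increment dn/dc in mL/g.
#' @param mass_density Protein mass density in g/mL.
#' @return An object of class `protein_params`.
#' @export
protein_params <- function(monomer_molar_mass = 20000,
                           refractive_index_increment = 0.185,
                           mass_density = 1.4) {
  vals <- c(monomer_molar_mass, refractive_index_increment, mass_density)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all protein parameters must be strictly positive")
  structure(list(monomer_molar_mass = monomer_molar_mass,
                 refractive_index_increment = refractive_index_increment,
                 mass_density = mass_density),
            class = "protein_params")
}

#' Static light scattering calibration constants
#'
#' Toluene Rayleigh ratio and the refractive indices of buffer and toluene
#' used to place scattered intensities on absolute scale. Defaults are the
#' 25 degrees C values R_t = 1.148e-5 1/cm, n_b = 1.33, n_t = 1.49.
#'
#' @param rayleigh_toluene Rayleigh ratio of toluene in 1/cm.
#' @param n_buffer Refractive index of the buffer.
#' @param n_toluene Refractive index of toluene.
#' @return An object of class `calibration_constants`.
#' @export
calibration_constants <- function(rayleigh_toluene = 1.148e-5,
                                  n_buffer = 1.33,
                                  n_toluene = 1.49) {
  if (rayleigh_toluene <= 0) stop("`rayleigh_toluene` must be > 0")
  if (n_buffer < 1 || n_toluene < 1) stop("refractive indices must be >= 1")
  structure(list(rayleigh_toluene = rayleigh_toluene,
                 n_buffer = n_buffer,
                 n_toluene = n_toluene),
            class = "calibration_constants")
}

#' Scattering vector magnitude
#'
#' q = 4 pi n sin(theta/2) / lambda, the momentum transfer probed at
#' scattering angle theta for incident wavelength lambda in a medium of
#' refractive index n. For X-rays n = 1.
#'
#' @param theta_deg Scattering angle in degrees, in (0, 180].
#' @param wavelength_nm Incident wavelength in nm (in vacuo).
#' @param refractive_index Refractive index of the medium (1 for X-rays).
#' @return q in 1/nm (vectorized over `theta_deg`).
#' @export
scattering_vector <- function(theta_deg, wavelength_nm, refractive_index = 1) {
  if (any(!is.finite(theta_deg)) || any(theta_deg <= 0) || any(theta_deg > 180))
    stop("`theta_deg` must lie in (0, 180]")
  if (!is.finite(wavelength_nm) || wavelength_nm <= 0)
    stop("`wavelength_nm` must be > 0")
  4 * pi * refractive_index * sin(theta_deg * pi / 360) / wavelength_nm
}

#' Hydrodynamic radius from a diffusion coefficient (Stokes-Einstein)
#'
#' R_H = k_B T / (6 pi eta D), valid in the dilute limit.
#'
#' @param diffusion Translational diffusion coefficient in m^2/s.
#' @param solvent A [solvent_conditions()] object.
#' @return Hydrodynamic radius in nm.
#' @seealso [diffusion_from_radius()] for the inverse.
#' @export
stokes_einstein <- function(diffusion, solvent = solvent_conditions()) {
  if (any(!is.finite(diffusion)) || any(diffusion <= 0))
    stop("`diffusion` must be > 0")
  r_m <- os_constants$boltzmann * solvent$temperature /
    (6 * pi * solvent$viscosity * diffusion)
  r_m * 1e9
}

#' Diffusion coefficient of a sphere of given hydrodynamic radius
#'
#' Inverse of [stokes_einstein()]: D = k_B T / (6 pi eta R_H).
#'
#' @param r_h_nm Hydrodynamic radius in nm.
#' @param solvent A [solvent_conditions()] object.
#' @return Diffusion coefficient in m^2/s.
#' @export
diffusion_from_radius <- function(r_h_nm, solvent = solvent_conditions()) {
  if (any(!is.finite(r_h_nm)) || any(r_h_nm <= 0))
    stop("`r_h_nm` must be > 0")
  os_constants$boltzmann * solvent$temperature /
    (6 * pi * solvent$viscosity * r_h_nm * 1e-9)
}

#' Convert molar protein concentration to mass concentration
#'
#' Mass and molar concentration conventions coexist in this package: the
#' association model works in nM of monomer while scattering optics work in
#' g/mL. All conversions pass explicitly through the monomer molar mass.
#'
#' @param conc_uM Concentration in micromolar (monomer units).
#' @param protein A [protein_params()] object.
#' @return Mass concentration in g/mL.
#' @export
molar_to_mass_conc <- function(conc_uM, protein = protein_params()) {
  if (any(!is.finite(conc_uM)) || any(conc_uM < 0))
    stop("`conc_uM` must be >= 0")
  conc_uM * 1e-9 * protein$monomer_molar_mass
}

#' @rdname molar_to_mass_conc
#' @param conc_g_ml Mass concentration in g/mL.
#' @export
mass_to_molar_conc <- function(conc_g_ml, protein = protein_params()) {
  if (any(!is.finite(conc_g_ml)) || any(conc_g_ml < 0))
    stop("`conc_g_ml` must be >= 0")
  conc_g_ml / (1e-9 * protein$monomer_molar_mass)
}

# Error signalled when a fit degenerates rather than when input is invalid;
# callers can distinguish it via class "os_fit_failure".
stop_fit_failure <- function(msg, ...) {
  stop(errorCondition(msg, ..., class = c("os_fit_failure", "error", "condition")))
}
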