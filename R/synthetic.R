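## Seeded instrument emulators. Each generator returns list(data, truth):
## the dataset in the same table layout the corresponding reader produces,
## plus a ground-truth record for recovery tests.

#' Named parameter presets for the synthetic generators
#'
#' Encodes the study conditions used throughout the package as ground
#' truth for recovery runs:
#' * `day0` — freshly diluted static light scattering series, aggregation
#'   number 24, concentrations 10, 22, 34, 46, 58, 69 uM, 2% noise.
#' * `day7` — equilibrated series, aggregation number 18 (the stable value
#'   reached after about one week), same concentrations; the matching DLS
#'   condition has hydrodynamic radius 7.4 nm.
#' * `sphere` — SAXS sphere of radius 6 nm, q = 0.05-3 1/nm, 200
#'   log-spaced points, 2% noise.
#' * `paper_mds` — closed-association model with K = 1e-4 nM^-8, 9 dimeric
#'   subunits, radii 5/7 nm, the 16-point 1 nM - 8 uM dilution grid,
#'   triplicates with 0.3 nm replicate noise.
#'
#' @param name One of `"day0"`, `"day7"`, `"sphere"`, `"paper_mds"`.
#' @return A named list of generator arguments.
#' @export
os_preset <- function(name = c("day0", "day7", "sphere", "paper_mds")) {
  name <- match.arg(name)
  sls_conc <- c(10, 22, 34, 46, 58, 69)
  mds_conc <- c(1, 3, 5, 8, 10, 15, 20, 30, 50, 100, 250, 500,
                1000, 3000, 5000, 8000)
  switch(name,
    day0 = list(modality = "sls", n_agg = 24, concentrations_uM = sls_conc,
                noise_frac = 0.02),
    day7 = list(modality = "sls", n_agg = 18, concentrations_uM = sls_conc,
                noise_frac = 0.02, r_h_nm = 7.4, dls_noise_sd = 1e-3),
    sphere = list(modality = "saxs", radius = 6, forward_intensity = 1,
                  internal_background = 1e-3,
                  q_grid = 10^seq(log10(0.05), log10(3), length.out = 200),
                  noise_frac = 0.02),
    paper_mds = list(modality = "mds",
                     params = association_params(assoc_constant = 1e-4,
                                                 subunits_per_oligomer = 9,
                                                 r_h_subunit = 5,
                                                 r_h_oligomer = 7),
                     concentrations_nM = mds_conc,
                     replicate_sd = 0.3, n_replicates = 3)
  )
}

#' Generate synthetic multi-angle DLS correlograms
#'
#' Emulates a goniometer run: per angle, g2(tau) = 1 + beta *
#' exp(-2 q^2 D tau) on a log-spaced lag grid (1e-6 to 1 s, 200 points, a
#' typical correlator span) with additive Gaussian noise; D comes from the
#' Stokes-Einstein relation at the requested hydrodynamic radius.
#'
#' @param r_h_nm Ground-truth hydrodynamic radius in nm.
#' @param solvent A [solvent_conditions()] object.
#' @param angles_deg Scattering angles (default 60-140 degrees in 5 degree
#'   steps).
#' @param wavelength_nm Laser wavelength in nm.
#' @param beta Siegert coherence factor (0 < beta <= 1).
#' @param noise_sd Additive Gaussian noise SD on g2.
#' @param seed Integer seed; identical seed and parameters give identical
#'   output.
#' @param n_lags,lag_range Lag grid size and span in seconds.
#' @return A list with `data` (data frame `angle_deg`, `lag_s`, `g2`) and
#'   `truth` (parameter record).
#' @export
gen_dls <- function(r_h_nm = 7.4,
                    solvent = solvent_conditions(),
                    angles_deg = seq(60, 140, by = 5),
                    wavelength_nm = 660,
                    beta = 0.9,
                    noise_sd = 1e-3,
                    seed = 1,
                    n_lags = 200,
                    lag_range = c(1e-6, 1)) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  set.seed(seed)
  D <- diffusion_from_radius(r_h_nm, solvent)
  tau <- 10^seq(log10(lag_range[1]), log10(lag_range[2]), length.out = n_lags)
  data <- do.call(rbind, lapply(angles_deg, function(a) {
    q <- scattering_vector(a, wavelength_nm, solvent$refractive_index)
    gamma <- (q * 1e9)^2 * D
    g2 <- 1 + beta * exp(-2 * gamma * tau) +
      stats::rnorm(length(tau), sd = noise_sd)
    data.frame(angle_deg = a, lag_s = tau, g2 = g2)
  }))
  list(data = data,
       truth = list(modality = "dls", r_h_nm = r_h_nm, diffusion = D,
                    beta = beta, noise_sd = noise_sd, seed = seed,
                    noise_model = "additive gaussian on g2"))
}

#' Generate a synthetic SLS intensity table
#'
#' Emulates a toluene-calibrated concentration series: the forward excess
#' Rayleigh ratio dR(0) = K_opt c N M_w is converted to raw (sample,
#' buffer, toluene) count rates by inverting the calibration relation with
#' fixed buffer and toluene levels; multiplicative Gaussian noise is
#' applied to the excess counts per angle.
#'
#' @param n_agg Ground-truth aggregation number.
#' @param concentrations_uM Molar concentrations of the series.
#' @param protein A [protein_params()] object.
#' @param calib A [calibration_constants()] object.
#' @param wavelength_nm Laser wavelength in nm.
#' @param angles_deg Recorded angles.
#' @param noise_frac Relative SD of the multiplicative noise.
#' @param seed Integer seed.
#' @param I_toluene,I_buffer Fixed standard/buffer count rates (counts/s).
#' @param day Label stored in the `day` column.
#' @return A list with `data` (data frame `angle_deg`, `I_sample`,
#'   `I_buffer`, `I_toluene`, `conc_uM`, `day`) and `truth`.
#' @export
gen_sls <- function(n_agg = 18,
                    concentrations_uM = c(10, 22, 34, 46, 58, 69),
                    protein = protein_params(),
                    calib = calibration_constants(),
                    wavelength_nm = 660,
                    angles_deg = seq(60, 140, by = 5),
                    noise_frac = 0.02,
                    seed = 1,
                    I_toluene = 1e5,
                    I_buffer = 5e3,
                    day = "day") {
  if (noise_frac < 0) stop("`noise_frac` must be >= 0")
  set.seed(seed)
  K_opt <- optical_constant(protein, calib, wavelength_nm)
  data <- do.call(rbind, lapply(concentrations_uM, function(cu) {
    c_mass <- molar_to_mass_conc(cu, protein)
    dR0 <- K_opt * c_mass * n_agg * protein$monomer_molar_mass
    excess <- dR0 / (calib$rayleigh_toluene * (calib$n_buffer / calib$n_toluene)^2) *
      I_toluene
    noisy <- excess * (1 + stats::rnorm(length(angles_deg), sd = noise_frac))
    data.frame(angle_deg = angles_deg,
               I_sample = I_buffer + noisy,
               I_buffer = I_buffer,
               I_toluene = I_toluene,
               conc_uM = cu,
               day = day)
  }))
  list(data = data,
       truth = list(modality = "sls", n_agg = n_agg,
                    concentrations_uM = concentrations_uM,
                    noise_frac = noise_frac, seed = seed,
                    noise_model = "multiplicative gaussian on excess counts"))
}

#' Generate a synthetic SAXS curve
#'
#' Evaluates the homogeneous-sphere profile ([sphere_intensity()]) on a q
#' grid and applies multiplicative Gaussian noise; the sigma column is set
#' to `noise_frac` times the observed intensity.
#'
#' @param radius Sphere radius in nm.
#' @param forward_intensity,internal_background Model intensities in 1/cm.
#' @param q_grid Scattering vector grid in 1/nm.
#' @param noise_frac Relative noise SD.
#' @param seed Integer seed.
#' @param concentration Optional concentration in uM carried in the curve.
#' @return A list with `data` (data frame `q`, `intensity`, `sigma`, and
#'   `concentration` when given) and `truth`.
#' @export
gen_saxs <- function(radius = 6,
                     forward_intensity = 1,
                     internal_background = 1e-3,
                     q_grid = 10^seq(log10(0.05), log10(3), length.out = 200),
                     noise_frac = 0.02,
                     seed = 1,
                     concentration = NULL) {
  if (noise_frac < 0) stop("`noise_frac` must be >= 0")
  set.seed(seed)
  I_true <- sphere_intensity(q_grid, radius, forward_intensity,
                             internal_background)
  I_obs <- I_true * (1 + stats::rnorm(length(q_grid), sd = noise_frac))
  data <- data.frame(q = q_grid, intensity = I_obs,
                     sigma = if (noise_frac > 0) noise_frac * abs(I_obs) else
                       rep(0, length(q_grid)))
  if (!is.null(concentration)) data$concentration <- concentration
  list(data = data,
       truth = list(modality = "saxs", radius = radius,
                    forward_intensity = forward_intensity,
                    internal_background = internal_background,
                    noise_frac = noise_frac, seed = seed,
                    noise_model = "multiplicative gaussian"))
}

#' Generate a synthetic diffusional-sizing dilution series
#'
#' Emulates a fluorescence-based sizing run over a dilution series: the
#' true concentration is the nominal one reduced by `adsorption_loss`
#' below a threshold (surface losses in dilute samples); replicate radii
#' follow the closed-association mean-radius curve plus additive Gaussian
#' noise; intensities are proportional to the true concentration with
#' small multiplicative noise, so the concentration correction can be
#' exercised end to end.
#'
#' @param params An [association_params()] object (ground truth).
#' @param concentrations_nM Nominal total monomer concentrations.
#' @param replicate_sd Additive noise SD on replicate radii (nm).
#' @param n_replicates Replicates per sample.
#' @param adsorption_loss Length-2 numeric `c(threshold_nM, fraction)`:
#'   samples below the threshold lose this fraction of protein.
#' @param intensity_gain Intensity counts per nM of true concentration.
#' @param intensity_noise_frac Relative noise SD on intensities.
#' @param seed Integer seed.
#' @param day Label stored in the `day` column.
#' @return A list with `data` (data frame `conc_nM_nominal`, `replicate`,
#'   `r_h_nm`, `intensity`, `day`) and `truth` (including the per-sample
#'   true concentrations).
#' @export
gen_mds <- function(params = association_params(),
                    concentrations_nM = c(1, 3, 5, 8, 10, 15, 20, 30, 50,
                                          100, 250, 500, 1000, 3000, 5000,
                                          8000),
                    replicate_sd = 0.3,
                    n_replicates = 3,
                    adsorption_loss = c(threshold_nM = 100, fraction = 0),
                    intensity_gain = 1,
                    intensity_noise_frac = 0.002,
                    seed = 1,
                    day = "day7") {
  if (replicate_sd < 0) stop("`replicate_sd` must be >= 0")
  if (n_replicates < 1) stop("`n_replicates` must be >= 1")
  set.seed(seed)
  loss_thr <- adsorption_loss[[1]]
  loss_frac <- adsorption_loss[[2]]
  true_conc <- ifelse(concentrations_nM < loss_thr,
                      concentrations_nM * (1 - loss_frac),
                      concentrations_nM)
  r_model <- mean_hydrodynamic_radius(true_conc, params)
  data <- do.call(rbind, lapply(seq_along(concentrations_nM), function(i) {
    r_rep <- r_model[i] + stats::rnorm(n_replicates, sd = replicate_sd)
    int_rep <- intensity_gain * true_conc[i] *
      (1 + stats::rnorm(n_replicates, sd = intensity_noise_frac))
    data.frame(conc_nM_nominal = concentrations_nM[i],
               replicate = seq_len(n_replicates),
               r_h_nm = r_rep,
               intensity = int_rep,
               day = day)
  }))
  list(data = data,
       truth = list(modality = "mds",
                    assoc_constant = params$assoc_constant,
                    subunits_per_oligomer = params$subunits_per_oligomer,
                    r_h_subunit = params$r_h_subunit,
                    r_h_oligomer = params$r_h_oligomer,
                    true_conc_nM = true_conc,
                    replicate_sd = replicate_sd,
                    adsorption_loss = c(threshold_nM = loss_thr,
                                        fraction = loss_frac),
                    seed = seed,
                    noise_model = "additive gaussian on R_H, multiplicative on intensity"))
}
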