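#' Excess Rayleigh ratio from raw intensities via toluene calibration
#'
#' Converts time-averaged scattered count rates from sample, buffer and
#' toluene standard to absolute scale:
#' dR = ((I_s - I_b) / I_t) * R_t * (n_b / n_t)^2.
#' A negative excess (buffer brighter than sample) is returned but flagged
#' with a warning rather than rejected, since it can arise from noise at
#' low concentration.
#'
#' @param I_sample,I_buffer,I_toluene Count rates (same arbitrary units);
#'   `I_toluene` must be strictly positive. Vectorized.
#' @param calib A [calibration_constants()] object.
#' @return Excess Rayleigh ratio in 1/cm.
#' @export
excess_rayleigh <- function(I_sample, I_buffer, I_toluene,
                            calib = calibration_constants()) {
  if (any(!is.finite(I_toluene)) || any(I_toluene <= 0))
    stop("`I_toluene` must be > 0")
  if (any(I_sample < 0) || any(I_buffer < 0))
    stop("intensities must be >= 0")
  dR <- ((I_sample - I_buffer) / I_toluene) * calib$rayleigh_toluene *
    (calib$n_buffer / calib$n_toluene)^2
  if (any(dR < 0))
    warning("negative excess Rayleigh ratio (buffer brighter than sample)")
  dR
}

#' Extrapolate the excess Rayleigh ratio to zero scattering vector
#'
#' Ordinary least-squares fit of dR against q^2; the intercept is the
#' forward-scattering value dR(0). For particles with q R << 1 the slope is
#' expected to be statistically consistent with zero, which is reported as
#' a diagnostic.
#'
#' @param q Scattering vectors in 1/nm (>= 3 values).
#' @param deltaR Excess Rayleigh ratios in 1/cm at each q.
#' @return A list with `deltaR0` (1/cm), `slope`, `slope_se` and
#'   `slope_consistent_zero` (logical).
#' @export
extrapolate_to_zero_q <- function(q, deltaR) {
  if (length(q) < 3L) stop("need at least 3 angles to extrapolate to q = 0")
  if (length(q) != length(deltaR)) stop("`q` and `deltaR` lengths differ")
  q2 <- q^2
  fit <- stats::lm(deltaR ~ q2)
  cf <- suppressWarnings(summary(fit))$coefficients  # noiseless data fit exactly
  list(deltaR0 = cf[1, 1],
       slope = cf[2, 1],
       slope_se = cf[2, 2],
       slope_consistent_zero = abs(cf[2, 1] / cf[2, 2]) < 2)
}

#' Optical constant for static light scattering
#'
#' K_opt = 4 pi^2 n_b^2 (dn/dc)^2 / (N_A lambda^4), with the wavelength
#' converted to cm and dn/dc taken in cm^3/g, so that
#' dR(0) = K_opt * c * N * M_w with c in g/mL.
#'
#' @param protein A [protein_params()] object (supplies dn/dc).
#' @param calib A [calibration_constants()] object (supplies n_b).
#' @param wavelength_nm Laser wavelength in nm.
#' @return K_opt in cm^2 mol / g^2.
#' @export
optical_constant <- function(protein = protein_params(),
                             calib = calibration_constants(),
                             wavelength_nm = 660) {
  if (wavelength_nm <= 0) stop("`wavelength_nm` must be > 0")
  lambda_cm <- wavelength_nm * 1e-7
  dndc <- protein$refractive_index_increment  # mL/g == cm^3/g
  4 * pi^2 * calib$n_buffer^2 * dndc^2 /
    (os_constants$avogadro * lambda_cm^4)
}

#' Aggregation number from the concentration dependence of dR(0)
#'
#' For monodisperse assemblies of N monomers the forward excess Rayleigh
#' ratio is linear in mass concentration, dR(0) = K_opt c N M_w, so the
#' through-origin slope of dR(0) vs c yields N = slope / (K_opt M_w).
#' A free-intercept fit is reported as a linearity diagnostic.
#'
#' @param conc_g_ml Mass concentrations in g/mL (>= 2 distinct values).
#' @param deltaR0 Forward excess Rayleigh ratios in 1/cm.
#' @param protein A [protein_params()] object.
#' @param K_opt Optical constant in cm^2 mol/g^2; defaults to
#'   [optical_constant()] evaluated with `protein`.
#' @return A list with `N_raw`, `N_rounded`, `slope` (cm^2/g), `stderr`
#'   (relative standard error of the slope), and free-intercept
#'   diagnostics `intercept`, `intercept_se`.
#' @export
aggregation_number <- function(conc_g_ml, deltaR0,
                               protein = protein_params(),
                               K_opt = optical_constant(protein)) {
  if (length(conc_g_ml) != length(deltaR0))
    stop("`conc_g_ml` and `deltaR0` lengths differ")
  if (length(unique(conc_g_ml)) < 2L)
    stop("need at least 2 distinct concentrations")
  if (any(conc_g_ml <= 0)) stop("concentrations must be > 0")
  fit <- stats::lm(deltaR0 ~ 0 + conc_g_ml)
  slope <- stats::coef(fit)[[1]]
  if (slope <= 0)
    stop_fit_failure("dR(0) vs c slope is non-positive; no aggregation number")
  slope_se <- suppressWarnings(summary(fit))$coefficients[1, 2]
  free <- if (length(conc_g_ml) >= 3L) {
    cf <- suppressWarnings(summary(stats::lm(deltaR0 ~ conc_g_ml)))$coefficients
    list(intercept = cf[1, 1], intercept_se = cf[1, 2])
  } else list(intercept = NA_real_, intercept_se = NA_real_)
  N <- slope / (K_opt * protein$monomer_molar_mass)
  list(N_raw = N,
       N_rounded = round(N),
       slope = slope,
       stderr = slope_se / slope,
       intercept = free$intercept,
       intercept_se = free$intercept_se)
}

#' Full static light scattering analysis of an intensity table
#'
#' Converts raw (sample, buffer, toluene) intensity triplets per angle to
#' excess Rayleigh ratios, extrapolates each concentration to q = 0, and
#' estimates the aggregation number per day from the through-origin fit of
#' dR(0) against mass concentration.
#'
#' @param df A data frame with columns `angle_deg`, `I_sample`, `I_buffer`,
#'   `I_toluene`, `conc_uM` and optionally `day`.
#' @param protein A [protein_params()] object.
#' @param calib A [calibration_constants()] object.
#' @param wavelength_nm Laser wavelength in nm.
#' @return A list with `by_day` (data frame: `day`, `N_raw`, `N_rounded`,
#'   `slope`, `stderr`) and `series` (data frame of per-concentration
#'   `deltaR0` values).
#' @export
analyze_sls <- function(df,
                        protein = protein_params(),
                        calib = calibration_constants(),
                        wavelength_nm = 660) {
  req <- c("angle_deg", "I_sample", "I_buffer", "I_toluene", "conc_uM")
  stopifnot(is.data.frame(df), all(req %in% names(df)))
  if (is.null(df$day)) df$day <- "day0"

  series <- do.call(rbind, lapply(split(df, list(df$day, df$conc_uM), drop = TRUE),
    function(sub) {
      q <- scattering_vector(sub$angle_deg, wavelength_nm, calib$n_buffer)
      dR <- excess_rayleigh(sub$I_sample, sub$I_buffer, sub$I_toluene, calib)
      ext <- extrapolate_to_zero_q(q, dR)
      data.frame(day = sub$day[1], conc_uM = sub$conc_uM[1],
                 deltaR0 = ext$deltaR0, slope_q2 = ext$slope)
    }))
  rownames(series) <- NULL

  K_opt <- optical_constant(protein, calib, wavelength_nm)
  by_day <- do.call(rbind, lapply(split(series, series$day), function(sub) {
    agg <- aggregation_number(molar_to_mass_conc(sub$conc_uM, protein),
                              sub$deltaR0, protein, K_opt)
    data.frame(day = sub$day[1], N_raw = agg$N_raw, N_rounded = agg$N_rounded,
               slope = agg$slope, stderr = agg$stderr)
  }))
  rownames(by_day) <- NULL
  list(by_day = by_day, series = series)
}
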