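#' Fit a mono-exponential decay to an intensity correlation function
#'
#' Fits the Siegert relation g2(tau) = 1 + beta * exp(-2 Gamma tau) to a
#' single-angle intensity-intensity correlogram by least squares in linear
#' g2 space with uniform weights. Initial values come from a log-linear
#' regression of log(g2 - 1) on tau; lag points whose amplitude has decayed
#' below 1e-3 * beta are excluded so baseline noise does not dominate.
#'
#' @param correlogram A data frame with columns `lag_s` (strictly
#'   increasing, > 0) and `g2`.
#' @param q Scattering vector in 1/nm at which the correlogram was
#'   recorded (stored in the result; not used by the fit).
#' @return An object of class `decay_fit`: a list with `beta`, `gamma`
#'   (1/s), `q` (1/nm), `residual_rms` and `n_used`.
#' @examples
#' tau <- 10^seq(-6, 0, length.out = 100)
#' g2 <- 1 + 0.9 * exp(-2 * 1e4 * tau)
#' fit_monoexponential(data.frame(lag_s = tau, g2 = g2), q = 0.0179)
#' @export
fit_monoexponential <- function(correlogram, q = NA_real_) {
  stopifnot(is.data.frame(correlogram),
            all(c("lag_s", "g2") %in% names(correlogram)))
  tau <- correlogram$lag_s
  g2 <- correlogram$g2
  if (length(tau) < 10L) stop("need at least 10 lag points")
  if (any(!is.finite(tau)) || any(tau <= 0) || any(diff(tau) <= 0))
    stop("`lag_s` must be a strictly increasing positive grid")
  if (any(!is.finite(g2))) stop("`g2` must be finite")

  y <- g2 - 1
  n_short <- max(5L, length(y) %/% 10L)
  if (max(y[seq_len(n_short)]) <= 0)
    stop_fit_failure("correlogram shows no positive amplitude at short lags")

  ## log-linear initialization on the decaying part
  amp <- max(y)
  init_idx <- which(y > 0.05 * amp)
  if (length(init_idx) < 3L)
    stop_fit_failure("too few decaying points for initialization")
  lf <- stats::lm(log(y[init_idx]) ~ tau[init_idx])
  gamma0 <- -stats::coef(lf)[[2]] / 2
  beta0 <- exp(stats::coef(lf)[[1]])
  if (!is.finite(gamma0) || gamma0 <= 0)
    stop_fit_failure("no decaying component found (non-positive decay rate)")
  beta0 <- min(max(beta0, 1e-3), 1.5)

  ## exclude the noise-dominated baseline tail
  keep <- 1 + beta0 * exp(-2 * gamma0 * tau) - 1 > 1e-3 * beta0
  keep[seq_len(min(10L, length(keep)))] <- TRUE
  dat <- data.frame(tau = tau[keep], g2 = g2[keep])

  fit <- minpack.lm::nlsLM(
    g2 ~ 1 + beta * exp(-2 * gamma * tau),
    data = dat,
    start = list(beta = beta0, gamma = gamma0),
    lower = c(beta = 0, gamma = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  if (cf[["gamma"]] <= 0)
    stop_fit_failure("fitted decay rate is non-positive")
  if (cf[["beta"]] > 1)
    warning("fitted beta exceeds 1; the Siegert coherence factor should satisfy beta <= 1")

  structure(list(beta = cf[["beta"]],
                 gamma = cf[["gamma"]],
                 q = q,
                 residual_rms = sqrt(mean(stats::resid(fit)^2)),
                 n_used = nrow(dat)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Mono-exponential correlogram fit: beta = %.4f, Gamma = %.4g 1/s (q = %.4g 1/nm)\n",
              x$beta, x$gamma, x$q))
  invisible(x)
}

#' Diffusion coefficient from the angle dependence of the decay rate
#'
#' Regresses the per-angle decay rates Gamma on q^2. For free diffusion
#' Gamma = q^2 D with no intercept, so the headline diffusion coefficient is
#' the through-origin least-squares slope; a free-intercept fit is also
#' performed and the consistency of its intercept with zero reported as a
#' diagnostic.
#'
#' @param fits A list of `decay_fit` objects from at least 3 angles, each
#'   carrying a finite `q`.
#' @return A list with `diffusion` (m^2/s, through-origin slope),
#'   `diffusion_free` (slope with free intercept), `intercept`,
#'   `intercept_se` (1/s) and `intercept_consistent_zero` (logical, |t| < 2).
#' @export
fit_gamma_vs_q2 <- function(fits) {
  if (inherits(fits, "decay_fit")) fits <- list(fits)
  if (length(fits) < 3L)
    stop("need decay fits from at least 3 angles")
  gamma <- vapply(fits, function(f) f$gamma, numeric(1))
  q <- vapply(fits, function(f) f$q, numeric(1))
  if (any(!is.finite(q))) stop("every decay fit must carry a finite q")
  q2 <- (q * 1e9)^2  # 1/m^2
  if (diff(range(q2)) <= 0) stop("q^2 values must span a nonzero range")

  f0 <- stats::lm(gamma ~ 0 + q2)
  d0 <- stats::coef(f0)[[1]]
  if (d0 <= 0)
    stop_fit_failure("through-origin Gamma vs q^2 slope is non-positive")
  f1 <- stats::lm(gamma ~ q2)
  s1 <- suppressWarnings(summary(f1))$coefficients  # noiseless data fit exactly
  list(diffusion = d0,
       diffusion_free = stats::coef(f1)[[2]],
       intercept = s1[1, 1],
       intercept_se = s1[1, 2],
       intercept_consistent_zero = abs(s1[1, 1] / s1[1, 2]) < 2)
}

#' Hydrodynamic radius from a multi-angle correlogram set
#'
#' Runs the full dynamic light scattering pipeline: computes q at each
#' angle, fits each correlogram mono-exponentially, regresses Gamma on q^2
#' through the origin, and converts the slope to a hydrodynamic radius via
#' the Stokes-Einstein relation.
#'
#' @param correlograms A data frame with columns `angle_deg`, `lag_s`, `g2`
#'   covering at least 3 distinct angles.
#' @param solvent A [solvent_conditions()] object.
#' @param wavelength_nm Laser wavelength in nm.
#' @return A list with `r_h_nm`, `diffusion` (m^2/s), per-angle `fits`
#'   (list of `decay_fit`), and the `gamma_regression` diagnostics.
#' @export
hydrodynamic_radius <- function(correlograms,
                                solvent = solvent_conditions(),
                                wavelength_nm = 660) {
  stopifnot(is.data.frame(correlograms),
            all(c("angle_deg", "lag_s", "g2") %in% names(correlograms)))
  angles <- sort(unique(correlograms$angle_deg))
  if (length(angles) < 3L)
    stop("need correlograms at 3 or more angles")
  fits <- lapply(angles, function(a) {
    sub <- correlograms[correlograms$angle_deg == a, , drop = FALSE]
    q <- scattering_vector(a, wavelength_nm, solvent$refractive_index)
    tryCatch(fit_monoexponential(sub, q = q),
             error = function(e) {
               stop(sprintf("correlogram fit failed at angle %g deg: %s",
                            a, conditionMessage(e)), call. = FALSE)
             })
  })
  reg <- fit_gamma_vs_q2(fits)
  list(r_h_nm = stokes_einstein(reg$diffusion, solvent),
       diffusion = reg$diffusion,
       fits = fits,
       gamma_regression = reg)
}
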