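## Homogeneous-sphere scattering and pair-distance distribution analysis.

# Normalized sphere form-factor amplitude 3(sin x - x cos x)/x^3, with a
# series guard near x = 0 (limit 1) to avoid 0/0.
sphere_amplitude <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-2
  xs <- x[small]
  out[small] <- 1 - xs^2 / 10 + xs^4 / 280
  xl <- x[!small]
  out[!small] <- 3 * (sin(xl) - xl * cos(xl)) / xl^3
  out
}

#' Scattering intensity of a homogeneous sphere
#'
#' I(q) = I(0) * \[3 (sin(qR) - qR cos(qR)) / (qR)^3\]^2 + I_int, where the
#' flat term I_int captures the small residual intensity from the internal
#' structure of a protein assembly. The bracket tends to 1 as q -> 0
#' (evaluated by series, never 0/0), so I -> I(0) + I_int.
#'
#' @param q Scattering vector(s) in 1/nm.
#' @param radius Sphere radius in nm (> 0).
#' @param forward_intensity Forward intensity I(0) in 1/cm.
#' @param internal_background Flat internal-structure intensity in 1/cm.
#' @return Intensity in 1/cm, vectorized over `q`.
#' @export
sphere_intensity <- function(q, radius, forward_intensity,
                             internal_background = 0) {
  if (!is.finite(radius) || radius <= 0) stop("`radius` must be > 0")
  forward_intensity * sphere_amplitude(q * radius)^2 + internal_background
}

#' Fit the homogeneous-sphere model to a SAXS curve
#'
#' Weighted least-squares fit of [sphere_intensity()] over (R, I(0),
#' I_int). The form-factor oscillations create local minima in R, so the
#' fit multi-starts from a grid of radii (2-15 nm in 0.5 nm steps); at each
#' grid radius the two linear parameters are profiled out by weighted
#' linear least squares, and the best start is refined with
#' Levenberg-Marquardt. Weights are 1/sigma^2 when a positive `sigma`
#' column is present, else 1/I (Poisson-like).
#'
#' @param curve A data frame with columns `q` (1/nm, strictly increasing),
#'   `intensity` (1/cm) and optionally `sigma`.
#' @param q_max Upper q cutoff in 1/nm for the fit; the default 2.5 covers
#'   the first two form-factor oscillations of a 6 nm sphere while leaving
#'   out the high-q region where real assemblies deviate from the sharp-
#'   interface model.
#' @param radius_grid Multi-start radii in nm.
#' @return An object of class `sphere_fit`: list with `radius` (nm),
#'   `forward_intensity`, `internal_background` (1/cm), `goodness`
#'   (reduced chi-square) and `n_points`.
#' @export
fit_sphere <- function(curve, q_max = 2.5,
                       radius_grid = seq(2, 15, by = 0.5)) {
  stopifnot(is.data.frame(curve), all(c("q", "intensity") %in% names(curve)))
  sel <- curve$q <= q_max
  if (sum(sel) < 20L) stop("need at least 20 points below `q_max`")
  q <- curve$q[sel]
  I <- curve$intensity[sel]
  w <- if (!is.null(curve$sigma) && all(is.finite(curve$sigma[sel])) &&
           all(curve$sigma[sel] > 0)) {
    1 / curve$sigma[sel]^2
  } else {
    1 / pmax(abs(I), max(abs(I)) * 1e-12)
  }

  profile_rss <- function(R) {
    f2 <- sphere_amplitude(q * R)^2
    X <- cbind(f2, 1)
    fit <- stats::lm.wfit(X, I, w)
    cf <- pmax(fit$coefficients, 0)  # both linear parameters are intensities
    r <- I - X %*% cf
    list(rss = sum(w * r^2), I0 = unname(cf[1]), Iint = unname(cf[2]))
  }
  starts <- lapply(radius_grid, profile_rss)
  best <- which.min(vapply(starts, `[[`, numeric(1), "rss"))
  st <- starts[[best]]

  dat <- data.frame(q = q, I = I)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      I ~ sphere_intensity(q, R, I0, Iint),
      data = dat, weights = w,
      start = list(R = radius_grid[best], I0 = st$I0,
                   Iint = max(st$Iint, 0)),
      lower = c(R = 0.5, I0 = 0, Iint = 0),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) stop_fit_failure(
      paste("sphere model fit did not converge:", conditionMessage(e))))
  cf <- stats::coef(fit)

  # a curve carrying no form-factor signal cannot constrain R
  mean_level <- stats::weighted.mean(I, w)
  if (cf[["I0"]] <= 1e-6 * max(mean_level, cf[["Iint"]]))
    stop_fit_failure("no form-factor signal above background: radius unidentifiable")

  rss <- sum(w * stats::resid(fit)^2)
  structure(list(radius = cf[["R"]],
                 forward_intensity = cf[["I0"]],
                 internal_background = cf[["Iint"]],
                 goodness = rss / (length(q) - 3),
                 n_points = length(q)),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("Homogeneous-sphere fit: R = %.3f nm, I(0) = %.4g 1/cm, I_int = %.4g 1/cm (red. chi^2 = %.3g)\n",
              x$radius, x$forward_intensity, x$internal_background, x$goodness))
  invisible(x)
}

#' Analytic pair-distance distribution function of a homogeneous sphere
#'
#' With x = r/R, p(r) is proportional to x^2 (1 - (3/4) x + (1/16) x^3) on
#' 0 <= x <= 2 and zero outside; the output is normalized to unit maximum
#' (the peak sits at r ~= 1.05 R).
#'
#' @param r Distances in nm (vectorized).
#' @param radius Sphere radius in nm.
#' @return Normalized p(r) values.
#' @export
sphere_pddf <- function(r, radius) {
  if (!is.finite(radius) || radius <= 0) stop("`radius` must be > 0")
  x <- r / radius
  p <- ifelse(x >= 0 & x <= 2, x^2 * (1 - 0.75 * x + x^3 / 16), 0)
  # peak location: real root of 2 - 2.25 x + 0.3125 x^3 in (0, 2)
  xs <- Re(polyroot(c(2, -2.25, 0, 0.3125)))
  x_peak <- xs[which(abs(Im(polyroot(c(2, -2.25, 0, 0.3125)))) < 1e-8 &
                       xs > 0 & xs < 2)][1]
  p_max <- x_peak^2 * (1 - 0.75 * x_peak + x_peak^3 / 16)
  p / p_max
}

#' Estimate the pair-distance distribution function by regularized IFT
#'
#' Indirect Fourier transform of a measured SAXS curve: p(r) is represented
#' on an r grid in \[0, d_max\] with fixed endpoints p(0) = p(d_max) = 0 and
#' estimated by nonnegative least squares against the forward model
#' I(q) = 4 pi sum_j p(r_j) sinc(q r_j) dr, with a second-difference
#' smoothness penalty. When `smoothness` is NULL the penalty is chosen by
#' an L-curve-style scan: the largest penalty whose chi-square stays within
#' 50% of the minimum over the scan.
#'
#' @param curve A data frame with columns `q`, `intensity`, optionally
#'   `sigma`. The low-q end must satisfy q_min * d_max <= pi.
#' @param d_max Assumed maximum particle dimension in nm.
#' @param n_points Number of r-grid points (default 101).
#' @param smoothness Dimensionless penalty weight, or NULL to scan.
#' @return An object of class `pddf`: list with `r` (nm), `p` (normalized
#'   to unit maximum), `d_max`, `smoothness`, `chisq` (reduced), `I_fit`
#'   (forward model on the data grid) and `misfit_flag` (TRUE when the
#'   reduced chi-square indicates the assumed d_max cannot describe the
#'   data).
#' @export
estimate_pddf <- function(curve, d_max, n_points = 101, smoothness = NULL) {
  stopifnot(is.data.frame(curve), all(c("q", "intensity") %in% names(curve)))
  if (!is.finite(d_max) || d_max <= 0) stop("`d_max` must be > 0")
  q <- curve$q
  I <- curve$intensity
  if (min(q) * d_max > pi)
    stop("curve does not reach low enough q for this d_max (need q_min * d_max <= pi)")
  sig <- if (!is.null(curve$sigma) && all(is.finite(curve$sigma)) &&
             all(curve$sigma > 0)) curve$sigma else pmax(abs(I), max(abs(I)) * 1e-6) * 0.01
  w <- 1 / sig

  r <- seq(0, d_max, length.out = n_points)
  dr <- r[2] - r[1]
  interior <- 2:(n_points - 1)
  qr <- outer(q, r[interior])
  sinc <- ifelse(qr == 0, 1, sin(qr) / qr)
  A <- 4 * pi * sinc * dr            # nq x (n_points - 2)
  Aw <- A * w

  m <- length(interior)
  D2 <- diag(m)
  D2 <- diff(diff(D2))               # (m - 2) x m second differences
  scale_ratio <- norm(Aw, "F") / norm(D2, "F")

  solve_one <- function(lam) {
    C <- rbind(Aw, sqrt(lam) * scale_ratio * D2)
    d <- c(I * w, numeric(nrow(D2)))
    p_int <- pracma::lsqnonneg(C, d)$x
    I_fit <- as.vector(A %*% p_int)
    chisq <- sum(((I - I_fit) * w)^2) / length(I)
    list(p_int = p_int, I_fit = I_fit, chisq = chisq, smoothness = lam)
  }

  if (is.null(smoothness)) {
    lams <- 10^seq(-6, 0, length.out = 9)
    sols <- lapply(lams, solve_one)
    chis <- vapply(sols, `[[`, numeric(1), "chisq")
    ok <- which(chis <= 1.5 * min(chis))
    sol <- sols[[max(ok)]]
  } else {
    if (smoothness < 0) stop("`smoothness` must be >= 0")
    sol <- solve_one(smoothness)
    if (!all(is.finite(sol$p_int)))
      stop_fit_failure("ill-conditioned IFT system; increase `smoothness`")
  }

  p <- c(0, sol$p_int, 0)
  pmx <- max(p)
  if (pmx <= 0) stop_fit_failure("IFT returned an identically zero p(r)")
  structure(list(r = r,
                 p = p / pmx,
                 d_max = d_max,
                 smoothness = sol$smoothness,
                 chisq = sol$chisq,
                 I_fit = sol$I_fit,
                 scale = pmx,
                 misfit_flag = sol$chisq > 10),
            class = "pddf")
}

#' Forward scattering model of an estimated p(r)
#'
#' Evaluates I(q) = 4 pi sum p(r) sinc(q r) dr for a [estimate_pddf()]
#' result (un-normalized internal scale), used for self-consistency checks.
#'
#' @param pddf A `pddf` object.
#' @param q Scattering vectors in 1/nm.
#' @return Model intensities in 1/cm.
#' @export
pddf_forward <- function(pddf, q) {
  stopifnot(inherits(pddf, "pddf"))
  dr <- pddf$r[2] - pddf$r[1]
  qr <- outer(q, pddf$r)
  sinc <- ifelse(qr == 0, 1, sin(qr) / qr)
  as.vector(4 * pi * (sinc %*% (pddf$p * pddf$scale)) * dr)
}

#' Protein volume fraction inside a spherical assembly
#'
#' f = N M_w / (N_A rho (4/3) pi R^3): the dry protein volume of N
#' monomers relative to the volume of the bounding sphere. Values near 0.5
#' indicate an assembly that is roughly half water.
#'
#' @param aggregation_number Monomers per assembly (>= 0).
#' @param protein A [protein_params()] object (molar mass, density).
#' @param radius_nm Sphere radius in nm.
#' @return Dimensionless volume fraction.
#' @export
volume_fraction <- function(aggregation_number,
                            protein = protein_params(),
                            radius_nm) {
  if (aggregation_number < 0) stop("`aggregation_number` must be >= 0")
  if (radius_nm <= 0) stop("`radius_nm` must be > 0")
  v_sphere_cm3 <- 4 / 3 * pi * (radius_nm * 1e-7)^3
  aggregation_number * protein$monomer_molar_mass /
    (os_constants$avogadro * protein$mass_density * v_sphere_cm3)
}

#' Normalize SAXS curves by sample concentration
#'
#' Divides intensity (and sigma) of each curve by its concentration so
#' that curves from assemblies of concentration-independent size and shape
#' collapse onto one master curve. The collapse is quantified as the
#' maximum pairwise RMS difference of log-intensities.
#'
#' @param curves A list of SAXS data frames, each with columns `q`,
#'   `intensity`, optionally `sigma`, and a `concentration` column or
#'   attribute (same q grid across curves).
#' @return A list with `curves` (normalized data frames) and
#'   `collapse_metric` (max pairwise RMS log-intensity difference).
#' @export
normalize_by_concentration <- function(curves) {
  stopifnot(is.list(curves), length(curves) >= 1L)
  conc <- vapply(curves, function(cv) {
    cc <- if (!is.null(cv$concentration)) cv$concentration[1] else attr(cv, "concentration")
    if (is.null(cc) || !is.finite(cc) || cc <= 0)
      stop("every curve must carry a positive concentration")
    cc
  }, numeric(1))
  norm <- Map(function(cv, cc) {
    cv$intensity <- cv$intensity / cc
    if (!is.null(cv$sigma)) cv$sigma <- cv$sigma / cc
    cv
  }, curves, conc)
  metric <- 0
  if (length(norm) > 1L) {
    for (i in seq_along(norm)[-length(norm)]) {
      for (j in (i + 1):length(norm)) {
        li <- log(pmax(norm[[i]]$intensity, 1e-300))
        lj <- log(pmax(norm[[j]]$intensity, 1e-300))
        metric <- max(metric, sqrt(mean((li - lj)^2)))
      }
    }
  }
  list(curves = norm, collapse_metric = metric)
}
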