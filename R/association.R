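#' Closed-association model parameters
#'
#' The closed association model describes subunits (here dimers, two
#' monomers each) in equilibrium with a single preferred N-mer governed by
#' one association constant K = c_N / c_s^N, with concentrations in nM.
#' Defaults encode the model used for alpha-B-crystallin: K = 1e-4 nM^-8,
#' 9 dimeric subunits per oligomer (18 monomers), subunit and oligomer
#' hydrodynamic radii 5 and 7 nm.
#'
#' @param assoc_constant Association constant K in nM^-(N-1), N =
#'   `subunits_per_oligomer`.
#' @param subunits_per_oligomer Number of subunits per oligomer (>= 2).
#' @param monomers_per_subunit Monomers per irreducible subunit (2 for a
#'   dimer).
#' @param r_h_subunit,r_h_oligomer Hydrodynamic radii in nm, with
#'   `r_h_oligomer > r_h_subunit > 0`.
#' @return An object of class `association_params`.
#' @export
association_params <- function(assoc_constant = 1e-4,
                               subunits_per_oligomer = 9,
                               monomers_per_subunit = 2,
                               r_h_subunit = 5,
                               r_h_oligomer = 7) {
  if (assoc_constant <= 0) stop("`assoc_constant` must be > 0")
  if (subunits_per_oligomer < 2) stop("`subunits_per_oligomer` must be >= 2")
  if (monomers_per_subunit < 1) stop("`monomers_per_subunit` must be >= 1")
  if (!(r_h_oligomer > r_h_subunit && r_h_subunit > 0))
    stop("need r_h_oligomer > r_h_subunit > 0")
  structure(list(assoc_constant = assoc_constant,
                 subunits_per_oligomer = as.integer(subunits_per_oligomer),
                 monomers_per_subunit = as.integer(monomers_per_subunit),
                 r_h_subunit = r_h_subunit,
                 r_h_oligomer = r_h_oligomer),
            class = "association_params")
}

#' Solve mass-action speciation of the closed association model
#'
#' Finds the unique subunit concentration c_s satisfying the mass balance
#' c = m (c_s + N K c_s^N), where m is the number of monomers per subunit
#' (so total concentration is counted in monomers) and c_N = K c_s^N.
#' Solved by Newton iteration on u = log(c_s) with a log-sum-exp guard, so
#' large concentrations do not overflow; converged to relative tolerance
#' below 1e-12.
#'
#' @param total_monomer_conc Total protein concentration in nM of monomer
#'   (>= 0); vectorized.
#' @param params An [association_params()] object.
#' @return A data frame with columns `total_monomer_conc`, `subunit_conc`
#'   (c_s, nM), `oligomer_conc` (c_N, nM), `subunit_mass_fraction` and
#'   `oligomer_mass_fraction`.
#' @export
solve_speciation <- function(total_monomer_conc,
                             params = association_params()) {
  if (any(!is.finite(total_monomer_conc)) || any(total_monomer_conc < 0))
    stop("`total_monomer_conc` must be >= 0")
  K <- params$assoc_constant
  N <- params$subunits_per_oligomer
  m <- params$monomers_per_subunit

  solve_one <- function(ctot) {
    if (ctot == 0) return(c(cs = 0, cN = 0))
    lc <- log(ctot)
    # f(u) = log(m e^u + m N K e^(N u)) - log(ctot), monotone increasing in u
    la <- log(m)             # subunit branch: la + u
    lb <- log(m * N * K)     # oligomer branch: lb + N u
    u <- min(lc - la, (lc - lb) / N)  # start below the root
    for (it in 1:200) {
      t1 <- la + u
      t2 <- lb + N * u
      mx <- max(t1, t2)
      s <- exp(t1 - mx) + exp(t2 - mx)
      f <- mx + log(s) - lc
      df <- (exp(t1 - mx) + N * exp(t2 - mx)) / s
      step <- f / df
      u <- u - step
      if (abs(step) < 1e-15) break
    }
    cs <- exp(u)
    c(cs = cs, cN = K * cs^N)
  }

  sol <- vapply(total_monomer_conc, solve_one, numeric(2))
  cs <- sol["cs", ]
  cN <- sol["cN", ]
  # fractions computed directly from both species (not as 1 - w) so tiny
  # oligomer fractions keep full relative precision; normalized to sum 1
  tot <- m * (cs + N * cN)
  ws <- ifelse(tot > 0, cs / (cs + N * cN), 1)
  data.frame(total_monomer_conc = total_monomer_conc,
             subunit_conc = cs,
             oligomer_conc = cN,
             subunit_mass_fraction = ws,
             oligomer_mass_fraction = ifelse(tot > 0, N * cN / (cs + N * cN), 0))
}

#' Mean hydrodynamic radius of a bimodal subunit/oligomer mixture
#'
#' The size read out by a mass-transport measurement on a bimodal mixture
#' is the mass-weighted harmonic mean of the two species' radii (diffusion
#' coefficients average linearly in mass):
#' <R_H> = 1 / (w_s / R_Hs + w_N / R_HN),
#' with mass fractions from [solve_speciation()]. It rises monotonically
#' from the subunit radius at low concentration to the oligomer radius at
#' high concentration.
#'
#' @param total_monomer_conc Total concentration(s) in nM of monomer.
#' @param params An [association_params()] object.
#' @return Mean hydrodynamic radius in nm (vectorized).
#' @export
mean_hydrodynamic_radius <- function(total_monomer_conc,
                                     params = association_params()) {
  sp <- solve_speciation(total_monomer_conc, params)
  1 / (sp$subunit_mass_fraction / params$r_h_subunit +
         sp$oligomer_mass_fraction / params$r_h_oligomer)
}

#' Onset concentration of self-assembly
#'
#' Operational definition: the smallest total monomer concentration at
#' which the oligomer mass fraction reaches `threshold` (default 10%).
#' Found by monotone root bracketing on the speciation curve; the analytic
#' concentration scale (1/K)^(1/(N-1)) (in subunit units) is reported
#' alongside for reference.
#'
#' @param params An [association_params()] object.
#' @param oligomer_mass_threshold Mass-fraction threshold in (0, 1).
#' @return A list with `c_agg_nM` (total monomer concentration) and
#'   `scale_nM` (analytic subunit-concentration scale).
#' @export
onset_concentration <- function(params = association_params(),
                                oligomer_mass_threshold = 0.1) {
  t <- oligomer_mass_threshold
  if (!is.finite(t) || t <= 0 || t >= 1)
    stop("`oligomer_mass_threshold` must lie in (0, 1)")
  K <- params$assoc_constant
  N <- params$subunits_per_oligomer
  scale <- (1 / K)^(1 / (N - 1))
  f <- function(lc) {
    solve_speciation(exp(lc), params)$oligomer_mass_fraction - t
  }
  lo <- log(scale) - 40
  hi <- log(scale) + 40
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-13)
  list(c_agg_nM = exp(root$root), scale_nM = scale)
}

#' Fit the association constant to diffusional-sizing data
#'
#' Least-squares fit of the model mean hydrodynamic radius
#' ([mean_hydrodynamic_radius()]) to replicate-averaged measured radii,
#' over log10(K) for conditioning. The objective is profiled on a log10(K)
#' grid (returned, so flatness of the fit is visible) and the minimum is
#' polished by golden-section search. Data lying entirely on one plateau
#' cannot constrain K; such fits are flagged as unidentifiable with a
#' one-sided bound.
#'
#' @param data A data frame with columns `conc_nM` (total monomer, nM) and
#'   `r_h_nm` (replicate measurements; replicates are averaged per
#'   concentration).
#' @param params An [association_params()] object supplying the fixed
#'   shape parameters (N, subunit/oligomer radii); its `assoc_constant` is
#'   ignored.
#' @param log10K_grid Grid over which the objective is profiled.
#' @return A list with `assoc_constant`, `log10K`, `profile` (data frame
#'   `log10K`, `rss`), `identifiable` (logical) and `bound` (`NA`, or
#'   `"upper"`/`"lower"` when only a one-sided bound is supported).
#' @export
fit_association_constant <- function(data,
                                     params = association_params(),
                                     log10K_grid = seq(-8, 0, by = 0.1)) {
  stopifnot(is.data.frame(data), all(c("conc_nM", "r_h_nm") %in% names(data)))
  agg <- stats::aggregate(r_h_nm ~ conc_nM, data = data, FUN = mean)
  conc <- agg$conc_nM
  robs <- agg$r_h_nm
  if (length(conc) < 3L) stop("need at least 3 distinct concentrations")

  obj <- function(l10K) {
    p <- params
    p$assoc_constant <- 10^l10K
    sum((mean_hydrodynamic_radius(conc, p) - robs)^2)
  }
  rss <- vapply(log10K_grid, obj, numeric(1))
  profile <- data.frame(log10K = log10K_grid, rss = rss)
  i_min <- which.min(rss)

  # data on a single plateau (radii spanning < 10% of the subunit-oligomer
  # contrast) or a boundary/flat profile cannot pin K down
  span <- diff(range(robs))
  contrast <- params$r_h_oligomer - params$r_h_subunit
  one_plateau <- span < 0.1 * contrast
  flat <- (max(rss) - min(rss)) < 1e-9 * max(max(rss), 1e-12)
  at_boundary <- i_min %in% c(1L, length(log10K_grid))
  if (one_plateau || flat || at_boundary) {
    bound <- if (one_plateau) {
      midpoint <- (params$r_h_oligomer + params$r_h_subunit) / 2
      if (mean(robs) > midpoint) "lower" else "upper"
    } else if (flat) NA_character_
    else if (i_min == 1L) "upper" else "lower"
    return(list(assoc_constant = 10^log10K_grid[i_min],
                log10K = log10K_grid[i_min],
                profile = profile,
                identifiable = FALSE,
                bound = bound))
  }

  opt <- stats::optimize(obj,
                         lower = log10K_grid[max(1L, i_min - 2L)],
                         upper = log10K_grid[min(length(log10K_grid), i_min + 2L)],
                         tol = 1e-10)
  list(assoc_constant = 10^opt$minimum,
       log10K = opt$minimum,
       profile = profile,
       identifiable = TRUE,
       bound = NA_character_)
}

#' Correct nominal concentrations for surface adsorption losses
#'
#' Dilute samples lose protein to tube and chip surfaces; the measured
#' fluorescence intensity tracks the true concentration. A linear
#' regression of replicate- and timepoint-averaged intensity on nominal
#' concentration over the calibration range (where losses are negligible)
#' provides an intensity-to-concentration map; samples below the
#' calibration range get corrected concentrations by inverse regression of
#' their mean intensities, while calibration samples keep nominal values.
#'
#' @param data A data frame with columns `conc_nM_nominal`, `intensity`
#'   and optionally `day`/`replicate`.
#' @param calibration_range Numeric length-2: concentration window in nM
#'   assumed loss-free (default 1000-8000 nM).
#' @return The input data frame with an added `conc_nM_corrected` column,
#'   plus attributes `calibration_slope` and `calibration_intercept`.
#' @export
correct_concentrations <- function(data,
                                   calibration_range = c(1000, 8000)) {
  stopifnot(is.data.frame(data),
            all(c("conc_nM_nominal", "intensity") %in% names(data)))
  mean_int <- stats::aggregate(intensity ~ conc_nM_nominal, data = data,
                               FUN = mean)
  in_cal <- mean_int$conc_nM_nominal >= calibration_range[1] &
    mean_int$conc_nM_nominal <= calibration_range[2]
  if (sum(in_cal) < 2L)
    stop("need at least 2 samples inside the calibration range")
  fit <- stats::lm(intensity ~ conc_nM_nominal, data = mean_int[in_cal, ])
  slope <- stats::coef(fit)[[2]]
  intercept <- stats::coef(fit)[[1]]
  if (slope <= 0)
    stop_fit_failure("intensity does not increase with concentration; calibration failed")

  corr_map <- ifelse(mean_int$conc_nM_nominal < calibration_range[1],
                     (mean_int$intensity - intercept) / slope,
                     mean_int$conc_nM_nominal)
  data$conc_nM_corrected <-
    corr_map[match(data$conc_nM_nominal, mean_int$conc_nM_nominal)]
  attr(data, "calibration_slope") <- slope
  attr(data, "calibration_intercept") <- intercept
  data
}

#' Pool replicate radii over a concentration plateau
#'
#' Pools all replicate hydrodynamic radii of all samples inside a
#' concentration window into one mean and sample standard deviation, as
#' used for the high- (1-8 uM) and low- (1-4 nM) concentration plateaus of
#' a dilution series.
#'
#' @param data A data frame with columns `conc_nM` and `r_h_nm`.
#' @param conc_range Numeric length-2 window in nM (inclusive).
#' @return A list with `mean`, `sd` (nm) and `n` (replicates pooled).
#' @export
pool_plateau <- function(data, conc_range) {
  stopifnot(is.data.frame(data), all(c("conc_nM", "r_h_nm") %in% names(data)))
  sel <- data$conc_nM >= conc_range[1] & data$conc_nM <= conc_range[2]
  vals <- data$r_h_nm[sel]
  if (length(vals) < 2L)
    stop("fewer than 2 replicate values inside `conc_range`")
  list(mean = mean(vals), sd = stats::sd(vals), n = length(vals))
}

#' Full microfluidic diffusional sizing analysis
#'
#' Applies the adsorption concentration correction, fits the association
#' constant of the closed association model, locates the onset
#' concentration at the fitted K, and pools the low- and high-concentration
#' plateaus.
#'
#' @param data A data frame with columns `conc_nM_nominal`, `replicate`,
#'   `r_h_nm`, `intensity`, optionally `day`.
#' @param params An [association_params()] object fixing N and the two
#'   radii.
#' @param calibration_range Loss-free window in nM for
#'   [correct_concentrations()].
#' @param low_plateau,high_plateau Concentration windows (nM) pooled by
#'   [pool_plateau()].
#' @return A list with `data` (corrected), `fit`
#'   ([fit_association_constant()] result), `onset`
#'   ([onset_concentration()] at the fitted K), `low_plateau` and
#'   `high_plateau` summaries.
#' @export
analyze_mds <- function(data,
                        params = association_params(),
                        calibration_range = c(1000, 8000),
                        low_plateau = c(1, 4),
                        high_plateau = c(1000, 8000)) {
  corrected <- correct_concentrations(data, calibration_range)
  fit_df <- data.frame(conc_nM = corrected$conc_nM_corrected,
                       r_h_nm = corrected$r_h_nm)
  # inverse regression can push the most dilute samples to non-positive
  # concentrations; those carry no usable abscissa for the K fit
  fit_df <- fit_df[is.finite(fit_df$conc_nM) & fit_df$conc_nM > 0, ]
  fit <- fit_association_constant(fit_df, params)
  p_hat <- params
  p_hat$assoc_constant <- fit$assoc_constant
  # plateaus are pooled by nominal concentration: the correction's
  # calibration noise would otherwise scatter the dilute samples out of
  # their window
  pool_df <- data.frame(conc_nM = corrected$conc_nM_nominal,
                        r_h_nm = corrected$r_h_nm)
  list(data = corrected,
       fit = fit,
       onset = onset_concentration(p_hat),
       low_plateau = pool_plateau(pool_df, low_plateau),
       high_plateau = pool_plateau(pool_df, high_plateau))
}
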