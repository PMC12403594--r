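test_that("speciation matches an independent bisection oracle", {
  p <- association_params(assoc_constant = 1e-4, subunits_per_oligomer = 9)
  sp <- solve_speciation(1000, p)
  cs_oracle <- oracle_subunit_conc(1000, 1e-4, 9)
  expect_equal(sp$subunit_conc, cs_oracle, tolerance = 1e-8)
  expect_equal(sp$subunit_conc, 4.344, tolerance = 1e-3)
  expect_equal(sp$oligomer_mass_fraction, 0.991, tolerance = 1e-3)

  # more oracle points across regimes and parameterizations
  for (case in list(c(c = 1, K = 1e-4, N = 9),
                    c(c = 4, K = 1e-4, N = 9),
                    c(c = 1e5, K = 1e-4, N = 9),
                    c(c = 50, K = 1e-6, N = 12))) {
    pc <- association_params(assoc_constant = case[["K"]],
                             subunits_per_oligomer = case[["N"]])
    sp <- solve_speciation(case[["c"]], pc)
    expect_equal(sp$subunit_conc,
                 oracle_subunit_conc(case[["c"]], case[["K"]], case[["N"]]),
                 tolerance = 1e-8)
  }
})

test_that("speciation obeys mass balance, limits and monotonicity", {
  p <- association_params()
  # K -> 0: everything stays subunit (K deep below 1/c_s^(N-1))
  weak <- association_params(assoc_constant = 1e-40)
  sp0 <- solve_speciation(1000, weak)
  expect_equal(sp0$subunit_conc, 500, tolerance = 1e-12)
  expect_equal(sp0$oligomer_mass_fraction, 0, tolerance = 1e-12)

  # mass balance < 1e-10 relative over 8 decades, no overflow in log-space
  cgrid <- 10^seq(-2, 6, length.out = 300)
  sp <- solve_speciation(cgrid, p)
  resid <- abs(2 * (sp$subunit_conc + 9 * sp$oligomer_conc) - cgrid) / cgrid
  expect_lt(max(resid), 1e-10)
  expect_true(all(sp$subunit_mass_fraction >= 0 & sp$subunit_mass_fraction <= 1))
  expect_equal(sp$subunit_mass_fraction + sp$oligomer_mass_fraction,
               rep(1, length(cgrid)))
  # monotone speciation curves (up to double-precision jitter)
  expect_true(all(diff(sp$subunit_conc) >= 0))
  expect_true(all(diff(sp$oligomer_conc) >= 0))
  expect_true(all(diff(sp$oligomer_mass_fraction) >= -1e-12))
  expect_error(solve_speciation(-1, p), ">= 0")
})

test_that("mean hydrodynamic radius is the mass-weighted harmonic mean with correct limits", {
  p <- association_params()
  # low-concentration limit: subunit radius
  expect_equal(mean_hydrodynamic_radius(0.1, p), 5.0, tolerance = 1e-3 / 5)
  # high-concentration plateau: 7.0 nm within 0.05 at 8 uM
  expect_equal(mean_hydrodynamic_radius(8000, p), 7.0, tolerance = 0.05 / 7)
  # equal mass fractions of 5 and 7 nm species: 35/6 nm
  expect_equal(1 / (0.5 / 5 + 0.5 / 7), 35 / 6)
  # monotone nondecreasing and bounded on [r_s, r_N]
  rh <- mean_hydrodynamic_radius(10^seq(-2, 5, length.out = 200), p)
  expect_true(all(diff(rh) >= -1e-12))
  expect_true(all(rh >= 5 - 1e-9 & rh <= 7 + 1e-9))
})

test_that("onset concentration agrees with the closed-form rearrangement", {
  p <- association_params()
  onset <- onset_concentration(p, oligomer_mass_threshold = 0.1)
  expect_equal(onset$c_agg_nM, oracle_onset(1e-4, 9, 0.1), tolerance = 1e-8)
  expect_equal(onset$c_agg_nM, 4.06, tolerance = 1e-2)
  expect_equal(onset$scale_nM, (1 / 1e-4)^(1 / 8))

  # strictly decreasing in K at fixed N and threshold
  onsets <- vapply(c(1e-5, 1e-4, 1e-3), function(K) {
    onset_concentration(association_params(assoc_constant = K))$c_agg_nM
  }, numeric(1))
  expect_true(all(diff(onsets) < 0))
  # the onset falls toward zero as the threshold does, following the
  # closed-form t^(1/(N-1)) scaling
  for (t in c(1e-12, 1e-6, 1e-3)) {
    expect_equal(onset_concentration(p, t)$c_agg_nM, oracle_onset(1e-4, 9, t),
                 tolerance = 1e-8)
  }
  expect_lt(onset_concentration(p, 1e-12)$c_agg_nM,
            0.2 * onset_concentration(p, 0.1)$c_agg_nM)
  expect_error(onset_concentration(p, 1.2), "threshold")
})

test_that("association constant is recovered exactly from noiseless data", {
  p <- association_params()
  g <- gen_mds(params = p, replicate_sd = 0, intensity_noise_frac = 0, seed = 1)
  d <- data.frame(conc_nM = g$data$conc_nM_nominal, r_h_nm = g$data$r_h_nm)
  fit <- fit_association_constant(d, p)
  expect_true(fit$identifiable)
  expect_equal(fit$log10K, -4, tolerance = 1e-6)
  # the profile is returned for flatness inspection
  expect_true(all(c("log10K", "rss") %in% names(fit$profile)))
  expect_gt(nrow(fit$profile), 10)
})

test_that("plateau-only data yield an unidentifiable flag with a one-sided bound", {
  p <- association_params()
  g <- gen_mds(params = p, replicate_sd = 0.1, seed = 2)
  d <- data.frame(conc_nM = g$data$conc_nM_nominal, r_h_nm = g$data$r_h_nm)
  high <- d[d$conc_nM >= 1000, ]
  fit <- fit_association_constant(high, p)
  expect_false(fit$identifiable)
  expect_equal(fit$bound, "lower")
})

test_that("concentration correction restores adsorption losses", {
  p <- association_params()
  # intensities exactly proportional to nominal concentration: identity
  g0 <- gen_mds(params = p, intensity_noise_frac = 0, seed = 3)
  c0 <- correct_concentrations(g0$data)
  expect_equal(c0$conc_nM_corrected, c0$conc_nM_nominal)

  # 30% loss below 100 nM, noiseless intensities: exact recovery
  g1 <- gen_mds(params = p, adsorption_loss = c(100, 0.3),
                intensity_noise_frac = 0, seed = 3)
  c1 <- correct_concentrations(g1$data)
  expect_equal(c1$conc_nM_corrected[c1$replicate == 1],
               g1$truth$true_conc_nM, tolerance = 1e-10)

  # with intensity noise the recovery is consistent with the calibration
  # uncertainty propagated through the inverse regression
  errs <- vapply(1:10, function(s) {
    g <- gen_mds(params = p, adsorption_loss = c(100, 0.3), seed = s)
    corr <- correct_concentrations(g$data)
    max(abs(corr$conc_nM_corrected[corr$replicate == 1] - g$truth$true_conc_nM))
  }, numeric(1))
  expect_lt(median(errs), 10)  # nM; intercept SE is a few nM at 0.2% noise

  # a single calibration sample is rejected
  sub <- g0$data[g0$data$conc_nM_nominal <= 1000, ]
  expect_error(correct_concentrations(sub), "at least 2 samples")
  # decreasing intensity with concentration is a calibration failure
  bad <- g0$data
  bad$intensity <- -bad$intensity
  expect_error(correct_concentrations(bad), class = "os_fit_failure")
})

test_that("plateau pooling returns pooled mean, SD and count", {
  d <- data.frame(conc_nM = rep(c(1000, 3000, 5000, 8000), each = 3),
                  r_h_nm = rep(7, 12))
  res <- pool_plateau(d, c(1000, 8000))
  expect_equal(res$mean, 7)
  expect_equal(res$sd, 0)
  expect_equal(res$n, 12)

  set.seed(5)
  d$r_h_nm <- rnorm(12, mean = 7, sd = 0.3)
  res2 <- pool_plateau(d, c(1000, 8000))
  expect_lt(abs(res2$mean - 7), 3 * 0.3 / sqrt(12))
  expect_lt(abs(res2$sd - 0.3), 0.2)

  expect_error(pool_plateau(d, c(10, 20)), "fewer than 2")
})

test_that("end-to-end diffusional sizing analysis ties the stages together", {
  p <- association_params()
  g <- gen_mds(params = p, adsorption_loss = c(100, 0.3), seed = 8)
  res <- analyze_mds(g$data, p)
  expect_true(res$fit$identifiable)
  expect_lt(abs(res$fit$log10K + 4), 1.5)
  expect_lt(abs(res$high_plateau$mean - 7.0), 0.3)
  expect_lt(abs(res$low_plateau$mean - 5.0), 0.5)
  expect_gt(res$onset$c_agg_nM, 0.5)
  expect_lt(res$onset$c_agg_nM, 40)
})
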