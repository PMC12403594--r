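test_that("mono-exponential fit inverts its own model and flags degenerate traces", {
  tau <- 10^seq(-6, 0, length.out = 200)
  g2 <- 1 + 0.9 * exp(-2 * 1e4 * tau)
  fit <- fit_monoexponential(data.frame(lag_s = tau, g2 = g2), q = 0.018)
  expect_equal(fit$beta, 0.9, tolerance = 1e-3)
  expect_equal(fit$gamma, 1e4, tolerance = 1e-3)
  expect_lt(fit$residual_rms, 1e-8)

  # flat correlogram: no decay to fit
  flat <- data.frame(lag_s = tau, g2 = rep(1, length(tau)))
  expect_error(fit_monoexponential(flat), class = "os_fit_failure")
  # too few points is a precondition violation, not a fit failure
  expect_error(fit_monoexponential(data.frame(lag_s = tau[1:5], g2 = g2[1:5])),
               "10 lag points")
})

test_that("decay rate at 90 degrees matches Gamma = q^2 D for a 7.4 nm particle", {
  g <- gen_dls(r_h_nm = 7.4, angles_deg = 90, noise_sd = 0, seed = 1)
  q <- scattering_vector(90, 660, 1.33)
  fit <- fit_monoexponential(g$data, q = q)
  expect_equal(fit$gamma, 1.066e4, tolerance = 1e-3)
})

test_that("Gamma vs q^2 regression recovers D and enforces its preconditions", {
  q <- scattering_vector(seq(60, 140, by = 20), 660, 1.33)
  D0 <- 3e-11
  fits <- lapply(q, function(qi) make_decay_fit(gamma = (qi * 1e9)^2 * D0, q = qi))
  reg <- fit_gamma_vs_q2(fits)
  expect_equal(reg$diffusion, D0, tolerance = 1e-12)

  expect_error(fit_gamma_vs_q2(fits[1]), "3 angles")
  neg <- lapply(q, function(qi) make_decay_fit(gamma = -(qi * 1e9)^2 * D0, q = qi))
  expect_error(fit_gamma_vs_q2(neg), class = "os_fit_failure")
})

test_that("recovered D is stable across angle subsets at 1% decay-rate noise", {
  set.seed(42)
  angles <- seq(60, 140, by = 5)
  q <- scattering_vector(angles, 660, 1.33)
  D0 <- 3.3e-11
  gam <- (q * 1e9)^2 * D0 * (1 + rnorm(length(q), sd = 0.01))
  fits <- Map(make_decay_fit, gam, q)
  reg_all <- fit_gamma_vs_q2(fits)
  d_all <- reg_all$diffusion
  # with noisy decay rates the free intercept is consistent with zero
  expect_true(reg_all$intercept_consistent_zero)
  subsets <- list(1:3, c(1, 9, 17), 15:17, seq(1, 17, by = 2))
  for (idx in subsets) {
    d_sub <- fit_gamma_vs_q2(fits[idx])$diffusion
    expect_equal(d_sub, d_all, tolerance = 0.02)
  }
})

test_that("full DLS pipeline recovers the generating radius", {
  # noiseless: exact to < 0.1%
  g0 <- gen_dls(r_h_nm = 7.4, noise_sd = 0, seed = 1)
  expect_equal(hydrodynamic_radius(g0$data)$r_h_nm, 7.4, tolerance = 1e-3)
  # 1% additive g2 noise, fixed seed: within 0.1 nm of 7.0
  g1 <- gen_dls(r_h_nm = 7.0, noise_sd = 0.01, seed = 7)
  expect_equal(hydrodynamic_radius(g1$data)$r_h_nm, 7.0, tolerance = 0.1 / 7.0)
  expect_error(hydrodynamic_radius(g0$data[g0$data$angle_deg < 70, ]),
               "3 or more angles")
})

test_that("doubling all decay rates halves the reported radius", {
  g <- gen_dls(r_h_nm = 7.4, noise_sd = 0, seed = 1)
  base <- hydrodynamic_radius(g$data)
  q <- vapply(base$fits, `[[`, numeric(1), "q")
  gam <- vapply(base$fits, `[[`, numeric(1), "gamma")
  doubled <- Map(make_decay_fit, 2 * gam, q)
  r2 <- stokes_einstein(fit_gamma_vs_q2(doubled)$diffusion)
  expect_equal(r2, base$r_h_nm / 2, tolerance = 1e-10)
})

test_that("mono-exponential residuals sit at the injected noise level", {
  sd0 <- 5e-3
  g <- gen_dls(r_h_nm = 7.4, angles_deg = 90, noise_sd = sd0, seed = 11)
  fit <- fit_monoexponential(g$data, q = scattering_vector(90, 660, 1.33))
  expect_gt(fit$residual_rms, 0.5 * sd0)
  expect_lt(fit$residual_rms, 2 * sd0)
})

test_that("decay rates increase monotonically with angle for a diffusing species", {
  g <- gen_dls(r_h_nm = 7.4, noise_sd = 1e-4, seed = 3)
  res <- hydrodynamic_radius(g$data)
  gam <- vapply(res$fits, `[[`, numeric(1), "gamma")
  expect_true(all(gam > 0))
  expect_true(all(diff(gam) > 0))
})
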