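test_that("sphere intensity has the correct forward limit, zeros and positivity", {
  # q -> 0: the form factor tends to 1 without 0/0 evaluation
  expect_equal(sphere_intensity(0, 6, 2.5, 0.01), 2.51)
  expect_equal(sphere_intensity(1e-9, 6, 2.5, 0.01), 2.51, tolerance = 1e-8)
  # first zero of the form factor at qR ~= 4.4934 (first root of
  # sin x - x cos x), where only the flat term survives
  x0 <- uniroot(function(x) sin(x) - x * cos(x), c(4, 5), tol = 1e-12)$root
  expect_equal(x0, 4.4934, tolerance = 1e-4)
  expect_equal(sphere_intensity(x0 / 6, 6, 2.5, 0.01), 0.01, tolerance = 1e-12)
  # squared amplitude: nonnegative everywhere with zero background
  q <- seq(0.01, 5, length.out = 500)
  expect_true(all(sphere_intensity(q, 6, 1, 0) >= 0))
})

test_that("sphere fit inverts noiseless curves exactly and tolerates 2% noise", {
  g0 <- gen_saxs(radius = 6, forward_intensity = 1, internal_background = 1e-3,
                 noise_frac = 0, seed = 1)
  f0 <- fit_sphere(g0$data)
  expect_equal(f0$radius, 6, tolerance = 1e-6)
  expect_equal(f0$forward_intensity, 1, tolerance = 1e-6)
  expect_equal(f0$internal_background, 1e-3, tolerance = 1e-4)

  g2 <- gen_saxs(radius = 6, noise_frac = 0.02, seed = 1)
  f2 <- fit_sphere(g2$data)
  expect_lt(abs(f2$radius - 6), 0.1)

  # radii off the multi-start grid are still found
  g3 <- gen_saxs(radius = 7.23, noise_frac = 0, seed = 1)
  expect_equal(fit_sphere(g3$data)$radius, 7.23, tolerance = 1e-5)
})

test_that("pure flat background leaves the radius unidentifiable", {
  q <- 10^seq(log10(0.05), log10(3), length.out = 100)
  flat <- data.frame(q = q, intensity = rep(0.02, length(q)),
                     sigma = rep(2e-4, length(q)))
  expect_error(fit_sphere(flat), class = "os_fit_failure")
})

test_that("sphere fit radius is invariant to uniform intensity rescaling", {
  g <- gen_saxs(radius = 6, noise_frac = 0.01, seed = 4)
  f1 <- fit_sphere(g$data)
  scaled <- g$data
  scaled$intensity <- scaled$intensity * 37
  scaled$sigma <- scaled$sigma * 37
  f2 <- fit_sphere(scaled)
  expect_equal(f2$radius, f1$radius, tolerance = 1e-6)
  expect_equal(f2$forward_intensity, 37 * f1$forward_intensity,
               tolerance = 1e-6)
})

test_that("analytic sphere p(r) has support [0, 2R], peak near 1.05 R, and is nonnegative", {
  r <- seq(0, 15, length.out = 3001)
  p <- sphere_pddf(r, 6)
  expect_equal(p[r == 0], 0)
  expect_true(all(p[r >= 12] == 0))
  expect_true(all(p >= 0))
  expect_equal(max(p), 1, tolerance = 1e-6)
  expect_equal(r[which.max(p)] / 6, 1.05, tolerance = 5e-3)
})

test_that("regularized IFT recovers the sphere p(r) and reproduces the data", {
  g <- gen_saxs(radius = 6, noise_frac = 0.01, seed = 2)
  pd <- estimate_pddf(g$data, d_max = 13)
  # shape agreement with the analytic transform: RMS below 5% of peak
  expect_lt(sqrt(mean((pd$p - sphere_pddf(pd$r, 6))^2)), 0.05)
  expect_equal(pd$p[1], 0)
  expect_equal(pd$p[length(pd$p)], 0)
  expect_true(all(pd$p >= 0))
  expect_false(pd$misfit_flag)
  # >= 95% of the p-mass below 2R plus one grid step
  dr <- pd$r[2] - pd$r[1]
  expect_gte(sum(pd$p[pd$r <= 12 + dr]) / sum(pd$p), 0.95)
  # self-consistency: forward model reproduces the curve within the noise
  I_fit <- pddf_forward(pd, g$data$q)
  rel <- (I_fit - g$data$intensity) / g$data$intensity
  expect_lt(sqrt(mean(rel^2)), 0.03)
})

test_that("a d_max far below the particle size is flagged as misfit", {
  g <- gen_saxs(radius = 6, noise_frac = 0.01, seed = 2)
  pd <- estimate_pddf(g$data, d_max = 6)
  expect_true(pd$misfit_flag)
})

test_that("volume fraction matches the worked example and scales as R^-3", {
  prot <- protein_params(monomer_molar_mass = 20000, mass_density = 1.4)
  f <- volume_fraction(18, prot, 6)
  expect_equal(f, 0.47, tolerance = 0.01)
  expect_equal(round(f, 1), 0.5)
  expect_equal(volume_fraction(18, prot, 12), f / 8)
  expect_equal(volume_fraction(0, prot, 6), 0)
})

test_that("concentration normalization collapses a common-shape family", {
  # exact scalar multiples collapse to metric zero
  g <- gen_saxs(radius = 6, noise_frac = 0, seed = 1, concentration = 10)
  c2 <- g$data
  c2$intensity <- c2$intensity * 5.8
  c2$concentration <- 58
  res <- normalize_by_concentration(list(g$data, c2))
  expect_lt(res$collapse_metric, 1e-12)

  # a noisy 5-concentration family with common shape (both the form-factor
  # and the internal term scale with concentration) collapses to within the
  # noise level
  fam <- lapply(seq_along(c(10, 22, 34, 46, 58)), function(i) {
    cc <- c(10, 22, 34, 46, 58)[i]
    g <- gen_saxs(radius = 6, forward_intensity = cc / 10,
                  internal_background = 1e-3 * cc / 10,
                  noise_frac = 0.01, seed = 100 + i, concentration = cc)
    g$data
  })
  res2 <- normalize_by_concentration(fam)
  expect_lt(res2$collapse_metric, 0.05)

  bad <- g$data
  bad$concentration <- 0
  expect_error(normalize_by_concentration(list(bad)), "positive concentration")
})
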