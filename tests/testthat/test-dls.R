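# Stokes-Einstein conversion, cumulant analysis and peak means

test_that("Stokes-Einstein conversion matches direct evaluation", {
  expect_equal(stokes_einstein_radius(1.2305e-10, 25, 8.872e-4),
               2.000386, tolerance = 1e-6)
  # inverse proportionality in D, exact algebraic round trip
  r1 <- stokes_einstein_radius(1e-11, 25, 8.9e-4)
  expect_equal(stokes_einstein_radius(5e-12, 25, 8.9e-4), 2 * r1)
  d <- diffusion_from_radius(r1, 25, 8.9e-4)
  expect_equal(d, 1e-11, tolerance = 1e-12)
  expect_error(stokes_einstein_radius(-1e-11, 25, 8.9e-4),
               class = "aggrekit_domain_error")
})

test_that("scattering vector matches the stated geometry", {
  expect_equal(scattering_vector(633, 90, 1.33), 1.8669934e7,
               tolerance = 1e-7)
})

test_that("cumulant fit recovers a single-exponential decay exactly", {
  gamma <- 4.0e3
  tau <- exp(seq(log(1e-6), log(2.5 / (2 * gamma)), length.out = 40))
  cv <- autocorrelation_curve(tau, exp(-2 * gamma * tau))
  fit <- fit_cumulant(cv)
  expect_equal(fit$gamma_s, gamma, tolerance = 1e-9)
  expect_equal(fit$diffusion_m2_s, 1.1475573e-11, tolerance = 1e-6)
  expect_lt(abs(fit$pdi), 1e-6)
})

test_that("non-decaying or too-short curves are rejected", {
  tau <- seq(1e-5, 1e-3, length.out = 30)
  rising <- autocorrelation_curve(tau, 0.1 + 0.5 * tau / max(tau))
  expect_error(fit_cumulant(rising), class = "aggrekit_fit_rejected_error")
  short <- autocorrelation_curve(tau[1:5], exp(-2e3 * tau[1:5]))
  expect_error(fit_cumulant(short),
               class = "aggrekit_insufficient_data_error")
})

test_that("windowed intensity-weighted mean respects the window contract", {
  d <- size_distribution(c(1, 3, 1000), c(0.25, 0.25, 0.5))
  expect_equal(intensity_weighted_mean_rh(d, c(0, 10)), 2)
  expect_equal(intensity_weighted_mean_rh(size_distribution(10, 1)), 10)
  # bimodal: small-peak window sees only the small peak
  s <- simulate_dls_sample(list(c(2, 0.1, 0.5), c(1000, 0.1, 0.5)))
  small <- intensity_weighted_mean_rh(s$distribution, c(0, 100))
  expect_equal(small, 2, tolerance = 0.05)
  expect_error(intensity_weighted_mean_rh(d, c(2000, 3000)),
               class = "aggrekit_domain_error")
})

test_that("windowed means are additive over disjoint windows", {
  s <- simulate_dls_sample(list(c(2, 0.15, 0.4), c(1000, 0.2, 0.6)))
  d <- s$distribution
  w_small <- sum(d$weights[d$rh_grid <= 100])
  w_large <- 1 - w_small
  m_small <- intensity_weighted_mean_rh(d, c(min(d$rh_grid), 100))
  m_large <- intensity_weighted_mean_rh(d, c(100 + 1e-9, max(d$rh_grid)))
  m_all <- intensity_weighted_mean_rh(d)
  expect_equal(w_small * m_small + w_large * m_large, m_all,
               tolerance = 1e-9)
})

test_that("simulate -> cumulant -> Stokes-Einstein returns the radius", {
  for (r in c(2, 10, 1000)) {
    s <- simulate_dls_sample(list(c(r, 0, 1)), noise_sd = 0)
    fit <- fit_cumulant(s$curve)
    expect_lt(abs(fit$rh_nm - r) / r, 0.02)
  }
})
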