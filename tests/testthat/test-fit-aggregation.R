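# Nonlinear least-squares fit of the autocatalytic model

test_that("noiseless model traces round-trip the generating parameters", {
  for (p in list(c(0.0186, 0.2087), c(0.0068, 0.29), c(0.0624, 0.2326))) {
    tr <- make_model_trace(p[1], p[2])
    fit <- fit_autocatalytic(tr)
    expect_equal(fit$rho, p[1], tolerance = 1e-6)
    expect_equal(fit$k, p[2], tolerance = 1e-6)
    expect_gt(fit$r_squared, 0.999999)
  }
})

test_that("derived constants and stored fields are self-consistent", {
  fit <- fit_autocatalytic(make_model_trace(0.0068, 0.29), a = 15e-6)
  expect_equal(fit$k_n, fit$rho * fit$k, tolerance = 1e-9)
  expect_equal(fit$k_e, fit$k / fit$a, tolerance = 1e-9)
  expect_true(fit$t0 < fit$t_half && fit$t_half < fit$t1)
  expect_equal(coef(fit)[["k_n"]], fit$k_n)
  expect_equal(predict(fit, 0), 0)
  expect_equal(length(residuals(fit)), fit$n_points)
})

test_that("fit recovers k within 5% under 2% additive noise (fixed seed)", {
  tr <- simulate_aggregation_trace(0.0186, 0.2087, t_grid = 0:36,
                                   noise_sd = 0.02, seed = 42)
  fit <- fit_autocatalytic(tr)
  expect_lt(abs(fit$k - 0.2087) / 0.2087, 0.05)
})

test_that("time-stretching a trace scales the fitted k as 1/c", {
  tr1 <- make_model_trace(0.01, 0.3, t_grid = seq(0, 36, 1))
  c_stretch <- 2
  tr2 <- kinetic_trace(tr1$times * c_stretch, tr1$signal,
                       is_normalized = TRUE)
  f1 <- fit_autocatalytic(tr1)
  f2 <- fit_autocatalytic(tr2)
  expect_equal(f2$k, f1$k / c_stretch, tolerance = 1e-6)
  expect_equal(f2$rho, f1$rho, tolerance = 1e-6)
})

test_that("flat or invalid traces are rejected with typed conditions", {
  flat <- kinetic_trace(0:9, rep(0.02, 10), is_normalized = TRUE)
  expect_error(fit_autocatalytic(flat), class = "aggrekit_fit_rejected_error")
  short <- kinetic_trace(0:3, c(0, 0.3, 0.7, 1), is_normalized = TRUE)
  expect_error(fit_autocatalytic(short),
               class = "aggrekit_insufficient_data_error")
  raw <- kinetic_trace(0:9, 1:10 * 10)
  expect_error(fit_autocatalytic(raw), class = "aggrekit_validation_error")
})

test_that("replicate groups report per-replicate rows plus mean and sd", {
  traces <- lapply(1:3, function(i)
    simulate_aggregation_trace(0.0068, 0.29, noise_sd = 0.02, seed = i,
                               replicate_id = paste0("r", i)))
  grp <- fit_aggregation_replicates(traces)
  expect_equal(nrow(grp$table), 5)
  expect_equal(grp$table$replicate, c("r1", "r2", "r3", "mean", "sd"))
  ks <- grp$table$k_per_h[1:3]
  expect_equal(grp$table$k_per_h[4], mean(ks))
  expect_equal(grp$table$k_per_h[5], sd(ks))
  expect_lt(abs(grp$table$k_per_h[4] - 0.29) / 0.29, 0.05)
})
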