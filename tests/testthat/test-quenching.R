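# Spectral integration, inner-filter correction, Stern-Volmer and
# double-log binding fits, mechanism classification

test_that("spectral integration is a trapezoidal rule, linear in intensity", {
  sp <- emission_spectrum(seq(290, 450, 10), rep(2, 17))
  expect_equal(integrate_spectrum(sp), 320)
  sp2 <- emission_spectrum(sp$wavelengths, 2 * sp$intensities)
  expect_equal(integrate_spectrum(sp2), 2 * integrate_spectrum(sp))
  # triangular peak of height 1 spanning 100 nm -> area 50
  w <- seq(300, 400, 1)
  tri <- emission_spectrum(w, pmax(0, 1 - abs(w - 350) / 50))
  expect_equal(integrate_spectrum(tri, 300, 400), 50)
  expect_error(integrate_spectrum(sp, 100, 450),
               class = "aggrekit_domain_error")
})

test_that("inner-filter correction is the standard half-absorbance factor", {
  expect_equal(correct_inner_filter(100, 0, 0), 100)
  expect_equal(correct_inner_filter(100, 0.1, 0.1), 125.8925, tolerance = 1e-6)
  expect_equal(correct_inner_filter(50, 0.2, 0), 62.94627, tolerance = 1e-6)
  expect_error(correct_inner_filter(10, -0.1, 0),
               class = "aggrekit_domain_error")
})

test_that("inner-filter correction commutes with spectral integration", {
  w <- seq(290, 450, 5)
  y <- exp(-(w - 340)^2 / 800)
  a_ex <- 0.12; a_em <- 0.05
  area_then_correct <- correct_inner_filter(
    integrate_spectrum(emission_spectrum(w, y)), a_ex, a_em)
  correct_then_area <- integrate_spectrum(
    emission_spectrum(w, correct_inner_filter(y, a_ex, a_em)))
  expect_equal(area_then_correct, correct_then_area, tolerance = 1e-12)
})

test_that("Stern-Volmer fit recovers the generating constant exactly", {
  tit <- make_titration(3.43e4, n = 1, temperature_c = 25)
  fit <- fit_stern_volmer(tit, tau0 = 5.91e-9)
  expect_equal(fit$k_sv, 3.43e4, tolerance = 1e-9)
  expect_equal(fit$k_q, 3.43e4 / 5.91e-9, tolerance = 1e-12)
  expect_gt(fit$r_squared, 0.999999)
  expect_false(fit$low_signal)
})

test_that("no quenching yields K_sv ~ 0 with a low-signal flag, not an error", {
  q <- c(0, seq(2e-6, 20e-6, 2e-6))
  tit <- quench_titration(q, rep(1000, length(q)), 25)
  fit <- fit_stern_volmer(tit)
  expect_equal(fit$k_sv, 0)
  expect_true(fit$low_signal)
  expect_error(fit_stern_volmer(quench_titration(c(0, 1e-6, 2e-6),
                                                 c(100, 90, 80), 25)),
               class = "aggrekit_insufficient_data_error")
})

test_that("K_q is K_sv over tau0, and reproduces K_sv when multiplied back", {
  expect_equal(bimolecular_quenching_constant(3.43e4, 5.91e-9),
               5.803722504230119e12, tolerance = 1e-12)
  expect_equal(bimolecular_quenching_constant(5e4, 1), 5e4)
  expect_equal(bimolecular_quenching_constant(0, 5.91e-9), 0)
  expect_equal(bimolecular_quenching_constant(3.43e4, 5.91e-9) * 5.91e-9,
               3.43e4, tolerance = 1e-15)
  expect_error(bimolecular_quenching_constant(1e4, 0),
               class = "aggrekit_domain_error")
})

test_that("quenching mechanism classification follows the two-signal rule", {
  sv <- function(ksv, kq, temp) {
    structure(list(k_sv = ksv, k_q = kq, temperature_c = temp),
              class = "sv_fit")
  }
  static <- list(sv(3.43e4, 5.8e12, 25), sv(2.70e4, 4.6e12, 30),
                 sv(2.30e4, 3.9e12, 37))
  expect_equal(classify_quenching(static), "static")
  dynamic <- list(sv(1e4, 1e9, 25), sv(2e4, 1.5e9, 37))
  expect_equal(classify_quenching(dynamic), "dynamic")
  conflicted <- list(sv(3e4, 1e9, 25), sv(2e4, 1e9, 37))
  expect_equal(classify_quenching(conflicted), "indeterminate")
  expect_error(classify_quenching(static[1]),
               class = "aggrekit_insufficient_data_error")
})

test_that("double-log binding fit recovers (K_b, n) exactly from the model", {
  tit <- make_titration(9.33e4, n = 1.15, temperature_c = 37)
  fit <- fit_binding_double_log(tit)
  expect_equal(fit$k_b, 9.33e4, tolerance = 1e-9)
  expect_equal(fit$n, 1.15, tolerance = 1e-9)
  expect_equal(fit$n_dropped, 0)
})

test_that("the double-log fit reduces to Stern-Volmer when n = 1", {
  tit <- make_titration(3.43e4, n = 1)
  bd <- fit_binding_double_log(tit)
  expect_equal(bd$n, 1, tolerance = 1e-9)
  expect_equal(log10(bd$k_b), log10(3.43e4), tolerance = 1e-9)
})

test_that("points with F >= F0 are dropped with a warning", {
  q <- c(0, seq(2e-6, 20e-6, 2e-6))
  f <- 1000 / (1 + 5e4 * q)
  f[2] <- 1001                       # brighter than F0
  tit <- quench_titration(q, f, 25)
  expect_warning(fit <- fit_binding_double_log(tit), "dropped")
  expect_equal(fit$n_dropped, 1)
  all_f0 <- quench_titration(q, rep(1000, length(q)), 25)
  expect_error(suppressWarnings(fit_binding_double_log(all_f0)),
               class = "aggrekit_insufficient_data_error")
})

test_that("stored absorbances trigger the inner-filter correction in fits", {
  tit <- simulate_quench_titration(3.43e4, n = 1, noise_sd = 0,
                                   inner_filter_eps = 5e3)
  fit <- fit_stern_volmer(tit)
  expect_equal(fit$k_sv, 3.43e4, tolerance = 1e-9)
  # without correction the attenuation masquerades as extra quenching
  naked <- quench_titration(tit$q_conc, tit$f_area, tit$temperature_c)
  expect_gt(fit_stern_volmer(naked)$k_sv, 3.43e4)
})
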