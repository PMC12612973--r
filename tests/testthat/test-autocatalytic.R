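# Closed-form autocatalytic sigmoid, its inverse and derived constants

test_that("fibrillar fraction matches the closed form and its limits", {
  expect_equal(autocatalytic_fraction(0, 0.0068, 0.29), 0)
  expect_equal(autocatalytic_fraction(0, 0.05, 1), 0)
  # frozen from an independent bisection oracle on the sigmoid
  expect_equal(autocatalytic_fraction(17.139, 0.0068, 0.29),
               0.499941379477179, tolerance = 1e-12)
  expect_equal(autocatalytic_fraction(1000, 0.0068, 0.29), 1,
               tolerance = 1e-9)
  # extreme argument: asymptote, no overflow/NaN
  expect_equal(autocatalytic_fraction(1e6, 0.1, 1), 1)
  expect_error(autocatalytic_fraction(-1, 0.01, 0.3),
               class = "aggrekit_domain_error")
  expect_error(autocatalytic_fraction(1, -0.01, 0.3),
               class = "aggrekit_domain_error")
})

test_that("fraction is strictly increasing in time and bounded in [0, 1)", {
  for (rho in c(1e-3, 1e-2, 1e-1)) {
    for (k in c(0.05, 0.29, 1)) {
      # stay below float saturation of the asymptote: f < 1 - 1e-12
      t_max <- min(100, invert_autocatalytic(1 - 1e-12, rho, k))
      t <- seq(0, t_max, length.out = 400)
      f <- autocatalytic_fraction(t, rho, k)
      expect_true(all(diff(f) > 0))
      expect_true(all(f >= 0 & f < 1))
    }
  }
})

test_that("inversion solves the sigmoid for time", {
  expect_equal(invert_autocatalytic(0, 0.0068, 0.29), 0)
  # frozen from the bisection oracle; consistent with a ~17.17 h halftime
  expect_equal(invert_autocatalytic(0.5, 0.0068, 0.29),
               17.139797709454122, tolerance = 1e-10)
  expect_equal(invert_autocatalytic(0.9, 0.0068, 0.29),
               24.644775524520636, tolerance = 1e-10)
  expect_error(invert_autocatalytic(1, 0.0068, 0.29),
               class = "aggrekit_domain_error")
})

test_that("forward and inverse are mutually consistent across the grid", {
  for (rho in c(1e-3, 3e-3, 1e-2, 3e-2, 1e-1)) {
    for (k in c(0.05, 0.2, 0.5, 1)) {
      t_max <- min(100, invert_autocatalytic(1 - 1e-6, rho, k))
      t <- t_max * c(0.001, 0.01, 0.05, 0.2, 0.5, 1)
      f <- autocatalytic_fraction(t, rho, k)
      expect_equal(invert_autocatalytic(f, rho, k), t, tolerance = 1e-9)
    }
  }
})

test_that("rate constants derive exactly from (rho, k, a)", {
  rc <- derive_rate_constants(0.0068, 0.29, 15e-6)
  expect_equal(round(unname(rc["k_n"]), 4), 0.0020)
  expect_equal(unname(rc["k_e"]), 0.29 / 15e-6)
  rc18 <- derive_rate_constants(0.0186, 0.2087, 15e-6)
  expect_equal(round(unname(rc18["k_n"]), 4), 0.0039)
  expect_equal(round(unname(rc18["k_e"])), 13913)
  expect_equal(unname(derive_rate_constants(0, 0.3, 1e-5)["k_n"]), 0)
  expect_error(derive_rate_constants(0.01, 0.3, 0),
               class = "aggrekit_domain_error")
})
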