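## Seed hygiene: every generator is a pure function of (parameters, seed).
## The global RNG state is saved and restored so simulation never leaks
## randomness into, or steals it from, the caller's session.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Simulate a ThT-style autocatalytic aggregation trace
#'
#' Evaluates the autocatalytic sigmoid at the requested times, scales it
#' to `f_max`, and adds Gaussian noise with standard deviation
#' `noise_sd * f_max` (additive, emulating plate-reader noise as a
#' fraction of the dynamic range).  The signal is clipped below at 0;
#' with `f_max = 1` the trace is returned flagged as normalized (and
#' clipped above at 1).  With `noise_sd = 0` the output lies exactly on
#' the forward model.
#'
#' @param rho,k Generating parameters (see [autocatalytic_fraction()]).
#' @param t_grid Increasing times in hours (default hourly 0-36 h, the
#'   standard incubation window).
#' @param f_max Plateau signal in arbitrary units (default 1).
#' @param noise_sd Noise SD as a fraction of `f_max` (default 0.02).
#' @param seed Integer seed; same seed, same trace.
#' @param replicate_id Replicate label.
#' @return A [kinetic_trace()].
#' @examples
#' tr <- simulate_aggregation_trace(0.0068, 0.29, seed = 1)
#' @export
simulate_aggregation_trace <- function(rho, k, t_grid = 0:36, f_max = 1,
                                       noise_sd = 0.02, seed = NULL,
                                       replicate_id = "r1") {
  if (length(t_grid) == 0) .domain_error("`t_grid` must be non-empty")
  if (noise_sd < 0) .domain_error("`noise_sd` must be non-negative")
  if (f_max <= 0) .domain_error("`f_max` must be positive")
  f <- autocatalytic_fraction(t_grid, rho, k)
  signal <- .with_seed(seed, {
    f_max * f + if (noise_sd > 0)
      stats::rnorm(length(f), 0, noise_sd * f_max) else 0
  })
  signal <- pmax(signal, 0)
  normalized <- isTRUE(all.equal(f_max, 1))
  if (normalized) signal <- pmin(signal, 1)
  kinetic_trace(t_grid, signal, replicate_id = replicate_id,
                is_normalized = normalized)
}

#' Simulate a fluorescence quench titration
#'
#' Generates fluorescence areas from the static-quenching forward model
#' `F([Q]) = F0 / (1 + K_b [Q]^n)`, under which both the Stern-Volmer
#' relation (at n = 1) and the double-log binding plot are exactly
#' recoverable.  If `inner_filter_eps` is given, each observed point is
#' attenuated by `10^-(A_ex + A_em)/2` with `A = eps * [Q]` and the
#' per-point absorbances are stored on the titration, so that
#' [correct_inner_filter()] restores the ideal signal exactly at zero
#' noise.  Noise is proportional (`F * (1 + N(0, noise_sd))`).
#'
#' @param k_b Binding constant, per molar, `> 0`.
#' @param n Apparent exponent (default 1).
#' @param f0 Unquenched fluorescence area, `> 0` (default 1000).
#' @param q_grid Molar concentrations, first entry 0 (default 0 and
#'   2-20 uM in 2 uM steps, the usual titration range).
#' @param temperature_c Temperature label in Celsius.
#' @param noise_sd Proportional noise SD (default 0.05).
#' @param seed Integer seed.
#' @param inner_filter_eps Optional molar absorptivity generating the
#'   inner-filter artifact (absorbance per molar of quencher).
#' @return A [quench_titration()].
#' @examples
#' tit <- simulate_quench_titration(9.33e4, n = 1.15, temperature_c = 37,
#'                                  noise_sd = 0, seed = 1)
#' coef(fit_binding_double_log(tit))
#' @export
simulate_quench_titration <- function(k_b, n = 1, f0 = 1000,
                                      q_grid = c(0, seq(2e-6, 20e-6, 2e-6)),
                                      temperature_c = 25, noise_sd = 0.05,
                                      seed = NULL, inner_filter_eps = NULL) {
  if (k_b <= 0 || f0 <= 0) .domain_error("k_b and f0 must be positive")
  if (any(q_grid < 0)) .domain_error("concentrations must be non-negative")
  if (noise_sd < 0) .domain_error("`noise_sd` must be non-negative")
  f_ideal <- f0 / (1 + k_b * q_grid^n)
  a_ex <- a_em <- NULL
  f_obs <- f_ideal
  if (!is.null(inner_filter_eps)) {
    if (inner_filter_eps < 0) .domain_error("inner_filter_eps must be >= 0")
    a_ex <- a_em <- inner_filter_eps * q_grid
    f_obs <- f_ideal * 10^(-(a_ex + a_em) / 2)
  }
  f_obs <- .with_seed(seed, {
    if (noise_sd > 0)
      f_obs * (1 + stats::rnorm(length(f_obs), 0, noise_sd))
    else f_obs
  })
  f_obs <- pmax(f_obs, 1e-9 * f0)
  quench_titration(q_grid, f_obs, temperature_c, a_ex = a_ex, a_em = a_em)
}

#' Simulate a Van't Hoff-consistent temperature series of titrations
#'
#' Computes `K_b(T) = exp(-dH/(R T) + dS/R)` with `T = T_C + 273` at
#' each requested temperature and generates one quench titration per
#' temperature from those binding constants, so that the full chain
#' titration -> [fit_binding_double_log()] -> [fit_vant_hoff()] recovers
#' `(dH, dS)` exactly at zero noise.
#'
#' @param delta_h Enthalpy in kJ/mol.
#' @param delta_s Entropy in J/(mol K).
#' @param temperatures_c Two or more temperatures in Celsius.
#' @param n,f0,q_grid,noise_sd,inner_filter_eps Per-titration settings
#'   passed to [simulate_quench_titration()].
#' @param seed Integer seed; each temperature uses `seed + index`.
#' @param kelvin_offset Celsius-to-Kelvin offset (default 273, matching
#'   the thermodynamics convention).
#' @return List of [quench_titration()] objects with a `k_b_true`
#'   attribute holding the generating constants.
#' @export
simulate_temperature_series <- function(delta_h, delta_s,
                                        temperatures_c = c(25, 30, 37),
                                        n = 1, f0 = 1000,
                                        q_grid = c(0, seq(2e-6, 20e-6, 2e-6)),
                                        noise_sd = 0, seed = NULL,
                                        inner_filter_eps = NULL,
                                        kelvin_offset = 273) {
  if (length(temperatures_c) < 2)
    .insufficient_error("need >= 2 temperatures for a Van't Hoff series")
  t_k <- temperatures_c + kelvin_offset
  k_b <- exp(-delta_h * 1000 / (.R_gas * t_k) + delta_s / .R_gas)
  out <- lapply(seq_along(t_k), function(i) {
    simulate_quench_titration(k_b[i], n = n, f0 = f0, q_grid = q_grid,
                              temperature_c = temperatures_c[i],
                              noise_sd = noise_sd,
                              seed = if (is.null(seed)) NULL else seed + i,
                              inner_filter_eps = inner_filter_eps)
  })
  attr(out, "k_b_true") <- k_b
  out
}

#' Simulate a dose-response table
#'
#' `response = bottom + (top - bottom) / (1 + (dose/ic50)^hill)` with
#' proportional Gaussian noise.
#'
#' @param ic50 Inflection dose in uM, `> 0`.
#' @param hill Hill slope (default 1).
#' @param top,bottom Response asymptotes (defaults 100 and 0).
#' @param dose_grid Doses in uM (default 8 log-spaced 0.1-30 uM).
#' @param noise_sd Proportional noise SD (default 0.05).
#' @param seed Integer seed.
#' @return Data frame with columns `dose_uM`, `response`.
#' @examples
#' dr <- simulate_dose_response(3.04, seed = 1)
#' fit_ic50(dr$dose_uM, dr$response)$ic50
#' @export
simulate_dose_response <- function(ic50, hill = 1, top = 100, bottom = 0,
                                   dose_grid = exp(seq(log(0.1), log(30),
                                                       length.out = 8)),
                                   noise_sd = 0.05, seed = NULL) {
  if (ic50 <= 0) .domain_error("`ic50` must be positive")
  if (any(dose_grid < 0)) .domain_error("doses must be non-negative")
  resp <- .logistic4(dose_grid, ic50, hill, top, bottom)
  resp <- .with_seed(seed, {
    if (noise_sd > 0) resp * (1 + stats::rnorm(length(resp), 0, noise_sd))
    else resp
  })
  data.frame(dose_uM = dose_grid, response = resp)
}

#' Simulate a DLS sample (size distribution and autocorrelation curve)
#'
#' Builds an intensity-weighted log-normal mixture over hydrodynamic
#' radius and the matching autocorrelation curve
#' `g2 - 1 = sum_i w_i exp(-2 Gamma_i tau)` with
#' `Gamma_i = q^2 D(R_h,i)` from the Stokes-Einstein relation and the
#' stated instrument geometry.  A mode with `sigma_log = 0` is a
#' monodisperse spike, for which the noiseless curve is a single
#' exponential.  The default modes reproduce the regimes seen in amylin
#' preparations: ~2 nm native peptide, ~10 nm inhibited oligomers,
#' ~1000 nm mature fibrils.
#'
#' @param modes Data frame or list of vectors with elements
#'   `mean_rh_nm`, `sigma_log` (SD of log R_h) and `weight`; e.g.
#'   `list(c(2, 0.15, 1))`.
#' @param wavelength_nm,angle_deg,refractive_index Instrument geometry
#'   (defaults 633 nm, 90 degrees, 1.33).
#' @param temperature_c,viscosity_pa_s Sample conditions (defaults 25
#'   degC, 8.9e-4 Pa s).
#' @param n_lags Number of lag points (default 40, typical of a 30-40
#'   point instrument export).
#' @param noise_sd Additive noise SD on `g2 - 1` relative to its maximum
#'   (default 0).
#' @param seed Integer seed.
#' @return List with components `distribution` ([size_distribution()])
#'   and `curve` ([autocorrelation_curve()]).
#' @examples
#' s <- simulate_dls_sample(list(c(2, 0, 1)), seed = 1)
#' fit_cumulant(s$curve)$rh_nm  # ~2 nm
#' @export
simulate_dls_sample <- function(modes = list(c(2, 0.15, 1)),
                                wavelength_nm = 633, angle_deg = 90,
                                refractive_index = 1.33,
                                temperature_c = 25,
                                viscosity_pa_s = 8.9e-4,
                                n_lags = 40, noise_sd = 0, seed = NULL) {
  if (is.data.frame(modes))
    modes <- lapply(seq_len(nrow(modes)), function(i) as.numeric(modes[i, ]))
  if (length(modes) == 0) .domain_error("`modes` must be non-empty")
  modes <- lapply(modes, function(m) {
    if (length(m) != 3) .validation_error("each mode is (mean_rh_nm, sigma_log, weight)")
    if (m[1] <= 0 || m[3] <= 0) .domain_error("mode means and weights must be positive")
    if (m[2] < 0) .domain_error("sigma_log must be >= 0")
    m
  })
  # discretize each mode; sigma_log = 0 contributes a single spike
  comp_r <- numeric(0); comp_w <- numeric(0)
  for (m in modes) {
    if (m[2] == 0) {
      comp_r <- c(comp_r, m[1]); comp_w <- c(comp_w, m[3])
    } else {
      lr <- seq(log(m[1]) - 4 * m[2], log(m[1]) + 4 * m[2],
                length.out = 61)
      dens <- stats::dnorm(lr, log(m[1]), m[2])
      comp_r <- c(comp_r, exp(lr))
      comp_w <- c(comp_w, m[3] * dens / sum(dens))
    }
  }
  ord <- order(comp_r)
  comp_r <- comp_r[ord]; comp_w <- comp_w[ord]
  # merge numerically identical radii so the grid is strictly increasing
  if (anyDuplicated(comp_r)) {
    comp_w <- as.numeric(tapply(comp_w, comp_r, sum))
    comp_r <- sort(unique(comp_r))
  }
  comp_w <- comp_w / sum(comp_w)

  d_i <- diffusion_from_radius(comp_r, temperature_c, viscosity_pa_s)
  q <- scattering_vector(wavelength_nm, angle_deg, refractive_index)
  gamma_i <- q^2 * d_i
  gamma_mean <- sum(comp_w * gamma_i)
  lags <- exp(seq(log(0.01 / (2 * gamma_mean)), log(2.5 / (2 * gamma_mean)),
                  length.out = n_lags))
  g2m1 <- vapply(lags, function(tau) sum(comp_w * exp(-2 * gamma_i * tau)),
                 numeric(1))
  g2m1 <- .with_seed(seed, {
    if (noise_sd > 0)
      g2m1 + stats::rnorm(length(g2m1), 0, noise_sd * max(g2m1))
    else g2m1
  })
  g2m1 <- pmax(g2m1, 1e-12)
  list(distribution = size_distribution(comp_r, comp_w),
       curve = autocorrelation_curve(lags, g2m1,
                                     wavelength_nm = wavelength_nm,
                                     angle_deg = angle_deg,
                                     refractive_index = refractive_index,
                                     temperature_c = temperature_c,
                                     viscosity_pa_s = viscosity_pa_s))
}
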