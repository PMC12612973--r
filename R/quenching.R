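#' Construct an emission spectrum
#'
#' @param wavelengths Strictly increasing wavelengths in nm.
#' @param intensities Finite intensities, same length.
#' @param excitation_nm Excitation wavelength (default 275, tyrosine).
#' @param temperature_c Temperature in Celsius (default 25).
#' @return An object of class `"emission_spectrum"`.
#' @export
emission_spectrum <- function(wavelengths, intensities,
                              excitation_nm = 275, temperature_c = 25) {
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) != length(intensities))
    .validation_error("wavelengths and intensities must have the same length")
  if (length(wavelengths) < 2 || any(diff(wavelengths) <= 0))
    .validation_error("wavelengths must be strictly increasing (>= 2 points)")
  if (!all(is.finite(intensities)))
    .validation_error("intensities must be finite")
  structure(list(wavelengths = wavelengths, intensities = intensities,
                 excitation_nm = excitation_nm,
                 temperature_c = temperature_c),
            class = "emission_spectrum")
}

#' Integrate an emission spectrum over a wavelength window
#'
#' Trapezoidal integral of intensity over wavelength; the integrated area
#' over 290-450 nm is the standard relative-fluorescence readout for the
#' tyrosine emission of amylin.
#'
#' @param spec An [emission_spectrum()].
#' @param lo_nm,hi_nm Integration window in nm, default `290` / `450`;
#'   must lie within the recorded range.
#' @return The integrated area (intensity x nm).
#' @examples
#' sp <- emission_spectrum(seq(290, 450, 10), rep(2, 17))
#' integrate_spectrum(sp)  # 320
#' @export
integrate_spectrum <- function(spec, lo_nm = 290, hi_nm = 450) {
  stopifnot(inherits(spec, "emission_spectrum"))
  w <- spec$wavelengths; y <- spec$intensities
  if (lo_nm >= hi_nm) .domain_error("`lo_nm` must be below `hi_nm`")
  if (lo_nm < min(w) || hi_nm > max(w))
    .domain_error("integration window outside the recorded wavelength range")
  # interpolate the window edges onto the grid, then trapezoid
  keep <- w > lo_nm & w < hi_nm
  wi <- c(lo_nm, w[keep], hi_nm)
  yi <- c(stats::approx(w, y, xout = lo_nm)$y, y[keep],
          stats::approx(w, y, xout = hi_nm)$y)
  sum(diff(wi) * (utils::head(yi, -1) + utils::tail(yi, -1)) / 2)
}

#' Inner-filter correction of an observed fluorescence signal
#'
#' Corrects attenuation of the excitation and emission beams by sample
#' absorbance (standard 1 cm cuvette geometry):
#' `F_corr = F_obs * 10^((A_ex + A_em)/2)`.
#'
#' @param f_obs Observed fluorescence (intensity or integrated area).
#' @param a_ex Absorbance at the excitation wavelength, `>= 0`.
#' @param a_em Absorbance at the emission wavelength, `>= 0`.
#' @return Corrected fluorescence, equal to `f_obs` when both absorbances
#'   are zero.
#' @examples
#' correct_inner_filter(100, 0.1, 0.1)  # 125.89
#' @export
correct_inner_filter <- function(f_obs, a_ex, a_em) {
  if (any(a_ex < 0) || any(a_em < 0))
    .domain_error("absorbances must be non-negative")
  f_obs * 10^((a_ex + a_em) / 2)
}

#' Construct a quencher titration series
#'
#' Holds one temperature's titration of integrated fluorescence against
#' quencher (ligand) concentration.  The first concentration must be 0;
#' its fluorescence is F0.  If per-point absorbances at the excitation
#' and emission wavelengths are supplied, [fit_stern_volmer()] and
#' [fit_binding_double_log()] apply the inner-filter correction before
#' fitting.
#'
#' @param q_conc Molar quencher concentrations, non-negative, strictly
#'   increasing, first entry 0.
#' @param f_area Positive integrated fluorescence per concentration.
#' @param temperature_c Temperature in Celsius.
#' @param a_ex,a_em Optional per-point absorbances.
#' @return An object of class `"quench_titration"`.
#' @export
quench_titration <- function(q_conc, f_area, temperature_c,
                             a_ex = NULL, a_em = NULL) {
  q_conc <- as.numeric(q_conc); f_area <- as.numeric(f_area)
  if (length(q_conc) != length(f_area))
    .validation_error("q_conc and f_area must have the same length")
  if (any(q_conc < 0) || q_conc[1] != 0)
    .validation_error("q_conc must be non-negative with first entry 0")
  if (any(diff(q_conc) <= 0))
    .validation_error("q_conc must be strictly increasing")
  if (any(f_area <= 0)) .validation_error("f_area must be positive")
  if (!is.null(a_ex) && length(a_ex) != length(q_conc))
    .validation_error("a_ex must match q_conc in length")
  if (!is.null(a_em) && length(a_em) != length(q_conc))
    .validation_error("a_em must match q_conc in length")
  structure(list(q_conc = q_conc, f_area = f_area,
                 temperature_c = temperature_c, a_ex = a_ex, a_em = a_em),
            class = "quench_titration")
}

#' @export
print.quench_titration <- function(x, ...) {
  cat(sprintf(
    "Quench titration at %g degC: %d points, [Q] up to %.3g M, F0 = %.4g\n",
    x$temperature_c, length(x$q_conc), max(x$q_conc), x$f_area[1]))
  invisible(x)
}

## internal: apply inner-filter correction when absorbances are present
.corrected_f <- function(tit) {
  if (!is.null(tit$a_ex) || !is.null(tit$a_em)) {
    a_ex <- if (is.null(tit$a_ex)) 0 else tit$a_ex
    a_em <- if (is.null(tit$a_em)) 0 else tit$a_em
    correct_inner_filter(tit$f_area, a_ex, a_em)
  } else tit$f_area
}

#' Stern-Volmer fit of a quench titration
#'
#' Fits the Stern-Volmer relation `F0/F = 1 + K_sv [Q]` by ordinary
#' least squares.  The reported `K_sv` is the slope with the intercept
#' fixed at 1 (the form the relation dictates); a free-intercept fit is
#' retained for diagnostics and supplies the quoted R-squared.  If `tau0`
#' is given, the bimolecular quenching constant `K_q = K_sv / tau0` is
#' filled in as well.
#'
#' When no point shows appreciable quenching (all `F >= F0` within the
#' noise floor) the fit returns `K_sv` near 0 with `low_signal = TRUE`
#' rather than failing.
#'
#' @param tit A [quench_titration()]; any stored absorbances are applied
#'   as inner-filter corrections first.
#' @param tau0 Optional fluorophore lifetime in seconds (e.g. `5.91e-9`).
#' @return An object of class `"sv_fit"` with `k_sv` (per molar), `k_q`
#'   (per molar per second, `NA` without `tau0`), `tau0`, `r_squared`
#'   (free-intercept fit), `intercept_free`, `slope_free`, `low_signal`,
#'   `temperature_c`, `n_points`.
#' @examples
#' q <- c(0, 2, 5, 10, 15, 20) * 1e-6
#' tit <- quench_titration(q, 1000 / (1 + 3.43e4 * q), 25)
#' coef(fit_stern_volmer(tit))
#' @export
fit_stern_volmer <- function(tit, tau0 = NULL) {
  stopifnot(inherits(tit, "quench_titration"))
  f <- .corrected_f(tit)
  q <- tit$q_conc
  if (sum(q > 0) < 4)
    .insufficient_error("Stern-Volmer fit needs >= 4 nonzero-quencher points")
  f0 <- f[1]
  ratio <- f0 / f
  qn <- q[q > 0]; rn <- ratio[q > 0]
  low_signal <- all(rn <= 1 + 1e-9)
  # fixed-intercept slope: OLS of (F0/F - 1) on [Q] through the origin
  k_sv <- sum((rn - 1) * qn) / sum(qn^2)
  free <- stats::lm(rn ~ qn)
  r2 <- .r_squared(rn, stats::fitted(free))
  k_q <- if (!is.null(tau0)) bimolecular_quenching_constant(k_sv, tau0)
         else NA_real_
  structure(list(k_sv = k_sv, k_q = k_q,
                 tau0 = if (is.null(tau0)) NA_real_ else tau0,
                 r_squared = r2,
                 intercept_free = unname(stats::coef(free)[1]),
                 slope_free = unname(stats::coef(free)[2]),
                 low_signal = low_signal,
                 temperature_c = tit$temperature_c,
                 n_points = length(qn)),
            class = "sv_fit")
}

#' @export
coef.sv_fit <- function(object, ...) c(k_sv = object$k_sv, k_q = object$k_q)

#' @export
print.sv_fit <- function(x, ...) {
  cat(sprintf("Stern-Volmer fit at %g degC (n = %d)\n",
              x$temperature_c, x$n_points))
  cat(sprintf("  K_sv = %.4g M^-1 (intercept fixed at 1)   R^2 = %.4f\n",
              x$k_sv, x$r_squared))
  if (!is.na(x$k_q))
    cat(sprintf("  K_q = %.3g M^-1 s^-1 (tau0 = %.3g s)\n", x$k_q, x$tau0))
  if (x$low_signal) cat("  warning: no quenching detected (low signal)\n")
  invisible(x)
}

#' Bimolecular quenching constant from K_sv and the fluorophore lifetime
#'
#' `K_q = K_sv / tau0`.  Values above the diffusion-controlled limit of
#' 2e10 per molar per second indicate static (complex-forming) rather
#' than collisional quenching.
#'
#' @param k_sv Stern-Volmer constant, per molar.
#' @param tau0 Unquenched fluorophore lifetime in seconds, `> 0`.
#' @return `K_q` in per molar per second.
#' @examples
#' bimolecular_quenching_constant(3.43e4, 5.91e-9)  # ~5.8e12
#' @export
bimolecular_quenching_constant <- function(k_sv, tau0) {
  if (any(tau0 <= 0)) .domain_error("`tau0` must be positive")
  k_sv / tau0
}

#' Classify the quenching mechanism across temperatures
#'
#' Static quenching (ground-state complex) shows `K_sv` decreasing with
#' temperature together with apparent `K_q` above the diffusion-limited
#' maximum of 2e10 per molar per second; dynamic (collisional) quenching
#' shows `K_sv` increasing with temperature and `K_q` at or below that
#' limit.  Conflicting evidence yields `"indeterminate"`.
#'
#' @param results List of [fit_stern_volmer()] results (with `k_q`
#'   filled) at two or more distinct temperatures.
#' @param kq_limit Diffusion-controlled ceiling, default `2e10`.
#' @return One of `"static"`, `"dynamic"`, `"indeterminate"`.
#' @export
classify_quenching <- function(results, kq_limit = 2e10) {
  if (length(results) < 2)
    .insufficient_error("need Stern-Volmer results at >= 2 temperatures")
  temps <- vapply(results, function(r) r$temperature_c, numeric(1))
  if (length(unique(temps)) < 2)
    .insufficient_error("need >= 2 distinct temperatures")
  ord <- order(temps)
  ksv <- vapply(results, function(r) r$k_sv, numeric(1))[ord]
  kq <- vapply(results, function(r) r$k_q, numeric(1))
  if (anyNA(kq))
    .validation_error("K_q missing: fit with `tau0` before classifying")
  decreasing <- all(diff(ksv) < 0)
  increasing <- all(diff(ksv) > 0)
  if (decreasing && all(kq > kq_limit)) "static"
  else if (increasing && all(kq <= kq_limit)) "dynamic"
  else "indeterminate"
}

#' Double-logarithmic binding fit (binding constant and apparent n)
#'
#' Fits `log10((F0 - F)/F) = log10(K_b) + n log10([Q])` by least
#' squares.  The intercept gives the binding constant `K_b` and the
#' slope the apparent exponent `n`; `n` reflects heterogeneity and
#' partial fluorophore accessibility and must not be read as a literal
#' binding-site count.  Points with `F >= F0` (logarithm undefined) are
#' dropped with a warning and counted in `n_dropped`.
#'
#' @param tit A [quench_titration()]; stored absorbances are applied as
#'   inner-filter corrections first.
#' @return An object of class `"binding_fit"` with `k_b` (per molar),
#'   `n` (apparent), `r_squared`, `temperature_c`, `n_points`,
#'   `n_dropped`.
#' @examples
#' q <- c(0, seq(2, 20, 2)) * 1e-6
#' f <- 1000 / (1 + 9.33e4 * q^1.15)
#' coef(fit_binding_double_log(quench_titration(q, f, 37)))
#' @export
fit_binding_double_log <- function(tit) {
  stopifnot(inherits(tit, "quench_titration"))
  f <- .corrected_f(tit)
  q <- tit$q_conc
  f0 <- f[1]
  use <- q > 0 & f < f0
  n_dropped <- sum(q > 0) - sum(use)
  if (n_dropped > 0)
    warning(sprintf("%d point(s) with F >= F0 dropped from binding fit",
                    n_dropped))
  if (sum(use) < 4)
    .insufficient_error("binding fit needs >= 4 points with F < F0")
  x <- log10(q[use])
  y <- log10((f0 - f[use]) / f[use])
  fit <- stats::lm(y ~ x)
  structure(list(k_b = 10^unname(stats::coef(fit)[1]),
                 n = unname(stats::coef(fit)[2]),
                 r_squared = .r_squared(y, stats::fitted(fit)),
                 temperature_c = tit$temperature_c,
                 n_points = sum(use), n_dropped = n_dropped),
            class = "binding_fit")
}

#' @export
coef.binding_fit <- function(object, ...) c(k_b = object$k_b, n = object$n)

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Double-log binding fit at %g degC (n = %d, dropped %d)\n",
              x$temperature_c, x$n_points, x$n_dropped))
  cat(sprintf("  K_b = %.4g M^-1   apparent n = %.3f   R^2 = %.4f\n",
              x$k_b, x$n, x$r_squared))
  invisible(x)
}
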