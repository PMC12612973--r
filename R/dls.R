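#' Construct an intensity-weighted particle size distribution
#'
#' @param rh_grid Strictly increasing hydrodynamic radii in nm.
#' @param weights Non-negative intensity weights; normalized to sum to 1.
#' @return An object of class `"size_distribution"`.
#' @export
size_distribution <- function(rh_grid, weights) {
  rh_grid <- as.numeric(rh_grid); weights <- as.numeric(weights)
  if (length(rh_grid) != length(weights))
    .validation_error("rh_grid and weights must have the same length")
  if (any(diff(rh_grid) <= 0))
    .validation_error("rh_grid must be strictly increasing")
  if (any(weights < 0)) .validation_error("weights must be non-negative")
  tot <- sum(weights)
  if (tot <= 0) .validation_error("total weight must be positive")
  structure(list(rh_grid = rh_grid, weights = weights / tot),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf(
    "Size distribution: %d grid points, R_h in [%.3g, %.3g] nm, mean %.3g nm\n",
    length(x$rh_grid), min(x$rh_grid), max(x$rh_grid),
    sum(x$rh_grid * x$weights)))
  invisible(x)
}

#' Construct a DLS autocorrelation curve with instrument geometry
#'
#' @param lags Strictly increasing lag times in seconds.
#' @param g2_minus_1 Normalized intensity autocorrelation minus baseline,
#'   positive at the shortest lag and decaying toward 0.
#' @param wavelength_nm Laser wavelength (default 633).
#' @param angle_deg Scattering angle (default 90).
#' @param refractive_index Medium refractive index (default 1.33).
#' @param temperature_c Sample temperature in Celsius (default 25).
#' @param viscosity_pa_s Solvent viscosity in Pa s (default 8.9e-4,
#'   water at 25 degC).
#' @return An object of class `"autocorrelation_curve"`.
#' @export
autocorrelation_curve <- function(lags, g2_minus_1, wavelength_nm = 633,
                                  angle_deg = 90, refractive_index = 1.33,
                                  temperature_c = 25,
                                  viscosity_pa_s = 8.9e-4) {
  lags <- as.numeric(lags); g2_minus_1 <- as.numeric(g2_minus_1)
  if (length(lags) != length(g2_minus_1))
    .validation_error("lags and g2_minus_1 must have the same length")
  if (any(diff(lags) <= 0)) .validation_error("lags must be strictly increasing")
  if (g2_minus_1[1] <= 0)
    .validation_error("g2 - 1 must be positive at the shortest lag")
  structure(list(lags = lags, g2_minus_1 = g2_minus_1,
                 wavelength_nm = wavelength_nm, angle_deg = angle_deg,
                 refractive_index = refractive_index,
                 temperature_c = temperature_c,
                 viscosity_pa_s = viscosity_pa_s),
            class = "autocorrelation_curve")
}

#' @export
print.autocorrelation_curve <- function(x, ...) {
  cat(sprintf(
    "DLS autocorrelation: %d lags [%.3g, %.3g] s, %g nm / %g deg / n = %g\n",
    length(x$lags), min(x$lags), max(x$lags),
    x$wavelength_nm, x$angle_deg, x$refractive_index))
  invisible(x)
}

#' Scattering vector magnitude
#'
#' `q = 4 pi n sin(theta/2) / lambda` in inverse meters.
#'
#' @param wavelength_nm Laser wavelength in nm.
#' @param angle_deg Scattering angle in degrees.
#' @param refractive_index Medium refractive index.
#' @return q in m^-1.
#' @examples
#' scattering_vector(633, 90, 1.33)  # ~1.867e7
#' @export
scattering_vector <- function(wavelength_nm = 633, angle_deg = 90,
                              refractive_index = 1.33) {
  if (wavelength_nm <= 0 || angle_deg <= 0 || refractive_index <= 0)
    .domain_error("geometry parameters must be positive")
  4 * pi * refractive_index * sin(angle_deg * pi / 360) /
    (wavelength_nm * 1e-9)
}

#' Hydrodynamic radius from a diffusion coefficient (Stokes-Einstein)
#'
#' `R_h = k_B T / (6 pi eta D)` with `T = temperature_c + 273.15`,
#' returned in nm.  [diffusion_from_radius()] is the exact algebraic
#' inverse.
#'
#' @param diffusion_m2_s Translational diffusion coefficient in m^2/s.
#' @param temperature_c Temperature in Celsius.
#' @param viscosity_pa_s Solvent viscosity in Pa s.
#' @return Hydrodynamic radius in nm.
#' @examples
#' stokes_einstein_radius(1.2305e-10, 25, 8.872e-4)  # ~2 nm
#' @export
stokes_einstein_radius <- function(diffusion_m2_s, temperature_c,
                                   viscosity_pa_s) {
  if (any(diffusion_m2_s <= 0)) .domain_error("diffusion must be positive")
  if (any(viscosity_pa_s <= 0)) .domain_error("viscosity must be positive")
  t_k <- temperature_c + 273.15
  if (any(t_k <= 0)) .domain_error("absolute temperature must be positive")
  .kB * t_k / (6 * pi * viscosity_pa_s * diffusion_m2_s) * 1e9
}

#' @rdname stokes_einstein_radius
#' @param rh_nm Hydrodynamic radius in nm.
#' @return `diffusion_from_radius()` returns D in m^2/s.
#' @export
diffusion_from_radius <- function(rh_nm, temperature_c, viscosity_pa_s) {
  if (any(rh_nm <= 0)) .domain_error("radius must be positive")
  if (any(viscosity_pa_s <= 0)) .domain_error("viscosity must be positive")
  t_k <- temperature_c + 273.15
  .kB * t_k / (6 * pi * viscosity_pa_s * rh_nm * 1e-9)
}

#' Second-order cumulant analysis of a DLS autocorrelation curve
#'
#' Fits `ln(g2 - 1) = ln(beta) - 2 Gamma tau + mu2 tau^2` over the
#' initial decay (lags where `g2 - 1` exceeds 5% of its maximum) and
#' converts the mean decay rate to a diffusion coefficient
#' `D = Gamma / q^2` using the curve's instrument geometry.  The
#' polydispersity index is `PDI = mu2 / Gamma^2` (0 for a monodisperse,
#' single-exponential decay).
#'
#' @param curve An [autocorrelation_curve()].
#' @return An object of class `"cumulant_fit"` with `diffusion_m2_s`,
#'   `pdi`, `gamma_s` (mean decay rate, 1/s), `mu2`, `beta`, `q_m`,
#'   `rh_nm` (Stokes-Einstein radius from the curve's temperature and
#'   viscosity), `n_points`, `r_squared`.
#' @examples
#' tau <- seq(1e-5, 1.5e-3, length.out = 40)
#' cv <- autocorrelation_curve(tau, exp(-2 * 4e3 * tau))
#' fit_cumulant(cv)$diffusion_m2_s  # ~1.147e-11
#' @export
fit_cumulant <- function(curve) {
  stopifnot(inherits(curve, "autocorrelation_curve"))
  g <- curve$g2_minus_1
  tau <- curve$lags
  keep <- g > 0.05 * max(g) & g > 0
  if (sum(keep) < 10)
    .insufficient_error("cumulant fit needs >= 10 lag points in the decay")
  x <- tau[keep]; y <- log(g[keep])
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- stats::coef(fit)
  gamma <- -unname(cf[2]) / 2
  mu2 <- unname(cf[3])
  if (!is.finite(gamma) || gamma <= 0)
    .fit_rejected_error("autocorrelation does not decay: no diffusion rate")
  q <- scattering_vector(curve$wavelength_nm, curve$angle_deg,
                         curve$refractive_index)
  d <- gamma / q^2
  structure(list(diffusion_m2_s = d,
                 pdi = mu2 / gamma^2,
                 gamma_s = gamma, mu2 = mu2, beta = exp(unname(cf[1])),
                 q_m = q,
                 rh_nm = stokes_einstein_radius(d, curve$temperature_c,
                                                curve$viscosity_pa_s),
                 n_points = sum(keep),
                 r_squared = .r_squared(y, stats::fitted(fit))),
            class = "cumulant_fit")
}

#' @export
coef.cumulant_fit <- function(object, ...) {
  c(diffusion_m2_s = object$diffusion_m2_s, pdi = object$pdi,
    gamma_s = object$gamma_s)
}

#' @export
print.cumulant_fit <- function(x, ...) {
  cat("Second-order cumulant DLS fit\n")
  cat(sprintf("  Gamma = %.4g s^-1   D = %.4g m^2/s   PDI = %.3g\n",
              x$gamma_s, x$diffusion_m2_s, max(x$pdi, 0)))
  cat(sprintf("  R_h = %.4g nm (Stokes-Einstein)   n = %d   R^2 = %.4f\n",
              x$rh_nm, x$n_points, x$r_squared))
  invisible(x)
}

#' Intensity-weighted mean hydrodynamic radius within a peak window
#'
#' Restricts the distribution to `peak_window` and returns the
#' intensity-weighted mean radius `sum(w R) / sum(w)` — the per-peak
#' summary quoted for multimodal DLS size distributions.
#'
#' @param dist A [size_distribution()].
#' @param peak_window Length-2 numeric `(lo_nm, hi_nm)`; defaults to the
#'   full grid range.
#' @return Mean radius in nm.
#' @examples
#' d <- size_distribution(c(1, 3, 1000), c(0.25, 0.25, 0.5))
#' intensity_weighted_mean_rh(d, c(0, 10))  # 2
#' @export
intensity_weighted_mean_rh <- function(dist, peak_window = NULL) {
  stopifnot(inherits(dist, "size_distribution"))
  if (is.null(peak_window)) peak_window <- range(dist$rh_grid)
  if (length(peak_window) != 2 || peak_window[1] > peak_window[2])
    .domain_error("`peak_window` must be (lo_nm, hi_nm) with lo <= hi")
  sel <- dist$rh_grid >= peak_window[1] & dist$rh_grid <= peak_window[2]
  w <- dist$weights[sel]
  if (sum(w) <= 0)
    .domain_error("no intensity weight inside the requested window")
  sum(w * dist$rh_grid[sel]) / sum(w)
}
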