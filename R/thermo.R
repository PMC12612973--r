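#' Van't Hoff analysis of temperature-dependent binding constants
#'
#' Regresses `ln K_b` on `1/T` (T in Kelvin):
#' `ln K_b = -dH/(R T) + dS/R`, so the slope gives the standard binding
#' enthalpy `dH = -slope * R` and the intercept the entropy
#' `dS = intercept * R`, with `R = 8.314 J/(mol K)`.  The Gibbs energy at
#' each input temperature is filled in via [gibbs_from_enthalpy()].
#'
#' Celsius temperatures are converted with the integer offset
#' `T_K = T_C + 273`, the convention under which the enthalpy/entropy
#' pair reproduces the tabulated Gibbs energies exactly.
#'
#' @param temperature K_b pairs: either a data frame with columns
#'   `temperature_c` (or `temperature_k`) and `k_b`, or two vectors via
#'   `temperature` and `k_b`.
#' @param k_b Binding constants (per molar), `> 0`, one per temperature.
#' @param celsius Logical: is `temperature` in Celsius? Default `TRUE`.
#' @param kelvin_offset Offset used when `celsius = TRUE`; default 273.
#'
#' @return An object of class `"vanthoff_fit"` with `delta_h` (kJ/mol),
#'   `delta_s` (J/(mol K)), `delta_g` (kJ/mol, named by temperature),
#'   `temperatures_k`, `r_squared`.
#' @examples
#' Tk <- c(298, 303, 310)
#' kb <- exp(-53.31e3 / (8.314 * Tk) + 199 / 8.314)
#' fit_vant_hoff(Tk, kb, celsius = FALSE)
#' @export
fit_vant_hoff <- function(temperature, k_b, celsius = TRUE,
                          kelvin_offset = 273) {
  if (is.data.frame(temperature)) {
    df <- temperature
    if ("temperature_k" %in% names(df)) {
      temperature <- df$temperature_k; celsius <- FALSE
    } else if ("temperature_c" %in% names(df)) {
      temperature <- df$temperature_c; celsius <- TRUE
    } else .validation_error("data frame needs temperature_c or temperature_k")
    k_b <- df$k_b
  }
  temperature <- as.numeric(temperature); k_b <- as.numeric(k_b)
  if (length(temperature) != length(k_b))
    .validation_error("temperature and k_b must have the same length")
  if (any(k_b <= 0)) .domain_error("K_b values must be positive")
  t_k <- if (celsius) temperature + kelvin_offset else temperature
  if (any(t_k <= 0)) .domain_error("absolute temperatures must be positive")
  if (length(unique(t_k)) < 2)
    .insufficient_error("Van't Hoff fit needs >= 2 distinct temperatures")
  x <- 1 / t_k
  y <- log(k_b)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  delta_h <- -slope * .R_gas / 1000       # kJ/mol
  delta_s <- intercept * .R_gas           # J/(mol K)
  delta_g <- gibbs_from_enthalpy(delta_h, delta_s, t_k)
  names(delta_g) <- sprintf("%g", t_k)
  r2 <- .r_squared(y, stats::fitted(fit))
  if (is.na(r2)) r2 <- 1            # flat line: fit is exact
  structure(list(delta_h = delta_h, delta_s = delta_s, delta_g = delta_g,
                 temperatures_k = t_k, r_squared = r2),
            class = "vanthoff_fit")
}

#' @export
coef.vanthoff_fit <- function(object, ...) {
  c(delta_h_kJ_mol = object$delta_h, delta_s_J_mol_K = object$delta_s)
}

#' @export
print.vanthoff_fit <- function(x, ...) {
  cat("Van't Hoff binding thermodynamics\n")
  cat(sprintf("  dH = %.2f kJ/mol   dS = %.2f J/(mol K)   R^2 = %.4f\n",
              x$delta_h, x$delta_s, x$r_squared))
  for (i in seq_along(x$temperatures_k))
    cat(sprintf("  dG(%g K) = %.2f kJ/mol\n",
                x$temperatures_k[i], x$delta_g[i]))
  invisible(x)
}

#' @rdname fit_vant_hoff
#' @param object A `vanthoff_fit`.
#' @param newdata Optional Kelvin temperatures at which to predict ln K_b.
#' @param ... Unused.
#' @return `predict()` returns predicted K_b at the given Kelvin
#'   temperatures.
#' @export
predict.vanthoff_fit <- function(object, newdata = NULL, ...) {
  t_k <- if (is.null(newdata)) object$temperatures_k else as.numeric(newdata)
  exp(-object$delta_h * 1000 / (.R_gas * t_k) + object$delta_s / .R_gas)
}

#' Gibbs free energy from enthalpy and entropy
#'
#' `dG = dH - T dS` with `dH` in kJ/mol, `dS` in J/(mol K) and `dG`
#' returned in kJ/mol.
#'
#' @param delta_h Enthalpy, kJ/mol.
#' @param delta_s Entropy, J/(mol K).
#' @param temperature_k Absolute temperature(s) in Kelvin, `> 0`.
#' @return Gibbs energy in kJ/mol (vectorized over `temperature_k`).
#' @examples
#' gibbs_from_enthalpy(53.31, 199, 310)  # -8.38
#' @export
gibbs_from_enthalpy <- function(delta_h, delta_s, temperature_k) {
  if (any(temperature_k <= 0)) .domain_error("temperature_k must be positive")
  delta_h - temperature_k * delta_s / 1000
}

#' Gibbs free energy from a binding constant
#'
#' `dG = -R T ln(K_b)` in kJ/mol.  This is the second, independent route
#' to the binding free energy; it is reported separately from
#' [gibbs_from_enthalpy()] and the two are never averaged, since with
#' noisy inputs they need not agree.
#'
#' @param k_b Binding constant, per molar, `> 0`.
#' @param temperature_k Absolute temperature in Kelvin, `> 0`.
#' @return Gibbs energy in kJ/mol.
#' @examples
#' gibbs_from_kb(3500, 310)  # about -21
#' @export
gibbs_from_kb <- function(k_b, temperature_k) {
  if (any(k_b <= 0)) .domain_error("k_b must be positive")
  if (any(temperature_k <= 0)) .domain_error("temperature_k must be positive")
  -.R_gas * temperature_k * log(k_b) / 1000
}
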