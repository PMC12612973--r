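#' Percent inhibition of an endpoint aggregation signal
#'
#' `100 * (1 - signal_sample / signal_control)` for blank-corrected
#' endpoint signals (ThT fluorescence or total scattered intensity at
#' the incubation endpoint).  Values are capped above at 100; a sample
#' brighter than the control yields a negative percentage (promotion).
#' The metric is invariant under common rescaling of both signals.
#'
#' @param signal_sample Endpoint signal with inhibitor, `>= 0`.
#' @param signal_control Endpoint signal of the uninhibited control,
#'   `> 0`.
#' @return Percent inhibition (vectorized over `signal_sample`).
#' @examples
#' percent_inhibition(8.5, 100)  # 91.5
#' @export
percent_inhibition <- function(signal_sample, signal_control) {
  if (any(signal_control <= 0))
    .domain_error("`signal_control` must be positive")
  pmin(100 * (1 - signal_sample / signal_control), 100)
}

## 4PL forward model: decreasing in dose for hill > 0
.logistic4 <- function(dose, ic50, hill, top, bottom) {
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

#' Four-parameter log-logistic IC50 fit
#'
#' Fits the 4PL dose-response model
#' `response = bottom + (top - bottom) / (1 + (dose/ic50)^hill)`
#' by Levenberg-Marquardt nonlinear least squares, with `ic50` and
#' `hill` fitted on the log scale (positivity structural).  The reported
#' IC50 is the inflection dose, i.e. the concentration producing the
#' half-maximal response.  Start values come from the data: `top` and
#' `bottom` from the extreme responses, `ic50` from the dose whose
#' response is nearest the midpoint; the fit is multi-started over hill
#' slopes {0.5, 1, 2}.
#'
#' @param doses Dose levels in uM (a zero dose is allowed as anchor).
#' @param responses Response at each dose (signal units; typically
#'   remaining aggregation signal, decreasing with dose).
#' @return An object of class `"ic50_fit"` with `ic50` (uM), `hill`,
#'   `top`, `bottom`, `r_squared`, `n_points`, `monotone_warning`.
#'   Methods: `print`, `coef`, `predict`, `residuals`.
#' @examples
#' d <- c(0.1, 0.3, 1, 3, 10, 30)
#' fit_ic50(d, 100 / (1 + d / 3.04))$ic50
#' @export
fit_ic50 <- function(doses, responses) {
  doses <- as.numeric(doses); responses <- as.numeric(responses)
  if (length(doses) != length(responses))
    .validation_error("doses and responses must have the same length")
  if (any(doses < 0)) .domain_error("doses must be non-negative")
  if (length(unique(doses)) < 5)
    .insufficient_error("IC50 fit needs >= 5 dose levels")
  rng <- diff(range(responses))
  if (rng <= 0 || rng < 1e-6 * max(abs(responses)))
    .fit_rejected_error("flat dose-response: no IC50 can be estimated")

  pos <- doses > 0
  top0 <- max(responses); bottom0 <- min(responses)
  mid <- (top0 + bottom0) / 2
  ic50_0 <- doses[pos][which.min(abs(responses[pos] - mid))]
  if (length(ic50_0) == 0 || ic50_0 <= 0) ic50_0 <- stats::median(doses[pos])

  best <- NULL
  for (h0 in c(0.5, 1, 2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        responses ~ .logistic4(doses, exp(lic50), exp(lhill), top, bottom),
        start = list(lic50 = log(ic50_0), lhill = log(h0),
                     top = top0, bottom = bottom0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    .convergence_error("IC50 fit failed to converge from all starts")
  p <- stats::coef(best$fit)
  ic50 <- exp(unname(p["lic50"])); hill <- exp(unname(p["lhill"]))
  top <- unname(p["top"]); bottom <- unname(p["bottom"])
  yhat <- .logistic4(doses, ic50, hill, top, bottom)
  rss <- sum((responses - yhat)^2)
  tss <- sum((responses - mean(responses))^2)
  # monotonicity check on dose-sorted responses (direction: decreasing)
  ord <- order(doses)
  runs <- diff(responses[ord])
  monotone_warning <- any(runs > 0.1 * rng)
  structure(list(ic50 = ic50, hill = hill, top = top, bottom = bottom,
                 r_squared = 1 - rss / tss,
                 n_points = length(doses),
                 monotone_warning = monotone_warning,
                 doses = doses, responses = responses, fitted = yhat),
            class = "ic50_fit")
}

#' @export
coef.ic50_fit <- function(object, ...) {
  c(ic50 = object$ic50, hill = object$hill,
    top = object$top, bottom = object$bottom)
}

#' @export
residuals.ic50_fit <- function(object, ...) object$responses - object$fitted

#' @rdname fit_ic50
#' @param object,x An `ic50_fit` object.
#' @param newdata Optional doses (uM) at which to evaluate the curve.
#' @param ... Unused.
#' @export
predict.ic50_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$doses else as.numeric(newdata)
  .logistic4(d, object$ic50, object$hill, object$top, object$bottom)
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("4PL dose-response fit (n = %d)   R^2 = %.4f\n",
              x$n_points, x$r_squared))
  cat(sprintf("  IC50 = %.3g uM   hill = %.3g   top = %.4g   bottom = %.4g\n",
              x$ic50, x$hill, x$top, x$bottom))
  if (x$monotone_warning)
    cat("  warning: response non-monotone beyond noise\n")
  invisible(x)
}
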