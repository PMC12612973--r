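#' Construct a kinetic aggregation trace
#'
#' A `kinetic_trace` holds one replicate of an aggregation time course:
#' time in hours against a fluorescence-type signal (ThT, ANS, scattered
#' intensity).  Raw traces carry arbitrary units; after
#' [normalize_trace()] the signal is the fraction of the (group) maximum
#' and lives in \[0, 1\].
#'
#' @param times Numeric vector of times in hours, strictly increasing,
#'   all `>= 0`.
#' @param signal Numeric vector of signal values, same length as `times`.
#' @param replicate_id Label for the replicate (default `"r1"`).
#' @param is_normalized Logical; `TRUE` once the signal is a fraction of
#'   the maximum fluorescence.
#' @param blank Optional scalar background already associated with the
#'   trace (informational; subtraction happens in [normalize_trace()]).
#'
#' @return An object of class `"kinetic_trace"`: a list with fields
#'   `times`, `signal`, `replicate_id`, `is_normalized`, `blank`.
#' @examples
#' tr <- kinetic_trace(0:10, c(0, 0.01, 0.03, 0.1, 0.3, 0.55, 0.8,
#'                             0.92, 0.98, 1, 1))
#' tr
#' @export
kinetic_trace <- function(times, signal, replicate_id = "r1",
                          is_normalized = FALSE, blank = NULL) {
  times <- as.numeric(times)
  signal <- as.numeric(signal)
  if (length(times) != length(signal))
    .validation_error("`times` and `signal` must have the same length")
  if (anyNA(times) || anyNA(signal))
    .validation_error("times and signal must not contain NA")
  if (any(times < 0))
    .validation_error("times must be non-negative")
  if (length(times) > 1 && any(diff(times) <= 0))
    .validation_error("times must be strictly increasing")
  if (isTRUE(is_normalized)) {
    if (any(signal < 0) || any(signal > 1 + 1e-12))
      .validation_error("normalized signal must lie in [0, 1]")
  }
  structure(list(times = times, signal = signal,
                 replicate_id = as.character(replicate_id),
                 is_normalized = isTRUE(is_normalized),
                 blank = blank),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("Kinetic trace '%s': %d points, t = [%.3g, %.3g] h, %s\n",
              x$replicate_id, length(x$times),
              min(x$times), max(x$times),
              if (x$is_normalized) "normalized" else "raw signal"))
  invisible(x)
}

#' Normalize an aggregation trace to fibrillar fraction
#'
#' Subtracts the blank, clips below at zero and divides by the largest
#' blank-corrected signal.  When replicates are normalized as a group,
#' pass the group's highest blank-corrected signal as `group_max` so that
#' only the brightest replicate reaches exactly 1 (the shared-maximum
#' convention used when several trials of one condition are reported
#' together).
#'
#' @param raw A raw (unnormalized) [kinetic_trace()].
#' @param blank Scalar background to subtract, `>= 0`. Default 0.
#' @param group_max Optional positive scalar: the highest blank-corrected
#'   signal across the replicate group. Defaults to the trace's own
#'   maximum.
#'
#' @return A normalized `kinetic_trace` on the same time grid.
#' @examples
#' tr <- kinetic_trace(c(0, 1, 2), c(10, 60, 110))
#' normalize_trace(tr, blank = 10)$signal  # 0, 0.5, 1
#' @export
normalize_trace <- function(raw, blank = 0, group_max = NULL) {
  stopifnot(inherits(raw, "kinetic_trace"))
  if (raw$is_normalized)
    .validation_error("trace is already normalized")
  if (length(blank) != 1 || is.na(blank) || blank < 0)
    .domain_error("`blank` must be a single non-negative number")
  corrected <- pmax(raw$signal - blank, 0)
  own_max <- max(corrected)
  if (own_max <= 0)
    .degenerate_error("trace has no signal above blank (zero dynamic range)")
  if (is.null(group_max)) group_max <- own_max
  if (length(group_max) != 1 || is.na(group_max) || group_max <= 0)
    .domain_error("`group_max` must be a single positive number")
  kinetic_trace(raw$times, corrected / group_max,
                replicate_id = raw$replicate_id,
                is_normalized = TRUE, blank = blank)
}

#' Threshold times of an aggregation trace
#'
#' Locates the times at which the signal first rises through 10%, 50%
#' and 90% of the highest fluorescence (t0, the onset of aggregation;
#' t1/2, the halftime; t1, the endpoint).  For a normalized trace the
#' reference maximum is 1 — the group's highest blank-corrected signal —
#' so a replicate that plateaus below the group maximum can leave upper
#' thresholds unreached; for a raw trace the trace's own maximum is
#' used.  Crossings are found on the data by linear interpolation
#' between the bracketing samples; when the signal is non-monotone the
#' first upward crossing wins, and a sample that hits a threshold
#' exactly counts as a crossing.  A threshold the trace never reaches
#' yields `NA` for that time, not an error.
#'
#' @param trace A [kinetic_trace()], normally normalized.
#' @param fractions Three strictly increasing fractions in (0, 1);
#'   default `c(0.1, 0.5, 0.9)`.
#'
#' @return Named numeric vector `c(t0 = , t_half = , t1 = )` in hours.
#' @examples
#' tr <- kinetic_trace(seq(0, 10), seq(0, 1, length.out = 11),
#'                     is_normalized = TRUE)
#' threshold_times(tr)  # 1, 5, 9
#' @export
threshold_times <- function(trace, fractions = c(0.1, 0.5, 0.9)) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (length(fractions) != 3 || any(fractions <= 0) || any(fractions >= 1) ||
      any(diff(fractions) <= 0))
    .domain_error("`fractions` must be three increasing values in (0, 1)")
  s <- trace$signal
  t <- trace$times
  smax <- if (trace$is_normalized) 1 else max(s)
  if (max(s) <= 0) .degenerate_error("trace maximum is not positive")
  out <- vapply(fractions, function(fr) {
    level <- fr * smax
    if (s[1] >= level) return(t[1])
    for (i in seq_len(length(s) - 1)) {
      # first upward crossing; exact hits at the right endpoint count
      if (s[i] < level && s[i + 1] >= level) {
        return(t[i] + (level - s[i]) / (s[i + 1] - s[i]) * (t[i + 1] - t[i]))
      }
    }
    NA_real_
  }, numeric(1))
  names(out) <- c("t0", "t_half", "t1")
  out
}
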