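#' Trapezoid response parameters
#'
#' Parameterises the idealised vascular reactivity response within one
#' stimulation block as a trapezoid in percent-BOLD-change units: the signal
#' rises linearly from `baseline` at block onset (t = 0) to
#' `baseline + amplitude` at `t_peak`, stays on that plateau until
#' `t_fall_start` (fixed at the end of the stimulus), then descends linearly
#' back to `baseline`, which it regains at `t_return`.
#'
#' Time-to-peak is `t_peak` (measured from block onset at t = 0);
#' time-to-baseline is `t_return - t_fall_start` (measured from stimulus
#' offset); amplitude is the plateau height above baseline.
#'
#' @param baseline Baseline level, percent change.
#' @param amplitude Plateau height above baseline, percent change. May be
#'   negative for a fitted deactivation.
#' @param t_peak Plateau onset, seconds from block start; 0 < t_peak <=
#'   t_fall_start.
#' @param t_return Time baseline is regained, seconds from block start;
#'   t_fall_start <= t_return.
#' @param t_fall_start Start of the descending edge, seconds; by convention
#'   the stimulus offset (20 s in the default paradigm).
#' @return An object of class `trapezoid_params`.
#' @examples
#' p <- trapezoid_params(baseline = 0, amplitude = 1, t_peak = 6,
#'                       t_return = 28)
#' trapezoid_value(c(0, 3, 10, 24, 40), p)
#' @export
trapezoid_params <- function(baseline = 0, amplitude = 1, t_peak = 6,
                             t_return = 28, t_fall_start = 20) {
  stopifnot(
    is.numeric(baseline), is.numeric(amplitude),
    "t_peak must satisfy 0 < t_peak <= t_fall_start" =
      is.numeric(t_peak) && t_peak > 0 && t_peak <= t_fall_start,
    "t_return must be >= t_fall_start" =
      is.numeric(t_return) && t_return >= t_fall_start
  )
  structure(
    list(baseline = baseline, amplitude = amplitude, t_peak = t_peak,
         t_return = t_return, t_fall_start = t_fall_start),
    class = "trapezoid_params"
  )
}

#' @export
print.trapezoid_params <- function(x, ...) {
  cat(sprintf(
    "<trapezoid_params> baseline %.3g, amplitude %.3g, t_peak %.3g s, t_return %.3g s (fall from %.3g s)\n",
    x$baseline, x$amplitude, x$t_peak, x$t_return, x$t_fall_start))
  invisible(x)
}

#' Evaluate the trapezoid response
#'
#' Piecewise-linear evaluation of the trapezoid described by
#' [trapezoid_params()]. Outside the block (t < 0 or t > t_return) the value
#' is the baseline. The function is continuous in t.
#'
#' @param t Time(s) in seconds, vectorised.
#' @param params A [trapezoid_params()].
#' @return Numeric vector of percent-change values, same length as `t`.
#' @export
trapezoid_value <- function(t, params) {
  stopifnot(inherits(params, "trapezoid_params"))
  params$baseline + params$amplitude *
    trapezoid_unit(t, params$t_peak, params$t_return, params$t_fall_start)
}

# Unit trapezoid (baseline 0, plateau 1); the shape basis used by the fitter.
# Vectorised over t and over the breakpoints. Handles the degenerate step
# case t_return == t_fall_start (plateau up to and including t_fall_start).
trapezoid_unit <- function(t, t_peak, t_return, t_fall_start) {
  n <- max(length(t), length(t_peak), length(t_return),
           length(t_fall_start))
  t <- rep_len(t, n)
  tp <- rep_len(t_peak, n)
  tr_ <- rep_len(t_return, n)
  tf <- rep_len(t_fall_start, n)
  rise <- t / tp
  denom <- tr_ - tf
  pos <- denom > 0
  fall <- numeric(n)
  fall[pos] <- (tr_[pos] - t[pos]) / denom[pos]
  fall[!pos] <- ifelse(t[!pos] <= tf[!pos], Inf, -Inf)
  pmax(0, pmin(rise, 1, fall))
}
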