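#' A sampled BOLD timeseries
#'
#' A regularly sampled one-dimensional signal: raw scanner units for an
#' extracted ROI-mean timeseries, or percent-change units for a block
#' average. `t0` is the time of the first sample relative to block (or run)
#' onset; with the package's sampling convention `t0 = 0`.
#'
#' @param values Numeric vector of samples (length >= 2, no missing values).
#' @param tr Sampling interval in seconds (> 0).
#' @param t0 Time of the first sample, seconds.
#' @param units Unit label, e.g. `"signal"` or `"percent"`.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(values, tr, t0 = 0, units = "signal") {
  stopifnot(
    "values must be numeric with at least 2 samples" =
      is.numeric(values) && length(values) >= 2,
    "values must not contain missing values" = !anyNA(values),
    "tr must be > 0" = is.numeric(tr) && length(tr) == 1 && tr > 0
  )
  structure(list(values = as.numeric(values), tr = tr, t0 = t0,
                 units = units),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series> %d samples @ TR %g s (t0 = %g s, %s units)\n",
              length(x$values), x$tr, x$t0, x$units))
  invisible(x)
}

#' @export
length.bold_series <- function(x) length(x$values)

#' Sample times of a series
#' @param x A [bold_series()].
#' @return Numeric vector of times in seconds.
#' @export
series_times <- function(x) {
  stopifnot(inherits(x, "bold_series"))
  x$t0 + (seq_along(x$values) - 1) * x$tr
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.bold_series <- function(x, ...) {
  tibble::tibble(time = series_times(x), value = x$values)
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.bold_series <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)",
                  y = paste0("BOLD (", object$units, ")")) +
    ggplot2::theme_minimal()
}
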