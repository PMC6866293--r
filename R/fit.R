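#' Fit a trapezoid to the average block response
#'
#' Least-squares fit of the trapezoid model ([trapezoid_value()]) to an
#' averaged percent-change block, over (baseline, amplitude, t_peak,
#' t_return) with the start of the descending edge fixed at the stimulus
#' offset.
#'
#' The optimisation is a profiled breakpoint search: for every candidate
#' (t_peak, t_return) pair on a regular grid, baseline and amplitude solve a
#' two-parameter linear least-squares problem in closed form; the global grid
#' minimum is then optionally polished by box-constrained continuous
#' optimisation of the same profiled objective. The returned SSE is never
#' above the SSE at any grid point. A perfectly flat input is fitted with
#' amplitude 0 and t_peak at the smallest grid value (the documented
#' tie-break, since all breakpoints fit a flat series equally well).
#'
#' @param avg A [bold_series()]: the average block in percent-change units,
#'   with at least 6 samples spanning one block.
#' @param paradigm A [stimulus_paradigm()]; fixes the descending-edge anchor
#'   at `stim_duration` and the admissible t_return range at
#'   `[stim_duration, block_length]`.
#' @param grid_resolution Breakpoint grid step in seconds (default 0.25).
#' @param refine Polish the grid optimum with L-BFGS-B (default TRUE).
#' @return An object of class `trapezoid_fit`: `params`
#'   ([trapezoid_params()]), `time_to_peak`, `time_to_baseline`, `amplitude`,
#'   `sse`, `n_samples`, `fitted`, `data` (the input series).
#' @examples
#' p <- stimulus_paradigm()
#' truth <- trapezoid_params(0, 1, 6, 28)
#' avg <- bold_series(trapezoid_value(block_time_grid(p), truth), tr = p$tr,
#'                    units = "percent")
#' fit <- fit_trapezoid(avg, p)
#' tidy(fit)
#' @export
fit_trapezoid <- function(avg, paradigm, grid_resolution = 0.25,
                          refine = TRUE) {
  stopifnot(inherits(avg, "bold_series"),
            inherits(paradigm, "stimulus_paradigm"),
            "grid_resolution must be > 0" = grid_resolution > 0)
  y <- avg$values
  n <- length(y)
  if (n < 6) {
    stop("need at least 6 samples to fit 4 parameters stably; got ", n,
         call. = FALSE)
  }
  times <- series_times(avg)
  t_fall <- paradigm$stim_duration
  t_max <- block_length(paradigm)

  grid <- trapezoid_breakpoint_grid(t_fall, t_max, grid_resolution)
  prof <- profile_breakpoints(times, y, grid$t_peak, grid$t_return, t_fall)
  best <- which.min(prof$sse)
  sol <- list(t_peak = grid$t_peak[best], t_return = grid$t_return[best],
              baseline = prof$baseline[best], amplitude = prof$amplitude[best],
              sse = prof$sse[best])

  if (refine) {
    # The profiled SSE surface has kinks wherever a breakpoint crosses a
    # sample time, so a single local descent can settle in the wrong cell.
    # Zoom: re-profile a fine local grid around the best coarse candidates
    # (vectorised, cheap), then polish the winner continuously.
    ord <- order(prof$sse)[seq_len(min(100L, length(prof$sse)))]
    step <- grid_resolution / 25
    zoom_tp <- zoom_tr <- numeric(0)
    for (i in ord) {
      tps <- seq(max(step, grid$t_peak[i] - grid_resolution),
                 min(t_fall, grid$t_peak[i] + grid_resolution), by = step)
      trs <- seq(max(t_fall, grid$t_return[i] - grid_resolution),
                 min(t_max, grid$t_return[i] + grid_resolution), by = step)
      zoom_tp <- c(zoom_tp, rep(tps, times = length(trs)))
      zoom_tr <- c(zoom_tr, rep(trs, each = length(tps)))
    }
    zprof <- profile_breakpoints(times, y, zoom_tp, zoom_tr, t_fall)
    zb <- which.min(zprof$sse)
    if (zprof$sse[zb] < sol$sse) {
      sol <- list(t_peak = zoom_tp[zb], t_return = zoom_tr[zb],
                  baseline = zprof$baseline[zb],
                  amplitude = zprof$amplitude[zb], sse = zprof$sse[zb])
    }
    ref <- refine_breakpoints(times, y, sol$t_peak, sol$t_return, t_fall,
                              t_max, grid_resolution)
    if (ref$sse < sol$sse) sol <- ref
  }

  params <- trapezoid_params(baseline = sol$baseline,
                             amplitude = sol$amplitude,
                             t_peak = sol$t_peak, t_return = sol$t_return,
                             t_fall_start = t_fall)
  structure(
    list(params = params,
         time_to_peak = sol$t_peak,
         time_to_baseline = sol$t_return - t_fall,
         amplitude = sol$amplitude,
         sse = sol$sse,
         n_samples = n,
         fitted = trapezoid_value(times, params),
         data = avg),
    class = "trapezoid_fit"
  )
}

# all admissible (t_peak, t_return) pairs on a regular grid; ordered so that
# which.min()'s first-minimum rule lands on the smallest t_peak, then the
# smallest t_return (the flat-input tie-break)
trapezoid_breakpoint_grid <- function(t_fall, t_max, res) {
  tp <- seq(res, t_fall, by = res)
  if (abs(tp[length(tp)] - t_fall) > 1e-9) tp <- c(tp, t_fall)
  tr_ <- seq(t_fall, t_max, by = res)
  if (abs(tr_[length(tr_)] - t_max) > 1e-9) tr_ <- c(tr_, t_max)
  list(t_peak = rep(tp, times = length(tr_)),
       t_return = rep(tr_, each = length(tp)))
}

# closed-form profiled LS over (baseline, amplitude) for each breakpoint
# pair; vectorised across pairs. Returns per-pair baseline, amplitude, sse.
profile_breakpoints <- function(times, y, t_peak, t_return, t_fall) {
  n <- length(y)
  npair <- length(t_peak)
  # shape matrix: pairs x samples, unit trapezoid at each sample time
  S <- matrix(0, nrow = npair, ncol = n)
  for (j in seq_len(n)) {
    S[, j] <- trapezoid_unit(times[j], t_peak, t_return, t_fall)
  }
  sbar <- rowMeans(S)
  ybar <- mean(y)
  Sc <- S - sbar
  yc <- y - ybar
  Sss <- rowSums(Sc * Sc)
  Ssy <- as.vector(Sc %*% yc)
  Syy <- sum(yc * yc)
  amp <- ifelse(Sss > 0, Ssy / Sss, 0)
  sse <- pmax(Syy - amp * Ssy, 0)
  # degenerate shape (constant over the samples): flat fit, amplitude 0
  sse[Sss <= 0] <- Syy
  list(baseline = ybar - amp * sbar, amplitude = amp, sse = sse)
}

# profiled SSE at one (t_peak, t_return); shared by the refiner
profiled_sse_at <- function(times, y, t_peak, t_return, t_fall) {
  s <- trapezoid_unit(times, t_peak, t_return, t_fall)
  sc <- s - mean(s)
  yc <- y - mean(y)
  sss <- sum(sc * sc)
  if (sss <= 0) {
    return(list(sse = sum(yc^2), amplitude = 0, baseline = mean(y)))
  }
  amp <- sum(sc * yc) / sss
  list(sse = max(sum(yc^2) - amp * sum(sc * yc), 0),
       amplitude = amp, baseline = mean(y) - amp * mean(s))
}

refine_breakpoints <- function(times, y, tp0, tr0, t_fall, t_max, res) {
  lower <- c(min(res, t_fall) * 1e-3, t_fall)
  upper <- c(t_fall, t_max)
  obj <- function(par) {
    profiled_sse_at(times, y, par[1], par[2], t_fall)$sse
  }
  opt <- tryCatch(
    stats::optim(c(tp0, tr0), obj, method = "L-BFGS-B",
                 lower = lower, upper = upper),
    error = function(e) NULL
  )
  if (is.null(opt)) return(list(sse = Inf))
  sol <- profiled_sse_at(times, y, opt$par[1], opt$par[2], t_fall)
  list(t_peak = opt$par[1], t_return = opt$par[2],
       baseline = sol$baseline, amplitude = sol$amplitude, sse = sol$sse)
}

#' Response metrics of a fitted trapezoid
#'
#' Time-to-peak is the plateau onset measured from block start (t = 0);
#' time-to-baseline is the interval from stimulus offset to the return to
#' baseline; amplitude is the plateau height above baseline.
#'
#' @param fit A [fit_trapezoid()] result.
#' @param paradigm A [stimulus_paradigm()] (fixes the stimulus offset).
#' @return A one-row tibble with `time_to_peak`, `time_to_baseline`,
#'   `amplitude`.
#' @export
extract_metrics <- function(fit, paradigm) {
  stopifnot(inherits(fit, "trapezoid_fit"),
            inherits(paradigm, "stimulus_paradigm"))
  tibble::tibble(
    time_to_peak = fit$params$t_peak,
    time_to_baseline = fit$params$t_return - paradigm$stim_duration,
    amplitude = fit$params$amplitude
  )
}

#' @export
print.trapezoid_fit <- function(x, ...) {
  cat(sprintf(
    "<trapezoid_fit> time-to-peak %.2f s, time-to-baseline %.2f s, amplitude %.3f%%\n",
    x$time_to_peak, x$time_to_baseline, x$amplitude))
  cat(sprintf("  baseline %.3f%%, SSE %.4g over %d samples\n",
              x$params$baseline, x$sse, x$n_samples))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.trapezoid_fit <- function(x, ...) {
  tibble::tibble(
    term = c("baseline", "amplitude", "time_to_peak", "time_to_baseline",
             "t_return"),
    estimate = c(x$params$baseline, x$amplitude, x$time_to_peak,
                 x$time_to_baseline, x$params$t_return),
    unit = c("percent", "percent", "s", "s", "s")
  )
}

#' @export
glance.trapezoid_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, n_samples = x$n_samples,
                 rmse = sqrt(x$sse / x$n_samples))
}

#' @export
autoplot.trapezoid_fit <- function(object, ...) {
  obs <- as_tibble(object$data)
  tt <- seq(min(obs$time), max(obs$time), by = 0.1)
  model <- tibble::tibble(time = tt,
                          value = trapezoid_value(tt, object$params))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = model, colour = "#c0392b") +
    ggplot2::labs(x = "time from block onset (s)",
                  y = "BOLD change (%)",
                  title = sprintf(
                    "trapezoid fit: peak %.1f s, return %.1f s, amplitude %.2f%%",
                    object$time_to_peak,
                    object$params$t_return, object$amplitude)) +
    ggplot2::theme_minimal()
}
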