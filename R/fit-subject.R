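#' Full subject-level vascular reactivity analysis
#'
#' Runs the complete per-subject chain on a 4D BOLD run: subject-level GLM
#' (Z-statistic map), functional ROI from the top `fraction` of activated
#' voxels, ROI-mean timeseries, block segmentation, percent-change
#' normalisation against the grand mean of all blocks, artifact-block
#' rejection at `threshold`% (strict inequality), block averaging, and
#' trapezoid fitting.
#'
#' @param run A [volume4d()].
#' @param paradigm A [stimulus_paradigm()].
#' @param fraction ROI fraction of in-mask voxels (default 0.2).
#' @param threshold Artifact rejection threshold, percent (default 3).
#' @param grid_resolution Trapezoid breakpoint grid step, seconds
#'   (default 0.25).
#' @param refine Continuous refinement of the fit (default TRUE).
#' @param highpass Optional high-pass cutoff in seconds for GLM drift
#'   columns; `NULL` (default) for none.
#' @param n_discard_initial_volumes Initial volumes to drop before analysis
#'   (e.g. dummy scans), default 0.
#' @return An object of class `fit_report`: `fit` ([fit_trapezoid()]
#'   result), `metrics` (one-row tibble), `n_blocks_total`,
#'   `n_blocks_retained`, `discarded_indices`, `normalization_mean`,
#'   `roi` ([top_fraction_mask()] result), `blocks` (`block_matrix`).
#' @export
fit_subject <- function(run, paradigm, fraction = 0.2, threshold = 3,
                        grid_resolution = 0.25, refine = TRUE,
                        highpass = NULL, n_discard_initial_volumes = 0) {
  stopifnot(inherits(run, "volume4d"), inherits(paradigm, "stimulus_paradigm"))
  if (n_discard_initial_volumes > 0) {
    nt <- n_volumes(run)
    run <- volume4d(run$data[, , , (n_discard_initial_volumes + 1):nt,
                             drop = FALSE],
                    run$mask, run$tr)
  }
  n_design <- paradigm$n_blocks * samples_per_block(paradigm)
  if (n_volumes(run) < n_design) {
    stop("run has ", n_volumes(run), " volumes but the design needs ",
         n_design, call. = FALSE)
  }
  design <- build_design_matrix(paradigm, n_volumes(run),
                                highpass = highpass)
  glm <- fit_glm(run, design)
  roi <- top_fraction_mask(glm$z, fraction = fraction)
  series <- roi_mean_timeseries(run, roi)
  blocks <- to_percent_change(segment_blocks(series, paradigm))
  blocks <- reject_artifact_blocks(blocks, threshold = threshold)
  avg <- average_block(blocks)
  fit <- fit_trapezoid(avg, paradigm, grid_resolution = grid_resolution,
                       refine = refine)
  structure(
    list(fit = fit,
         metrics = extract_metrics(fit, paradigm),
         n_blocks_total = nrow(blocks$blocks),
         n_blocks_retained = sum(blocks$retained),
         discarded_indices = which(!blocks$retained),
         normalization_mean = blocks$normalization_mean,
         roi = roi,
         blocks = blocks),
    class = "fit_report"
  )
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> %d/%d blocks retained", x$n_blocks_retained,
              x$n_blocks_total))
  if (length(x$discarded_indices)) {
    cat(" (discarded: ", paste(x$discarded_indices, collapse = ", "), ")",
        sep = "")
  }
  cat(sprintf(", normalization mean %.4g\n", x$normalization_mean))
  print(x$fit)
  invisible(x)
}

#' @export
tidy.fit_report <- function(x, ...) {
  dplyr::bind_cols(
    x$metrics,
    tibble::tibble(baseline = x$fit$params$baseline,
                   sse = x$fit$sse,
                   n_blocks_total = x$n_blocks_total,
                   n_blocks_retained = x$n_blocks_retained,
                   normalization_mean = x$normalization_mean)
  )
}

#' @export
autoplot.fit_report <- function(object, ...) {
  blk <- as_tibble(object$blocks)
  tt <- seq(0, max(blk$time), by = 0.1)
  model <- tibble::tibble(time = tt,
                          value = trapezoid_value(tt, object$fit$params))
  ggplot2::ggplot(blk,
                  ggplot2::aes(x = .data$time, y = .data$value,
                               group = .data$block,
                               alpha = .data$retained)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 0.6, `FALSE` = 0.15),
                                guide = "none") +
    ggplot2::geom_line(data = model,
                       ggplot2::aes(group = NULL, alpha = NULL),
                       colour = "#c0392b", linewidth = 1) +
    ggplot2::labs(x = "time from block onset (s)", y = "BOLD change (%)",
                  title = "per-block responses and fitted trapezoid") +
    ggplot2::theme_minimal()
}

#' Serialise a fit report to JSON
#'
#' Writes all stage diagnostics (metrics, block retention, normalisation
#' mean, fitted parameters) as a JSON file, atomically.
#'
#' @param report A [fit_subject()] result.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fit_report <- function(report, path) {
  stopifnot(inherits(report, "fit_report"))
  payload <- list(
    metrics = as.list(report$metrics),
    params = unclass(report$fit$params),
    sse = report$fit$sse,
    n_samples = report$fit$n_samples,
    n_blocks_total = report$n_blocks_total,
    n_blocks_retained = report$n_blocks_retained,
    discarded_indices = as.integer(report$discarded_indices),
    normalization_mean = report$normalization_mean,
    roi_voxels = report$roi$n_selected,
    roi_fraction = report$roi$fraction
  )
  write_atomically(path, function(tmp) {
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
  invisible(path)
}
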