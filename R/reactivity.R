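#' Functional ROI from the top fraction of activated voxels
#'
#' Builds a binary region-of-interest mask from a Z-statistic activation map
#' by selecting the `k = ceiling(fraction * N)` in-mask voxels with the
#' highest Z, where `N` is the in-mask voxel count. The default fraction of
#' 0.2 retains the top 20% most activated voxels. Ties at the cut are broken
#' by ascending linear voxel index, so the selection is deterministic.
#'
#' @param zmap A [zstat_map()].
#' @param fraction Fraction of in-mask voxels to retain, in (0, 1].
#' @return An object of class `roi_mask`: list with `voxels` (3D logical),
#'   `fraction`, and `n_selected`.
#' @export
top_fraction_mask <- function(zmap, fraction = 0.2) {
  stopifnot(inherits(zmap, "zstat_map"),
            "fraction must be in (0, 1]" =
              is.numeric(fraction) && length(fraction) == 1 &&
              fraction > 0 && fraction <= 1)
  idx <- which(zmap$mask)
  n <- length(idx)
  k <- ceiling(fraction * n)
  z <- zmap$values[idx]
  if (length(unique(z)) == 1 && n > 1) {
    warning("all Z values are equal; ROI selected purely by voxel index",
            call. = FALSE)
  }
  # decreasing Z, ties by ascending linear index (order() is stable)
  sel <- idx[order(-z, idx)[seq_len(k)]]
  voxels <- array(FALSE, dim = dim(zmap$values))
  voxels[sel] <- TRUE
  structure(list(voxels = voxels, fraction = fraction,
                 n_selected = as.integer(k)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d voxels (top %.0f%%)\n", x$n_selected,
              100 * x$fraction))
  invisible(x)
}

#' ROI-mean BOLD timeseries
#'
#' Unweighted mean across all ROI voxels at each time point.
#'
#' @param run A [volume4d()].
#' @param roi An [top_fraction_mask()] result (or any `roi_mask`).
#' @return A [bold_series()] in raw signal units.
#' @export
roi_mean_timeseries <- function(run, roi) {
  stopifnot(inherits(run, "volume4d"), inherits(roi, "roi_mask"))
  if (!identical(dim(run$data)[1:3], dim(roi$voxels))) {
    stop("run and ROI dimensions disagree", call. = FALSE)
  }
  vox <- which(roi$voxels)
  if (!length(vox)) stop("ROI is empty", call. = FALSE)
  nt <- n_volumes(run)
  Y <- matrix(aperm(run$data, c(4, 1, 2, 3)), nrow = nt)[, vox, drop = FALSE]
  bold_series(rowMeans(Y), tr = run$tr, t0 = 0, units = "signal")
}

#' Cut a timeseries into stimulus blocks
#'
#' Reshapes a run-length series into one row per block of
#' `samples_per_block(paradigm)` consecutive samples (stimulus period plus
#' the following rest period). Trailing samples beyond the last complete
#' design block are dropped with a warning.
#'
#' @param series A [bold_series()] covering at least one block.
#' @param paradigm A [stimulus_paradigm()].
#' @return A `block_matrix`: `blocks` (n_blocks x samples-per-block matrix),
#'   `tr`, `retained` (all `TRUE`), `units`, `normalization_mean` (`NA`
#'   until [to_percent_change()]).
#' @export
segment_blocks <- function(series, paradigm) {
  stopifnot(inherits(series, "bold_series"),
            inherits(paradigm, "stimulus_paradigm"))
  spb <- samples_per_block(paradigm)
  nb <- paradigm$n_blocks
  n_need <- nb * spb
  n_have <- length(series$values)
  if (n_have < spb) {
    stop("series (", n_have, " samples) shorter than one block (", spb, ")",
         call. = FALSE)
  }
  if (n_have < n_need) {
    stop("series (", n_have, " samples) shorter than the ", nb, "-block design (",
         n_need, ")", call. = FALSE)
  }
  if (n_have > n_need) {
    warning("dropping ", n_have - n_need,
            " trailing sample(s) beyond the block design", call. = FALSE)
  }
  blocks <- matrix(series$values[seq_len(n_need)], nrow = nb, ncol = spb,
                   byrow = TRUE)
  new_block_matrix(blocks, tr = series$tr, units = series$units)
}

#' Construct a block matrix directly
#'
#' Builds a `block_matrix` from a numeric matrix with one row per block,
#' e.g. to feed [reject_artifact_blocks()] with hand-made percent-change
#' blocks in tests or calibration studies.
#'
#' @param blocks Numeric matrix, block x within-block sample.
#' @param tr Sampling interval, seconds.
#' @param units `"signal"` or `"percent"`.
#' @param retained Logical retention flags, one per block (default all).
#' @param normalization_mean The grand mean used as the percent-change
#'   denominator, if known.
#' @return A `block_matrix`.
#' @export
block_matrix <- function(blocks, tr, units = "percent",
                         retained = rep(TRUE, nrow(blocks)),
                         normalization_mean = NA_real_) {
  stopifnot(is.matrix(blocks), is.numeric(blocks), tr > 0,
            length(retained) == nrow(blocks))
  new_block_matrix(blocks, tr = tr, units = units, retained = retained,
                   normalization_mean = normalization_mean)
}

new_block_matrix <- function(blocks, tr, units,
                             retained = rep(TRUE, nrow(blocks)),
                             normalization_mean = NA_real_) {
  dimnames(blocks) <- NULL
  structure(list(blocks = blocks, tr = tr, units = units,
                 retained = retained,
                 normalization_mean = normalization_mean),
            class = "block_matrix")
}

#' @export
print.block_matrix <- function(x, ...) {
  cat(sprintf("<block_matrix> %d blocks x %d samples (%s units), %d retained\n",
              nrow(x$blocks), ncol(x$blocks), x$units, sum(x$retained)))
  if (!is.na(x$normalization_mean)) {
    cat(sprintf("  normalization mean: %.4g\n", x$normalization_mean))
  }
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.block_matrix <- function(x, ...) {
  spb <- ncol(x$blocks)
  tibble::tibble(
    block = rep(seq_len(nrow(x$blocks)), each = spb),
    time = rep((seq_len(spb) - 1) * x$tr, times = nrow(x$blocks)),
    value = as.vector(t(x$blocks)),
    retained = rep(x$retained, each = spb)
  )
}

#' Express blocks as percent BOLD change
#'
#' Every sample `x` becomes `100 * (x - m) / m`, where `m` is the grand mean
#' over all blocks. The mean is computed once, over every block, before any
#' artifact rejection, and recorded as `normalization_mean`; later rejection
#' never recomputes it.
#'
#' @param blocks A `block_matrix` in raw signal units.
#' @return A `block_matrix` in percent-change units.
#' @export
to_percent_change <- function(blocks) {
  stopifnot(inherits(blocks, "block_matrix"))
  m <- mean(blocks$blocks)
  if (!is.finite(m) || m <= 0) {
    stop("grand mean over blocks is not positive (", format(m),
         "); non-physiological input", call. = FALSE)
  }
  new_block_matrix(100 * (blocks$blocks - m) / m, tr = blocks$tr,
                   units = "percent", retained = blocks$retained,
                   normalization_mean = m)
}

#' Discard artifact blocks
#'
#' A block is discarded when its maximum absolute percent BOLD change
#' exceeds the threshold (default 3%); a block peaking exactly at the
#' threshold is retained (strict inequality). The percent-change
#' normalisation mean is not recomputed after rejection.
#'
#' @param blocks A `block_matrix` in percent-change units.
#' @param threshold Rejection threshold in percent (default 3).
#' @return The `block_matrix` with updated `retained` flags.
#' @export
reject_artifact_blocks <- function(blocks, threshold = 3) {
  stopifnot(inherits(blocks, "block_matrix"))
  if (!identical(blocks$units, "percent")) {
    stop("blocks must be in percent-change units; run to_percent_change() first",
         call. = FALSE)
  }
  peak <- apply(abs(blocks$blocks), 1, max)
  retained <- blocks$retained & (peak <= threshold)
  if (!any(retained)) {
    stop("all ", nrow(blocks$blocks),
         " blocks exceed the ", threshold, "% artifact threshold; subject unfittable",
         call. = FALSE)
  }
  new_block_matrix(blocks$blocks, tr = blocks$tr, units = blocks$units,
                   retained = retained,
                   normalization_mean = blocks$normalization_mean)
}

#' Average response over retained blocks
#'
#' Sample-wise mean over the retained blocks only.
#'
#' @param blocks A `block_matrix` with at least one retained block.
#' @return A [bold_series()] of one block length.
#' @export
average_block <- function(blocks) {
  stopifnot(inherits(blocks, "block_matrix"))
  keep <- which(blocks$retained)
  if (!length(keep)) stop("no retained blocks to average", call. = FALSE)
  bold_series(colMeans(blocks$blocks[keep, , drop = FALSE]),
              tr = blocks$tr, t0 = 0, units = blocks$units)
}
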