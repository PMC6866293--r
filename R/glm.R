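#' Canonical double-gamma haemodynamic response function
#'
#' The canonical HRF used to convolve the stimulus boxcar: a gamma density
#' peaking around 5-6 s minus a later undershoot gamma (peak ~15-16 s)
#' scaled by `1/ratio`. Normalised to unit peak.
#'
#' @param t Times in seconds (vectorised; values < 0 give 0).
#' @param peak_shape,peak_rate Shape/rate of the response gamma (defaults 6, 1).
#' @param under_shape,under_rate Shape/rate of the undershoot gamma
#'   (defaults 16, 1).
#' @param ratio Peak-to-undershoot amplitude ratio (default 6).
#' @return Numeric vector of HRF values.
#' @export
hrf_double_gamma <- function(t, peak_shape = 6, peak_rate = 1,
                             under_shape = 16, under_rate = 1, ratio = 6) {
  h <- stats::dgamma(t, shape = peak_shape, rate = peak_rate) -
    stats::dgamma(t, shape = under_shape, rate = under_rate) / ratio
  h[t < 0] <- 0
  # unit-peak normalisation on a fine grid (analytic peak of the difference
  # has no closed form)
  tt <- seq(0, 32, by = 0.01)
  hmax <- max(stats::dgamma(tt, shape = peak_shape, rate = peak_rate) -
                stats::dgamma(tt, shape = under_shape, rate = under_rate) /
                ratio)
  h / hmax
}

#' Task regressor for the block design
#'
#' Builds the subject-level GLM task regressor: a stimulus boxcar (1 during
#' stimulation, 0 during rest) convolved with the canonical double-gamma HRF
#' on a fine time grid, sampled at the acquisition times, truncated to
#' `n_volumes`, and mean-centred.
#'
#' @param paradigm A [stimulus_paradigm()].
#' @param n_volumes Number of acquired volumes; must cover at least one block.
#' @param convolve Convolve with the HRF (default TRUE). `FALSE` returns the
#'   centred raw boxcar (useful for tests).
#' @param dt Internal convolution grid step, seconds.
#' @return A [bold_series()] of length `n_volumes` in regressor units.
#' @export
build_task_regressor <- function(paradigm, n_volumes, convolve = TRUE,
                                 dt = 0.1) {
  stopifnot(inherits(paradigm, "stimulus_paradigm"))
  spb <- samples_per_block(paradigm)
  if (n_volumes < spb) {
    stop("n_volumes (", n_volumes, ") shorter than one block (", spb,
         " samples)", call. = FALSE)
  }
  total_t <- n_volumes * paradigm$tr + 32  # pad past the last acquisition
  tt <- seq(0, total_t, by = dt)
  within_block <- tt %% block_length(paradigm)
  boxcar <- as.numeric(within_block < paradigm$stim_duration &
                         tt < paradigm$n_blocks * block_length(paradigm))
  x <- if (convolve) {
    h <- hrf_double_gamma(seq(0, 32, by = dt))
    conv <- stats::convolve(boxcar, rev(h), type = "open")[seq_along(tt)] * dt
    conv
  } else {
    boxcar
  }
  idx <- round(((seq_len(n_volumes) - 1) * paradigm$tr) / dt) + 1
  sampled <- x[idx]
  bold_series(sampled - mean(sampled), tr = paradigm$tr, t0 = 0,
              units = "regressor")
}

#' Discrete-cosine high-pass basis
#'
#' Low-frequency cosine regressors spanning periods longer than `cutoff`
#' seconds, the standard GLM stand-in for high-pass temporal filtering. The
#' number of columns is `floor(2 * T / cutoff)` with `T` the run duration.
#'
#' @param n_volumes Number of time points.
#' @param tr Repetition time, seconds.
#' @param cutoff High-pass cutoff, seconds (default 48 s, the task-fMRI
#'   filtering cutoff).
#' @return A numeric matrix with `n_volumes` rows (possibly 0 columns).
#' @export
dct_highpass_basis <- function(n_volumes, tr, cutoff = 48) {
  total <- n_volumes * tr
  k_max <- floor(2 * total / cutoff)
  if (k_max < 1) {
    return(matrix(numeric(0), nrow = n_volumes, ncol = 0))
  }
  n <- seq_len(n_volumes) - 1
  basis <- vapply(seq_len(k_max), function(k) {
    cos(pi * k * (n + 0.5) / n_volumes)
  }, numeric(n_volumes))
  colnames(basis) <- paste0("dct", seq_len(k_max))
  basis
}

#' Design matrix for the subject-level GLM
#'
#' Intercept + HRF-convolved task regressor, optionally plus discrete-cosine
#' drift columns. Checked for full column rank and a non-degenerate task
#' column.
#'
#' @param paradigm A [stimulus_paradigm()].
#' @param n_volumes Number of acquired volumes.
#' @param highpass Add drift columns for the given cutoff (seconds); `NULL`
#'   (default) for none.
#' @return A `design_matrix`: numeric matrix with columns `intercept`,
#'   `task`, and optional `dct*`, with attribute `task_col`.
#' @export
build_design_matrix <- function(paradigm, n_volumes, highpass = NULL) {
  task <- build_task_regressor(paradigm, n_volumes)$values
  if (stats::var(task) <= 0) {
    stop("task regressor has zero variance", call. = FALSE)
  }
  X <- cbind(intercept = 1, task = task)
  if (!is.null(highpass)) {
    X <- cbind(X, dct_highpass_basis(n_volumes, paradigm$tr,
                                     cutoff = highpass))
  }
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  structure(X, task_col = 2L, class = c("design_matrix", class(X)))
}

#' Voxelwise GLM: Z-statistic and beta maps
#'
#' Fits ordinary least squares of each in-mask voxel timeseries on the
#' design, and converts the task-coefficient t statistic (df = n - rank) to
#' a standard normal quantile through a sign-preserving two-sided quantile
#' map, giving the Z-statistic activation map.
#'
#' Voxels with (numerically) zero residual variance cannot support a t
#' statistic: when the task beta is materially nonzero the Z value is set to
#' the documented sentinel `z_sentinel` (with a warning), and to 0 when the
#' beta is also zero (a constant voxel carries no evidence).
#'
#' @param run A [volume4d()].
#' @param design A [build_design_matrix()] result with the same number of
#'   rows as the run has volumes.
#' @param z_sentinel Finite Z magnitude assigned to perfect fits
#'   (default 40).
#' @return A list of class `glm_fit` with elements `z` ([zstat_map()]),
#'   `beta` (3D array, `NA` outside the mask), and `df`.
#' @export
fit_glm <- function(run, design, z_sentinel = 40) {
  stopifnot(inherits(run, "volume4d"), inherits(design, "design_matrix"))
  X <- unclass(design)
  nt <- n_volumes(run)
  if (nrow(X) != nt) {
    stop("design has ", nrow(X), " rows but run has ", nt, " volumes",
         call. = FALSE)
  }
  task_col <- attr(design, "task_col")
  dims <- dim(run$data)
  vox <- which(run$mask)
  # time x voxel matrix of in-mask series
  Y <- matrix(aperm(run$data, c(4, 1, 2, 3)), nrow = nt)[, vox, drop = FALSE]

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient",
                               call. = FALSE)
  beta_all <- qr.coef(qrX, Y)
  resid <- Y - X %*% beta_all
  df <- nt - qrX$rank
  sigma2 <- colSums(resid^2) / df
  xtx_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(pmax(sigma2 * xtx_inv[task_col, task_col], 0))
  beta_task <- beta_all[task_col, ]

  tol <- sqrt(.Machine$double.eps)
  scale_y <- pmax(colMeans(abs(Y)), 1)
  degenerate <- se <= tol * scale_y
  tstat <- ifelse(degenerate, 0, beta_task / ifelse(degenerate, 1, se))
  z <- t_to_z(tstat, df)
  if (any(degenerate)) {
    big_beta <- abs(beta_task) > tol * scale_y
    z[degenerate] <- ifelse(big_beta[degenerate],
                            sign(beta_task[degenerate]) * z_sentinel, 0)
    if (any(degenerate & big_beta)) {
      warning(sum(degenerate & big_beta),
              " voxel(s) with zero residual variance; Z set to sentinel ",
              z_sentinel, call. = FALSE)
    }
  }

  zmap <- array(NA_real_, dim = dims[1:3])
  bmap <- array(NA_real_, dim = dims[1:3])
  zmap[vox] <- z
  bmap[vox] <- beta_task
  structure(list(z = zstat_map(zmap, run$mask), beta = bmap, df = df),
            class = "glm_fit")
}

# sign-preserving two-sided t -> Z quantile map, stable for large |t|
t_to_z <- function(tstat, df) {
  logp <- stats::pt(abs(tstat), df = df, lower.tail = FALSE, log.p = TRUE)
  sign(tstat) * stats::qnorm(logp, lower.tail = FALSE, log.p = TRUE)
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> df = %d\n", x$df))
  print(x$z)
  invisible(x)
}
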