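#' Ground truth for one synthetic subject
#'
#' Describes the planted signal of a simulated subject run: the trapezoid
#' response (in percent of baseline), the active voxel set carrying it, the
#' noise level, the slow drift amplitude, and the scanner baseline level.
#' Defaults plant a physiologically plausible response: amplitude 1% of
#' baseline, plateau from 6 s, return to baseline at 28 s.
#'
#' @param params A [trapezoid_params()] with baseline 0 (percent of the
#'   scanner baseline level).
#' @param active_fraction Fraction of in-mask voxels made active, used when
#'   `active_voxels` is not given (default 0.2, so the planted set matches
#'   the default functional-ROI size exactly).
#' @param active_voxels Optional explicit 3D logical array of active voxels;
#'   must lie inside the brain mask.
#' @param noise_sd Gaussian noise SD in scanner units (>= 0).
#' @param drift_amplitude Amplitude of the slow cosine drift, scanner units.
#' @param baseline_level Scanner baseline signal level (> 0).
#' @param seed Integer seed making the subject reproducible.
#' @return An object of class `subject_truth`.
#' @export
subject_truth <- function(params = trapezoid_params(0, 1, 6, 28),
                          active_fraction = 0.2, active_voxels = NULL,
                          noise_sd = 5, drift_amplitude = 0,
                          baseline_level = 1000, seed = 1L) {
  stopifnot(inherits(params, "trapezoid_params"),
            "noise_sd must be >= 0" = noise_sd >= 0,
            "baseline_level must be > 0" = baseline_level > 0,
            "active_fraction must be in [0, 1]" =
              active_fraction >= 0 && active_fraction <= 1)
  structure(list(params = params, active_fraction = active_fraction,
                 active_voxels = active_voxels, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude,
                 baseline_level = baseline_level, seed = as.integer(seed)),
            class = "subject_truth")
}

#' Simulate one subject's 4D BOLD run
#'
#' Generates a block-design run on a rectangular voxel grid. Active voxels
#' carry `baseline_level * (1 + trapezoid(t mod block_length) / 100)`
#' repeated over all blocks; every voxel then receives independent Gaussian
#' noise (`noise_sd`) and a shared slow cosine drift of one period per run
#' (`drift_amplitude`). The same seed reproduces the run bit-for-bit.
#'
#' When `truth$active_voxels` is `NULL`, the first
#' `ceiling(active_fraction * N)` in-mask voxels (linear order) are made
#' active, so under the default fractions the planted set coincides with the
#' functional ROI a noiseless analysis selects.
#'
#' @param paradigm A [stimulus_paradigm()].
#' @param truth A [subject_truth()].
#' @param grid_shape 3D integer extents, each >= 4.
#' @param mask Optional 3D logical in-brain mask (default: all voxels).
#' @param n_extra_volumes Extra rest-level volumes appended after the design
#'   (default 0).
#' @return A [volume4d()].
#' @export
simulate_subject_run <- function(paradigm, truth,
                                 grid_shape = c(10, 10, 6), mask = NULL,
                                 n_extra_volumes = 0) {
  stopifnot(inherits(paradigm, "stimulus_paradigm"),
            inherits(truth, "subject_truth"),
            "grid_shape must be 3 extents >= 4" =
              length(grid_shape) == 3 && all(grid_shape >= 4))
  grid_shape <- as.integer(grid_shape)
  if (is.null(mask)) {
    mask <- array(TRUE, dim = grid_shape)
  } else if (!identical(dim(mask), grid_shape)) {
    stop("mask dimensions disagree with grid_shape", call. = FALSE)
  }
  active <- truth$active_voxels
  if (is.null(active)) {
    active <- array(FALSE, dim = grid_shape)
    n_act <- ceiling(truth$active_fraction * sum(mask))
    if (n_act > 0) active[which(mask)[seq_len(n_act)]] <- TRUE
  } else if (!identical(dim(active), grid_shape)) {
    stop("active_voxels dimensions disagree with grid_shape", call. = FALSE)
  }
  if (any(active & !mask)) {
    stop("active voxels must lie inside the brain mask", call. = FALSE)
  }

  tt <- design_time_grid(paradigm)
  nt <- length(tt) + n_extra_volumes
  t_all <- (seq_len(nt) - 1) * paradigm$tr
  resp_pct <- numeric(nt)
  resp_pct[seq_along(tt)] <-
    trapezoid_value(tt %% block_length(paradigm), truth$params)
  signal_active <- truth$baseline_level * (1 + resp_pct / 100)

  nvox <- prod(grid_shape)
  run_t <- nt * paradigm$tr
  drift <- truth$drift_amplitude * cos(2 * pi * t_all / run_t)

  data <- with_seed(truth$seed, {
    noise <- if (truth$noise_sd > 0) {
      array(stats::rnorm(nvox * nt, sd = truth$noise_sd),
            dim = c(grid_shape, nt))
    } else {
      array(0, dim = c(grid_shape, nt))
    }
    base <- array(truth$baseline_level, dim = c(grid_shape, nt))
    act_idx <- which(active)
    for (j in seq_len(nt)) {
      slice <- base[, , , j]
      slice[act_idx] <- signal_active[j]
      base[, , , j] <- slice + drift[j]
    }
    base + noise
  })
  volume4d(data, mask, paradigm$tr)
}

#' Simulate a single noisy block response
#'
#' One block-length percent-change series sampled on the design grid:
#' trapezoid plus independent Gaussian noise. Intended as a direct input for
#' [fit_trapezoid()] unit tests and calibration studies.
#'
#' @param params A [trapezoid_params()].
#' @param paradigm A [stimulus_paradigm()].
#' @param noise_sd Noise SD in percent-change units (>= 0).
#' @param seed Integer seed.
#' @return A [bold_series()] in percent-change units.
#' @export
simulate_block_response <- function(params, paradigm, noise_sd = 0,
                                    seed = 1L) {
  stopifnot(inherits(params, "trapezoid_params"),
            inherits(paradigm, "stimulus_paradigm"),
            params$t_return <= block_length(paradigm))
  tt <- block_time_grid(paradigm)
  clean <- trapezoid_value(tt, params)
  vals <- if (noise_sd > 0) {
    with_seed(as.integer(seed),
              clean + stats::rnorm(length(tt), sd = noise_sd))
  } else {
    clean
  }
  bold_series(vals, tr = paradigm$tr, t0 = 0, units = "percent")
}

#' Write a subject's ground truth as a JSON sidecar
#'
#' @param truth A [subject_truth()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_subject_truth <- function(truth, path) {
  stopifnot(inherits(truth, "subject_truth"))
  payload <- list(params = unclass(truth$params),
                  active_fraction = truth$active_fraction,
                  noise_sd = truth$noise_sd,
                  drift_amplitude = truth$drift_amplitude,
                  baseline_level = truth$baseline_level,
                  seed = truth$seed)
  write_atomically(path, function(tmp) {
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
  invisible(path)
}
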