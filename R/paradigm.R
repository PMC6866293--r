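#' Block-design stimulus paradigm
#'
#' Describes the timing of a block-design visual stimulation run: `n_blocks`
#' repeats of `stim_duration` seconds of stimulation (e.g. an 8 Hz flashing
#' checkerboard) followed by `rest_duration` seconds of rest, sampled every
#' `tr` seconds. The default paradigm is seven 20 s-on / 28 s-off blocks at
#' TR = 3 s, i.e. 16 volumes per 48 s block and 112 volumes per run.
#'
#' @param n_blocks Number of stimulation blocks (>= 1).
#' @param stim_duration Stimulus-on duration per block, seconds (> 0).
#' @param rest_duration Rest duration per block, seconds (>= 0).
#' @param tr Repetition time (sampling interval), seconds (> 0). The block
#'   length `stim_duration + rest_duration` must be an integer multiple of
#'   `tr`.
#' @param flicker_rate Checkerboard flicker frequency in Hz. Metadata only;
#'   the flicker itself is never modelled.
#' @return An object of class `stimulus_paradigm`.
#' @examples
#' p <- stimulus_paradigm()
#' block_length(p)      # 48 s
#' samples_per_block(p) # 16
#' @export
stimulus_paradigm <- function(n_blocks = 7, stim_duration = 20,
                              rest_duration = 28, tr = 3,
                              flicker_rate = 8) {
  stopifnot(
    "n_blocks must be a single count >= 1" =
      is.numeric(n_blocks) && length(n_blocks) == 1 && n_blocks >= 1 &&
      n_blocks == round(n_blocks),
    "stim_duration must be > 0" =
      is.numeric(stim_duration) && length(stim_duration) == 1 &&
      stim_duration > 0,
    "rest_duration must be >= 0" =
      is.numeric(rest_duration) && length(rest_duration) == 1 &&
      rest_duration >= 0,
    "tr must be > 0" = is.numeric(tr) && length(tr) == 1 && tr > 0
  )
  bl <- stim_duration + rest_duration
  if (abs(bl / tr - round(bl / tr)) > 1e-8) {
    stop("block length (", bl, " s) is not an integer multiple of tr (",
         tr, " s)", call. = FALSE)
  }
  structure(
    list(n_blocks = as.integer(n_blocks), stim_duration = stim_duration,
         rest_duration = rest_duration, tr = tr,
         flicker_rate = flicker_rate),
    class = "stimulus_paradigm"
  )
}

#' @export
print.stimulus_paradigm <- function(x, ...) {
  cat(sprintf(
    "<stimulus_paradigm> %d blocks x (%g s on + %g s off), TR %g s, %g Hz flicker\n",
    x$n_blocks, x$stim_duration, x$rest_duration, x$tr, x$flicker_rate))
  invisible(x)
}

#' @rdname stimulus_paradigm
#' @param paradigm A `stimulus_paradigm`.
#' @export
block_length <- function(paradigm) {
  paradigm$stim_duration + paradigm$rest_duration
}

#' @rdname stimulus_paradigm
#' @export
samples_per_block <- function(paradigm) {
  as.integer(round(block_length(paradigm) / paradigm$tr))
}

#' Sample times of the design grid
#'
#' Returns the acquisition times of all samples in a run, in seconds from run
#' onset. Sample `k` (0-based) is at `t = k * tr`: the first sample of each
#' block coincides with block onset, matching the convention that response
#' timing is measured from the beginning of the block at t = 0.
#'
#' @param paradigm A [stimulus_paradigm()].
#' @return Numeric vector of `n_blocks * samples_per_block` times.
#' @export
design_time_grid <- function(paradigm) {
  stopifnot(inherits(paradigm, "stimulus_paradigm"))
  n <- paradigm$n_blocks * samples_per_block(paradigm)
  (seq_len(n) - 1) * paradigm$tr
}

#' Times within a single block
#'
#' @param paradigm A [stimulus_paradigm()].
#' @return Numeric vector of length `samples_per_block(paradigm)` starting
#'   at 0.
#' @export
block_time_grid <- function(paradigm) {
  (seq_len(samples_per_block(paradigm)) - 1) * paradigm$tr
}

#' Gaussian kernel width conversions
#'
#' Converts the standard deviation (sigma) of an isotropic Gaussian smoothing
#' kernel to its full width at half maximum, FWHM = sigma * 2 * sqrt(2 ln 2),
#' and back. A sigma of 3 mm corresponds to a FWHM of about 7 mm.
#'
#' @param sigma,fwhm Kernel width in mm (> 0).
#' @return The converted width in mm.
#' @examples
#' sigma_to_fwhm(3)    # ~7.05
#' fwhm_to_sigma(8)    # ~3.40
#' @export
sigma_to_fwhm <- function(sigma) {
  stopifnot("sigma must be positive" = is.numeric(sigma) && all(sigma > 0))
  sigma * (2 * sqrt(2 * log(2)))
}

#' @rdname sigma_to_fwhm
#' @export
fwhm_to_sigma <- function(fwhm) {
  stopifnot("fwhm must be positive" = is.numeric(fwhm) && all(fwhm > 0))
  fwhm / (2 * sqrt(2 * log(2)))
}

# flat config mapping <-> paradigm, keys fixed by the config schema
paradigm_config_keys <- c("n_blocks", "stim_duration_s", "rest_duration_s",
                          "tr_s", "flicker_hz")

#' Serialise a paradigm to/from a flat config mapping
#'
#' The mapping uses the keys `n_blocks`, `stim_duration_s`, `rest_duration_s`,
#' `tr_s`, `flicker_hz` and round-trips through YAML or JSON.
#'
#' @param paradigm A [stimulus_paradigm()].
#' @param config A named list with the keys above.
#' @return `paradigm_to_config()` a named list; `paradigm_from_config()` a
#'   `stimulus_paradigm`.
#' @export
paradigm_to_config <- function(paradigm) {
  stopifnot(inherits(paradigm, "stimulus_paradigm"))
  list(n_blocks = paradigm$n_blocks,
       stim_duration_s = paradigm$stim_duration,
       rest_duration_s = paradigm$rest_duration,
       tr_s = paradigm$tr,
       flicker_hz = paradigm$flicker_rate)
}

#' @rdname paradigm_to_config
#' @export
paradigm_from_config <- function(config) {
  missing <- setdiff(paradigm_config_keys, names(config))
  if (length(missing)) {
    stop("paradigm config is missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stimulus_paradigm(n_blocks = config$n_blocks,
                    stim_duration = config$stim_duration_s,
                    rest_duration = config$rest_duration_s,
                    tr = config$tr_s,
                    flicker_rate = config$flicker_hz)
}
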