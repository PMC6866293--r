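# Shared fixtures and independent oracles for the suite.

default_paradigm <- function() stimulus_paradigm()

# Brute-force trapezoid evaluation written independently of the package:
# plain piecewise logic, scalar t.
oracle_trapezoid_point <- function(t, baseline, amplitude, t_peak, t_return,
                                   t_fall = 20) {
  if (t < 0 || t > t_return) return(baseline)
  if (t < t_peak) return(baseline + amplitude * t / t_peak)
  if (t <= t_fall) return(baseline + amplitude)
  baseline + amplitude * (t_return - t) / (t_return - t_fall)
}

# Exhaustive fine-grid least-squares oracle: for every (t_peak, t_return)
# pair on a regular grid, solve the 2-parameter normal equations explicitly
# and return the minimal SSE. Independent of fit_trapezoid()'s code path.
oracle_fine_grid_sse <- function(y, times, res = 0.05, t_fall = 20,
                                 t_max = 48) {
  tp <- seq(res, t_fall, by = res)
  tr_ <- seq(t_fall, t_max, by = res)
  pairs_tp <- rep(tp, times = length(tr_))
  pairs_tr <- rep(tr_, each = length(tp))
  n <- length(y)
  npair <- length(pairs_tp)
  S <- matrix(0, nrow = npair, ncol = n)
  for (j in seq_len(n)) {
    t <- times[j]
    rise <- t / pairs_tp
    fall <- ifelse(pairs_tr > t_fall,
                   (pairs_tr - t) / (pairs_tr - t_fall),
                   ifelse(t <= t_fall, Inf, -Inf))
    S[, j] <- pmax(0, pmin(rise, 1, fall))
  }
  # normal equations for y ~ b0 + a * s, per pair
  Ss <- rowSums(S)
  Sss <- rowSums(S * S)
  Sy <- sum(y)
  Syy <- sum(y * y)
  Ssy <- as.vector(S %*% y)
  det <- n * Sss - Ss^2
  a <- ifelse(det > 0, (n * Ssy - Ss * Sy) / det, 0)
  b0 <- (Sy - a * Ss) / n
  sse <- Syy + n * b0^2 + a^2 * Sss + 2 * a * b0 * Ss -
    2 * b0 * Sy - 2 * a * Ssy
  min(pmax(sse, 0))
}

# small deterministic Z map on a given grid
make_zmap <- function(values, mask = array(TRUE, dim = dim(values))) {
  zstat_map(values, mask)
}
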