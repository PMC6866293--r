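test_that("top-fraction ROI is exact and matches a sort oracle", {
  # 1000 distinct Z values: exactly the 200 largest at fraction 0.2
  set.seed(3)
  vals <- array(sample(seq(0.001, 10, length.out = 1000)),
                dim = c(10, 10, 10))
  roi <- top_fraction_mask(make_zmap(vals), fraction = 0.2)
  expect_equal(roi$n_selected, 200L)
  expect_setequal(which(roi$voxels), order(vals, decreasing = TRUE)[1:200])

  # exhaustive small-N check against a brute-force sort, N = 1..50
  for (n in 1:50) {
    dims <- c(n, 1, 1)
    z <- array(rnorm(n), dim = dims)
    roi_n <- top_fraction_mask(make_zmap(z), fraction = 0.2)
    k <- ceiling(0.2 * n)
    expect_equal(roi_n$n_selected, as.integer(k))
    expect_setequal(which(roi_n$voxels),
                    order(z, decreasing = TRUE)[seq_len(k)])
  }
})

test_that("ROI edge cases: full fraction, ties, empty mask", {
  z <- array(rnorm(27), dim = c(3, 3, 3))
  full <- top_fraction_mask(make_zmap(z), fraction = 1)
  expect_true(all(full$voxels))
  # all-equal map: pure index tie-break, with a warning
  flat <- array(1, dim = c(3, 3, 3))
  expect_warning(roi <- top_fraction_mask(make_zmap(flat), 0.2),
                 "voxel index")
  expect_equal(which(roi$voxels), 1:ceiling(0.2 * 27))
  expect_error(top_fraction_mask(make_zmap(z), fraction = 0), "fraction")
})

test_that("ROI mean timeseries equals the arithmetic mean oracle", {
  set.seed(19)
  dat <- array(rnorm(5 * 5 * 4 * 30, mean = 100), dim = c(5, 5, 4, 30))
  run <- volume4d(dat, array(TRUE, c(5, 5, 4)), tr = 3)
  vox <- sample(100, 5)
  roi <- structure(list(voxels = array(FALSE, c(5, 5, 4)), fraction = 0.05,
                        n_selected = 5L), class = "roi_mask")
  roi$voxels[vox] <- TRUE
  ts <- roi_mean_timeseries(run, roi)
  flat <- matrix(aperm(dat, c(4, 1, 2, 3)), nrow = 30)
  expect_equal(ts$values, rowMeans(flat[, vox]), tolerance = 1e-12)

  # single-voxel ROI is that voxel's series
  roi1 <- roi; roi1$voxels[] <- FALSE; roi1$voxels[2, 3, 1] <- TRUE
  expect_equal(roi_mean_timeseries(run, roi1)$values, dat[2, 3, 1, ])

  # symmetric pair averages to zero
  dat2 <- array(0, dim = c(4, 4, 4, 20))
  s <- rnorm(20)
  dat2[1, 1, 1, ] <- s; dat2[2, 1, 1, ] <- -s
  run2 <- volume4d(dat2, array(TRUE, c(4, 4, 4)), tr = 3)
  roi2 <- roi1; roi2$voxels <- array(FALSE, c(4, 4, 4))
  roi2$voxels[1:2, 1, 1] <- TRUE
  expect_equal(roi_mean_timeseries(run2, roi2)$values, rep(0, 20))
})

test_that("block segmentation reshapes, truncates, and validates", {
  p <- default_paradigm()
  s <- bold_series(seq_len(112), tr = 3)
  b <- segment_blocks(s, p)
  expect_equal(dim(b$blocks), c(7, 16))
  expect_equal(b$blocks[1, ], as.numeric(1:16))
  expect_equal(b$blocks[7, ], as.numeric(97:112))

  p1 <- stimulus_paradigm(n_blocks = 1)
  b1 <- segment_blocks(bold_series(1:16, tr = 3), p1)
  expect_equal(as.vector(b1$blocks), as.numeric(1:16))

  expect_warning(bt <- segment_blocks(bold_series(seq_len(115), tr = 3), p),
                 "3 trailing")
  expect_equal(dim(bt$blocks), c(7, 16))
  expect_error(segment_blocks(bold_series(1:10, tr = 3), p), "shorter")
})

test_that("percent change uses the grand mean over all blocks, once", {
  p <- default_paradigm()
  m <- matrix(100, 7, 16)
  pc <- to_percent_change(block_matrix(m, tr = 3, units = "signal"))
  expect_true(all(pc$blocks == 0))
  expect_equal(pc$normalization_mean, 100)

  m2 <- m; m2[3, 5] <- 102
  pc2 <- to_percent_change(block_matrix(m2, tr = 3, units = "signal"))
  gm <- mean(m2)
  expect_equal(pc2$blocks[3, 5], 100 * (102 - gm) / gm)

  set.seed(23)
  r <- matrix(rnorm(7 * 16, 1000, 20), 7, 16)
  pcr <- to_percent_change(block_matrix(r, tr = 3, units = "signal"))
  expect_equal(pcr$blocks, 100 * (r - mean(r)) / mean(r),
               ignore_attr = TRUE)

  expect_error(to_percent_change(block_matrix(-m, tr = 3,
                                              units = "signal")),
               "not positive")
})

test_that("artifact rejection applies the strict 3% max-|change| rule", {
  mk <- function(peaks) {
    b <- matrix(0, length(peaks), 16)
    b[, 8] <- peaks
    block_matrix(b, tr = 3, units = "percent")
  }
  out <- reject_artifact_blocks(mk(c(1.0, 2.9, 3.5)))
  expect_equal(out$retained, c(TRUE, TRUE, FALSE))

  # a block peaking exactly at the threshold is retained
  out2 <- reject_artifact_blocks(mk(c(3.0, -3.0, 3.0000001)))
  expect_equal(out2$retained, c(TRUE, TRUE, FALSE))

  # constructed fixture: exactly the two planted spikes are discarded
  set.seed(31)
  b <- matrix(rnorm(7 * 16, sd = 0.5), 7, 16)
  b[abs(b) > 3] <- 2.9  # clamp accidental exceedances
  b[2, 4] <- 4.2; b[6, 12] <- -3.7
  out3 <- reject_artifact_blocks(block_matrix(b, tr = 3,
                                              units = "percent"))
  expect_equal(which(!out3$retained), c(2L, 6L))
  expect_equal(sum(out3$retained), 5)

  expect_error(reject_artifact_blocks(mk(c(5, 6))), "unfittable")
  expect_error(reject_artifact_blocks(block_matrix(matrix(1000, 2, 16),
                                                   tr = 3,
                                                   units = "signal")),
               "percent-change units")
})

test_that("average block uses retained blocks only", {
  b <- matrix(rnorm(5 * 16), 5, 16)
  bm <- block_matrix(b, tr = 3, units = "percent",
                     retained = c(TRUE, FALSE, TRUE, TRUE, FALSE))
  avg <- average_block(bm)
  expect_equal(avg$values, colMeans(b[c(1, 3, 4), ]), tolerance = 1e-12)

  one <- block_matrix(b[1, , drop = FALSE], tr = 3, units = "percent")
  expect_equal(average_block(one)$values, b[1, ])

  pm <- block_matrix(rbind(b[1, ], -b[1, ]), tr = 3, units = "percent")
  expect_equal(average_block(pm)$values, rep(0, 16))

  none <- block_matrix(b, tr = 3, units = "percent",
                       retained = rep(FALSE, 5))
  expect_error(average_block(none), "no retained")
})

test_that("a discarded spike block affects the fit only through the grand mean", {
  p <- default_paradigm()
  set.seed(41)
  base <- matrix(1000 * (1 + trapezoid_value(block_time_grid(p),
                                             trapezoid_params(0, 1, 6, 28))
                         / 100),
                 nrow = 7, ncol = 16, byrow = TRUE) +
    matrix(rnorm(7 * 16, sd = 1), 7, 16)
  fit_of <- function(raw) {
    pc <- reject_artifact_blocks(
      to_percent_change(block_matrix(raw, tr = 3, units = "signal")))
    list(fit = fit_trapezoid(average_block(pc), p),
         m = pc$normalization_mean)
  }
  a <- fit_of(base)
  spiked <- rbind(base, base[1, ] + c(rep(0, 7), 80, rep(0, 8)))
  b <- fit_of(spiked)
  # the spike block is discarded, so only the normalisation mean differs;
  # re-running with the spiked grand mean imposed reproduces fit b exactly
  expect_gt(b$m, a$m)
  pc_forced <- block_matrix(100 * (base - b$m) / b$m, tr = 3,
                            units = "percent")
  forced <- fit_trapezoid(average_block(pc_forced), p)
  expect_equal(b$fit$params$t_peak, forced$params$t_peak)
  expect_equal(b$fit$params$t_return, forced$params$t_return)
  expect_equal(b$fit$amplitude, forced$amplitude, tolerance = 1e-10)
})
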