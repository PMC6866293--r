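test_that("noiseless planted voxel reproduces the trapezoid in percent change", {
  p <- default_paradigm()
  truth <- subject_truth(params = trapezoid_params(0, 1, 6, 28),
                         active_fraction = 0, noise_sd = 0, seed = 1)
  act <- array(FALSE, c(4, 4, 4)); act[1, 1, 1] <- TRUE
  truth$active_voxels <- act
  run <- simulate_subject_run(p, truth, grid_shape = c(4, 4, 4))
  vox <- bold_series(run$data[1, 1, 1, ], tr = 3)
  pc <- to_percent_change(segment_blocks(vox, p))
  # percent change against the block grand mean is an affine map of the
  # planted trapezoid; undo it and compare exactly
  planted <- trapezoid_value(block_time_grid(p), truth$params)
  m <- pc$normalization_mean
  expected <- 100 * (1000 * (1 + planted / 100) - m) / m
  for (b in 1:7) expect_equal(pc$blocks[b, ], expected, tolerance = 1e-9)
})

test_that("zero-amplitude, zero-noise runs are constant at baseline", {
  p <- default_paradigm()
  truth <- subject_truth(params = trapezoid_params(0, 0.0001, 6, 28),
                         active_fraction = 0, noise_sd = 0,
                         baseline_level = 700, seed = 1)
  run <- simulate_subject_run(p, truth, grid_shape = c(4, 4, 4))
  expect_true(all(run$data == 700))
})

test_that("subject runs are bit-identical under the same seed", {
  p <- default_paradigm()
  truth <- subject_truth(noise_sd = 4, drift_amplitude = 2, seed = 99)
  r1 <- simulate_subject_run(p, truth, grid_shape = c(5, 5, 4))
  r2 <- simulate_subject_run(p, truth, grid_shape = c(5, 5, 4))
  expect_identical(r1$data, r2$data)
  truth2 <- subject_truth(noise_sd = 4, drift_amplitude = 2, seed = 100)
  r3 <- simulate_subject_run(p, truth2, grid_shape = c(5, 5, 4))
  expect_false(identical(r1$data, r3$data))
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(1234)
  expected <- rnorm(3)
  set.seed(1234)
  invisible(simulate_block_response(trapezoid_params(), default_paradigm(),
                                    noise_sd = 1, seed = 5))
  invisible(simulate_cohort(cohort_spec(seed = 8)))
  expect_equal(rnorm(3), expected)
})

test_that("block response matches the design-grid trapezoid when noiseless", {
  p <- default_paradigm()
  pars <- trapezoid_params(0.2, 1.5, 5, 30)
  s <- simulate_block_response(pars, p, noise_sd = 0)
  expect_equal(s$values, trapezoid_value(block_time_grid(p), pars))
  flat <- simulate_block_response(trapezoid_params(0.3, 0, 5, 30), p, 0)
  expect_equal(flat$values, rep(0.3, 16))
})

test_that("block-response noise has the stated per-timepoint SD", {
  p <- default_paradigm()
  pars <- trapezoid_params(0, 1, 6, 28)
  clean <- trapezoid_value(block_time_grid(p), pars)
  draws <- sapply(1:100, function(s) {
    simulate_block_response(pars, p, noise_sd = 0.2, seed = s)$values -
      clean
  })
  sds <- apply(draws, 1, sd)
  expect_equal(mean(sds), 0.2, tolerance = 0.05)
  expect_equal(mean(draws), 0, tolerance = 0.02)
})

test_that("cohort tables are reproducible and have the declared structure", {
  spec <- cohort_spec(seed = 7)
  t1 <- simulate_cohort(spec)
  t2 <- simulate_cohort(spec)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 18 + 21 + 20)
  expect_equal(as.vector(table(t1$group)), c(18, 21, 20))
  expect_true(all(is.na(t1$cag[t1$group == "control"])))
  expect_true(all(!is.na(t1$cag[t1$group != "control"])))
  expect_true(all(t1$education >= 8))
  expect_true(all(t1[grepl("^thickness_", names(t1))] > 0))
})

test_that("null cohort model yields no between-group thickness difference", {
  eff <- default_thickness_effects()
  eff$mean <- 2.5; eff$sd <- 0.15
  spec <- cohort_spec(n_per_group = c(control = 200, premanifest = 200,
                                      manifest = 200),
                      thickness_effects = eff, cognition_slope = 0,
                      seed = 42)
  tab <- simulate_cohort(spec)
  res <- ancova_contrast(tab, "thickness_cuneus")
  se <- (res$ci_high - res$ci_low) / (2 * qt(0.975, df = res$n - 5))
  expect_true(all(abs(res$estimate) < 3 * se))
})

test_that("association regression recovers the planted thickness-per-Z slope", {
  # Compound Z-scores are standardized against the control group, so when
  # cognition is tightly coupled to thickness one compound-Z unit equals one
  # control-group SD of thickness. Planting that SD at 0.13 mm makes the
  # true association 0.13 mm per Z, which the regression must recover.
  eff <- default_thickness_effects()
  eff$sd <- 0.13
  spec <- cohort_spec(n_per_group = c(control = 200, premanifest = 400,
                                      manifest = 400),
                      thickness_effects = eff,
                      cognition_slope = 1 / 0.13,
                      cognition_residual_sd = 0.05, test_noise_sd = 0.05,
                      age_slope = 0, seed = 17)
  tab <- compound_zscore(simulate_cohort(spec))
  res <- association_regression(tab, "thickness_superior_parietal",
                                "z_visual_perception")
  # finite-sample identity: B equals the observed control-group thickness SD
  ctrl_sd <- sd(tab$thickness_superior_parietal[tab$group == "control"])
  expect_equal(res$B, ctrl_sd, tolerance = 0.03)
  expect_equal(res$B, 0.13, tolerance = 0.1)
})
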