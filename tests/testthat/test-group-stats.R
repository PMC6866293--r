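test_that("compound Z-scores are control-referenced and sign-oriented", {
  tab <- compound_zscore(simulate_cohort(cohort_spec(seed = 2)))
  ctrl <- tab[tab$group == "control", ]
  # control mean 0 by construction of reference standardization
  expect_equal(mean(ctrl$z_visual_perception), 0, tolerance = 1e-10)
  expect_equal(mean(ctrl$z_visual_scanning), 0, tolerance = 1e-10)

  # timed test orientation: slowing (raising) carriers' tmt_a raw scores
  # must lower their compound Z while leaving the reference unchanged
  tab2 <- tab
  carriers <- tab2$group != "control"
  tab2$score_tmt_a[carriers] <- tab2$score_tmt_a[carriers] + 10
  z2 <- compound_zscore(tab2)
  expect_true(all(z2$z_visual_scanning[carriers] <
                    tab$z_visual_scanning[carriers]))
  expect_equal(z2$z_visual_scanning[!carriers],
               tab$z_visual_scanning[!carriers])

  # single-test domain equals that test's Z
  solo <- default_test_battery()[1, ]
  z3 <- compound_zscore(tab, battery = solo)
  m <- mean(tab$score_vosp[tab$group == "control"])
  s <- sd(tab$score_vosp[tab$group == "control"])
  expect_equal(z3$z_visual_perception, (tab$score_vosp - m) / s,
               tolerance = 1e-12)

  # degenerate test: zero variance in the reference group
  tab3 <- tab
  tab3$score_vosp[tab3$group == "control"] <- 19
  expect_error(compound_zscore(tab3), "zero variance")
})

test_that("a planted -1 SD manifest deficit appears as domain Z near -1", {
  spec <- cohort_spec(n_per_group = c(control = 1000, premanifest = 1000,
                                      manifest = 1000),
                      cognition_slope = 0, age_slope = 0,
                      cognition_residual_sd = 1, test_noise_sd = 0,
                      group_shifts = c(control = 0, premanifest = 0,
                                       manifest = -1),
                      seed = 12)
  tab <- compound_zscore(simulate_cohort(spec))
  man <- tab[tab$group == "manifest", ]
  expect_equal(mean(man$z_visual_perception), -1, tolerance = 0.1)
  expect_equal(mean(man$z_visual_scanning), -1, tolerance = 0.1)
})

test_that("ANCOVA contrast machinery is correct on identical groups", {
  spec <- cohort_spec(n_per_group = c(control = 200, premanifest = 200,
                                      manifest = 200),
                      age_mean = c(control = 45, premanifest = 45,
                                   manifest = 45),
                      thickness_effects = within(default_thickness_effects(),
                                                 {mean <- 2.2; sd <- 0.15}),
                      cognition_slope = 0, seed = 31)
  tab <- simulate_cohort(spec)
  res <- ancova_contrast(tab, "thickness_lingual")
  se <- (res$ci_high - res$ci_low) / (2 * qt(0.975, res$n - 5))
  expect_true(all(abs(res$estimate) < 3 * se))
})

test_that("without covariates the contrast is exactly the group mean difference", {
  tab <- simulate_cohort(cohort_spec(seed = 3))
  res <- ancova_contrast(tab, "thickness_cuneus", covariates = character(0))
  mns <- tapply(tab$thickness_cuneus, tab$group, mean)
  expect_equal(res$estimate[res$group == "premanifest"],
               unname(mns["premanifest"] - mns["control"]),
               tolerance = 1e-8)
  expect_equal(res$estimate[res$group == "manifest"],
               unname(mns["manifest"] - mns["control"]), tolerance = 1e-8)
})

test_that("contrast estimates are invariant to affine covariate rescaling", {
  tab <- simulate_cohort(cohort_spec(seed = 14))
  r1 <- ancova_contrast(tab, "thickness_fusiform")
  tab2 <- tab
  tab2$age <- (tab2$age - 50) / 10
  tab2$education <- tab2$education * 3 + 2
  r2 <- ancova_contrast(tab2, "thickness_fusiform")
  expect_equal(r2$estimate, r1$estimate, tolerance = 1e-10)
  expect_equal(r2$p, r1$p, tolerance = 1e-10)
})

test_that("collinear covariates raise a rank-deficiency error", {
  tab <- simulate_cohort(cohort_spec(seed = 4))
  tab$age2 <- tab$age * 2
  expect_error(ancova_contrast(tab, "thickness_cuneus",
                               covariates = c("age", "age2")),
               "rank deficient")
  expect_error(association_regression(compound_zscore(tab),
                                      "thickness_cuneus",
                                      "z_visual_perception",
                                      covariates = c("z_visual_perception",
                                                     "age")),
               "duplicated")
})

test_that("partial eta squared matches the Type-III oracle and stays in [0,1]", {
  tab <- compound_zscore(simulate_cohort(cohort_spec(seed = 21)))
  for (oc in c("thickness_cuneus", "thickness_superior_parietal")) {
    res <- association_regression(tab, oc, "z_visual_perception")
    expect_gte(res$partial_eta_sq, 0)
    expect_lte(res$partial_eta_sq, 1)
    carriers <- tab[tab$group != "control", ]
    fit <- lm(stats::reformulate(c("z_visual_perception", "age", "gender",
                                   "education", "cag"), response = oc),
              data = carriers)
    a3 <- car::Anova(fit, type = "III")
    ss_p <- a3["z_visual_perception", "Sum Sq"]
    ss_r <- a3["Residuals", "Sum Sq"]
    expect_equal(res$partial_eta_sq, ss_p / (ss_p + ss_r),
                 tolerance = 1e-10)
    # identity with the squared partial correlation (t-statistic form)
    tval <- summary(fit)$coefficients["z_visual_perception", "t value"]
    expect_equal(res$partial_eta_sq,
                 tval^2 / (tval^2 + fit$df.residual), tolerance = 1e-10)
  }
})

test_that("an independent predictor has partial eta squared near zero", {
  spec <- cohort_spec(n_per_group = c(control = 300, premanifest = 300,
                                      manifest = 300),
                      cognition_slope = 0, age_slope = 0, seed = 25)
  tab <- compound_zscore(simulate_cohort(spec))
  res <- association_regression(tab, "thickness_lingual",
                                "z_visual_perception")
  expect_lt(res$partial_eta_sq, 0.02)
})

test_that("confidence intervals cover planted effects at the nominal rate", {
  # 300 small cohorts here (the acceptance suite runs the full 2,000)
  n_rep <- 300
  eff <- default_thickness_effects()
  eff <- eff[eff$region == "superior_parietal", ]
  truth <- eff$mean[eff$group == "manifest"] -
    eff$mean[eff$group == "control"]
  cover <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    spec <- cohort_spec(n_per_group = c(control = 20, premanifest = 20,
                                        manifest = 20),
                        thickness_effects = eff, cognition_slope = 0,
                        seed = 5000 + r)
    tab <- simulate_cohort(spec)
    res <- ancova_contrast(tab, "thickness_superior_parietal")
    man <- res[res$group == "manifest", ]
    cover[r] <- man$ci_low <= truth && truth <= man$ci_high
  }
  expect_equal(mean(cover), 0.95, tolerance = 0.045)
})

test_that("bonferroni alpha is alpha over m", {
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 2), 0.025)
  expect_equal(bonferroni_alpha(0.05, 12), 0.05 / 12)
  expect_equal(round(bonferroni_alpha(0.05, 12), 3), 0.004)
  expect_error(bonferroni_alpha(0.05, 0), "m must be")
})
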