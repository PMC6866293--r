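#' Default per-region cortical thickness distributions
#'
#' Mean and SD of cortical thickness (mm) per visual region and group used
#' by the cohort generator: eight visually responsive regions (four
#' occipital, one parietal, three temporal), with controls thickest and the
#' manifest group showing thinning in most regions.
#'
#' @return A tibble with columns `region`, `group`, `mean`, `sd`.
#' @export
default_thickness_effects <- function() {
  regions <- c("cuneus", "fusiform", "inferior_temporal",
               "lateral_occipital", "lingual", "pericalcarine",
               "superior_parietal", "temporal_pole")
  means <- rbind(
    c(1.95, 1.93, 1.82),
    c(2.71, 2.72, 2.55),
    c(2.70, 2.73, 2.58),
    c(2.11, 2.17, 1.99),
    c(2.10, 2.08, 1.96),
    c(1.74, 1.71, 1.67),
    c(2.21, 2.19, 2.02),
    c(3.60, 3.77, 3.59))
  sds <- rbind(
    c(0.14, 0.13, 0.15),
    c(0.16, 0.11, 0.21),
    c(0.13, 0.13, 0.18),
    c(0.13, 0.11, 0.22),
    c(0.16, 0.09, 0.18),
    c(0.16, 0.13, 0.16),
    c(0.16, 0.10, 0.19),
    c(0.36, 0.21, 0.40))
  groups <- c("control", "premanifest", "manifest")
  tibble::tibble(
    region = rep(regions, each = 3),
    group = rep(groups, times = length(regions)),
    mean = as.vector(t(means)),
    sd = as.vector(t(sds))
  )
}

#' Default cognitive test battery
#'
#' The visual cognitive tests the generator simulates and the compound
#' scorer aggregates: a visual-perception domain (object/space perception
#' subtests) and a visual-scanning-and-attention domain (symbol-digit,
#' word-reading, trail-making). `direction` is +1 when a higher raw score is
#' better and -1 for timed tests where higher means worse.
#'
#' @return A tibble with columns `test`, `domain`, `direction`, `mean`, `sd`
#'   (control-population raw-score mean and SD).
#' @export
default_test_battery <- function() {
  tibble::tribble(
    ~test,             ~domain,             ~direction, ~mean, ~sd,
    "vosp",            "visual_perception",          1,    19,  1.5,
    "git_perception",  "visual_perception",          1,    25,  4,
    "sdmt",            "visual_scanning",            1,    50,  10,
    "stroop_reading",  "visual_scanning",            1,    95,  15,
    "tmt_a",           "visual_scanning",           -1,    30,  10
  )
}

#' Cohort simulation specification
#'
#' Parameters of the synthetic cohort: three groups (healthy controls,
#' premanifest and manifest gene carriers), per-region thickness
#' distributions, a cognition model linking thickness to latent domain
#' ability, and covariate distributions (age, gender, education, CAG repeat
#' length for gene carriers). Defaults emulate the structure of a
#' characteristic HD imaging cohort: group sizes 18/21/20; ages ~46/37/52 y;
#' education ~17 y truncated at 8; CAG ~42/43 repeats.
#'
#' The cognition model generates, per domain, a latent ability
#' `group_shift + slope * (thickness_ref - control mean) + age_slope * (age
#' - 45) + N(0, residual_sd)` where `thickness_ref` is the subject's
#' thickness in `reference_region`; each test's raw score is then
#' `mean + direction * sd * (latent + N(0, test_noise_sd))`. With the
#' default slope of 1/0.13 Z per mm, regressing thickness on domain score
#' recovers ~0.13 mm per Z when residuals are small.
#'
#' @param n_per_group Named counts for control/premanifest/manifest (each
#'   >= 2).
#' @param thickness_effects Tibble as [default_thickness_effects()].
#' @param test_battery Tibble as [default_test_battery()].
#' @param cognition_slope Latent-ability change per mm of reference-region
#'   thickness (Z per mm).
#' @param cognition_residual_sd Residual SD of the latent ability.
#' @param test_noise_sd Per-test noise SD (latent units).
#' @param group_shifts Named per-group additive shifts of latent ability.
#' @param age_slope Latent-ability change per year of age.
#' @param reference_region Region driving the cognition model.
#' @param thickness_cor Correlation of a subject's thickness deviations
#'   across regions (shared-factor loading), in [0, 1).
#' @param age_mean,age_sd Named per-group age distributions (years).
#' @param male_prop Named per-group probability of male gender.
#' @param education_mean,education_sd Education (years), truncated at >= 8.
#' @param cag_mean,cag_sd Named CAG distributions for the two gene-carrier
#'   groups.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(control = 18, premanifest = 21,
                                        manifest = 20),
                        thickness_effects = default_thickness_effects(),
                        test_battery = default_test_battery(),
                        cognition_slope = 1 / 0.13,
                        cognition_residual_sd = 1,
                        test_noise_sd = 0.5,
                        group_shifts = c(control = 0, premanifest = 0,
                                         manifest = 0),
                        age_slope = -0.02,
                        reference_region = "superior_parietal",
                        thickness_cor = 0.5,
                        age_mean = c(control = 46.2, premanifest = 37.4,
                                     manifest = 52.1),
                        age_sd = c(control = 10.7, premanifest = 9.0,
                                   manifest = 10.8),
                        male_prop = c(control = 7 / 18,
                                      premanifest = 11 / 21,
                                      manifest = 11 / 20),
                        education_mean = c(control = 17.0,
                                           premanifest = 16.8,
                                           manifest = 16.4),
                        education_sd = c(control = 2.2, premanifest = 3.2,
                                         manifest = 2.3),
                        cag_mean = c(premanifest = 41.8, manifest = 42.8),
                        cag_sd = c(premanifest = 2.2, manifest = 2.4),
                        seed = 1L) {
  groups <- c("control", "premanifest", "manifest")
  stopifnot(
    "n_per_group must name control, premanifest, manifest" =
      all(groups %in% names(n_per_group)),
    "each group needs at least 2 subjects" = all(n_per_group[groups] >= 2),
    "all SDs must be >= 0" =
      all(thickness_effects$sd >= 0) && all(age_sd >= 0) &&
      all(education_sd >= 0) && all(cag_sd >= 0) &&
      cognition_residual_sd >= 0 && test_noise_sd >= 0,
    "thickness_cor must be in [0, 1)" =
      thickness_cor >= 0 && thickness_cor < 1,
    "reference_region must appear in thickness_effects" =
      reference_region %in% thickness_effects$region,
    "CAG parameters are defined for gene-carrier groups only" =
      setequal(names(cag_mean), c("premanifest", "manifest"))
  )
  structure(
    list(n_per_group = n_per_group[groups],
         thickness_effects = thickness_effects,
         test_battery = test_battery,
         cognition_slope = cognition_slope,
         cognition_residual_sd = cognition_residual_sd,
         test_noise_sd = test_noise_sd,
         group_shifts = group_shifts,
         age_slope = age_slope,
         reference_region = reference_region,
         thickness_cor = thickness_cor,
         age_mean = age_mean, age_sd = age_sd, male_prop = male_prop,
         education_mean = education_mean, education_sd = education_sd,
         cag_mean = cag_mean, cag_sd = cag_sd,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> n = %s; %d regions, %d tests; seed %d\n",
    paste(sprintf("%s %d", names(x$n_per_group), x$n_per_group),
          collapse = ", "),
    length(unique(x$thickness_effects$region)),
    nrow(x$test_battery), x$seed))
  invisible(x)
}

#' Simulate a cohort table
#'
#' One row per subject: group, covariates (age, gender, education, CAG for
#' gene carriers), per-region cortical thickness drawn from the group's
#' distribution with a shared subject-level thickness factor, and raw
#' cognitive test scores generated from the cognition model described in
#' [cohort_spec()]. Fully reproducible from (spec, seed).
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `id`, `group`, `age`, `gender`,
#'   `education`, `cag`, `thickness_<region>` ..., `score_<test>` ....
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- names(spec$n_per_group)
  regions <- unique(spec$thickness_effects$region)
  tests <- spec$test_battery
  domains <- unique(tests$domain)

  with_seed(spec$seed, {
    rows <- lapply(groups, function(g) {
      n <- spec$n_per_group[[g]]
      age <- stats::rnorm(n, spec$age_mean[[g]], spec$age_sd[[g]])
      gender <- ifelse(stats::runif(n) < spec$male_prop[[g]], "male",
                       "female")
      education <- pmax(8, stats::rnorm(n, spec$education_mean[[g]],
                                        spec$education_sd[[g]]))
      cag <- if (g %in% names(spec$cag_mean)) {
        pmax(36, round(stats::rnorm(n, spec$cag_mean[[g]],
                                    spec$cag_sd[[g]])))
      } else {
        rep(NA_real_, n)
      }
      # shared subject factor correlates thickness deviations across regions
      u <- stats::rnorm(n)
      lam <- sqrt(spec$thickness_cor)
      th <- sapply(regions, function(r) {
        eff <- spec$thickness_effects[
          spec$thickness_effects$region == r &
            spec$thickness_effects$group == g, ]
        eff$mean + eff$sd * (lam * u +
                               sqrt(1 - spec$thickness_cor) *
                               stats::rnorm(n))
      })
      th <- matrix(th, nrow = n,
                   dimnames = list(NULL, paste0("thickness_", regions)))

      ref_mean <- spec$thickness_effects$mean[
        spec$thickness_effects$region == spec$reference_region &
          spec$thickness_effects$group == "control"]
      th_ref <- th[, paste0("thickness_", spec$reference_region)]
      base_latent <- spec$group_shifts[[g]] +
        spec$cognition_slope * (th_ref - ref_mean) +
        spec$age_slope * (age - 45)

      scores <- matrix(NA_real_, nrow = n, ncol = nrow(tests),
                       dimnames = list(NULL, paste0("score_", tests$test)))
      for (d in domains) {
        latent_d <- base_latent +
          stats::rnorm(n, sd = spec$cognition_residual_sd)
        for (j in which(tests$domain == d)) {
          obs <- latent_d + stats::rnorm(n, sd = spec$test_noise_sd)
          scores[, j] <- tests$mean[j] + tests$direction[j] * tests$sd[j] *
            obs
        }
      }

      dplyr::bind_cols(
        tibble::tibble(group = g, age = age, gender = gender,
                       education = education, cag = cag),
        tibble::as_tibble(th), tibble::as_tibble(scores))
    })
    out <- dplyr::bind_rows(rows)
    out$group <- factor(out$group, levels = groups)
    out$gender <- factor(out$gender, levels = c("female", "male"))
    dplyr::bind_cols(tibble::tibble(id = sprintf("S%03d", seq_len(nrow(out)))),
                     out)
  })
}

#' Write / read a cohort table as CSV
#'
#' UTF-8, comma-separated, with a mandatory header row. `read_cohort_csv()`
#' restores the `group` and `gender` factor codings.
#'
#' @param table A cohort tibble from [simulate_cohort()].
#' @param path File path.
#' @return The path (writer, invisibly) or the tibble (reader).
#' @export
write_cohort_csv <- function(table, path) {
  write_atomically(path, function(tmp) {
    utils::write.csv(table, tmp, row.names = FALSE, fileEncoding = "UTF-8")
  })
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, fileEncoding = "UTF-8"))
  if ("group" %in% names(out)) {
    out$group <- factor(out$group,
                        levels = c("control", "premanifest", "manifest"))
  }
  if ("gender" %in% names(out)) {
    out$gender <- factor(out$gender, levels = c("female", "male"))
  }
  out
}
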