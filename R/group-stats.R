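#' Compound cognitive domain Z-scores
#'
#' Converts raw cognitive test scores to standardized Z-scores against a
#' reference group (default: controls) and averages them into per-domain
#' compound scores. Timed tests (where a higher raw score means worse
#' performance) are sign-flipped before averaging, so a higher compound Z
#' always means better function in every domain.
#'
#' Per test, `Z = direction * (x - mean_ref) / sd_ref` with `mean_ref` and
#' `sd_ref` taken from the reference group; the domain score is the mean of
#' its tests' Z-scores ("summed and averaged").
#'
#' @param table A cohort tibble with `group` and `score_<test>` columns.
#' @param battery Test battery tibble with columns `test`, `domain`,
#'   `direction` (see [default_test_battery()]).
#' @param reference Reference group for standardization (default
#'   `"control"`); `"all"` standardizes against the whole sample.
#' @return The input tibble with one added `z_<domain>` column per domain.
#' @export
compound_zscore <- function(table, battery = default_test_battery(),
                            reference = "control") {
  stopifnot(is.data.frame(table), "group" %in% names(table))
  cols <- paste0("score_", battery$test)
  missing <- setdiff(cols, names(table))
  if (length(missing)) {
    stop("cohort table is missing test columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ref_rows <- if (identical(reference, "all")) {
    rep(TRUE, nrow(table))
  } else {
    table$group == reference
  }
  if (!any(ref_rows)) {
    stop("reference group '", reference, "' is empty", call. = FALSE)
  }
  z <- matrix(NA_real_, nrow = nrow(table), ncol = nrow(battery))
  for (j in seq_len(nrow(battery))) {
    x <- table[[cols[j]]]
    m <- mean(x[ref_rows])
    s <- stats::sd(x[ref_rows])
    if (!is.finite(s) || s <= 0) {
      stop("test '", battery$test[j],
           "' has zero variance in the reference group", call. = FALSE)
    }
    z[, j] <- battery$direction[j] * (x - m) / s
  }
  out <- table
  for (d in unique(battery$domain)) {
    out[[paste0("z_", d)]] <-
      rowMeans(z[, battery$domain == d, drop = FALSE])
  }
  tibble::as_tibble(out)
}

#' Covariate-adjusted group contrasts (ANCOVA, simple contrasts)
#'
#' Least-squares fit of `outcome ~ group + covariates` with the reference
#' group (controls) as baseline. Each non-reference group's coefficient is
#' its adjusted difference from the reference; 95% confidence intervals and
#' two-sided p values come from the t distribution of the fit.
#'
#' @param table Cohort tibble.
#' @param outcome Name of the outcome column (string).
#' @param covariates Character vector of covariate columns (default age,
#'   gender, education).
#' @param reference Reference group label (default `"control"`).
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with one row per non-reference group: `group`,
#'   `estimate`, `ci_low`, `ci_high`, `p`, `reference`, `n`.
#' @export
ancova_contrast <- function(table, outcome,
                            covariates = c("age", "gender", "education"),
                            reference = "control", conf_level = 0.95) {
  stopifnot(is.data.frame(table), outcome %in% names(table),
            all(covariates %in% names(table)),
            "group" %in% names(table))
  dat <- droplevels(as.data.frame(
    table[stats::complete.cases(table[c(outcome, "group", covariates)]),
          c(outcome, "group", covariates)]))
  dat$group <- stats::relevel(factor(dat$group), ref = reference)
  if (nlevels(dat$group) < 2) {
    stop("need at least two non-empty groups", call. = FALSE)
  }
  fml <- stats::reformulate(c("group", covariates), response = outcome)
  mm <- stats::model.matrix(fml, data = dat)
  if (qr(mm)$rank < ncol(mm)) {
    stop("model matrix is rank deficient (collinear covariates?)",
         call. = FALSE)
  }
  fit <- stats::lm(fml, data = dat)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = conf_level)
  terms <- paste0("group", setdiff(levels(dat$group), reference))
  tibble::tibble(
    group = sub("^group", "", terms),
    estimate = unname(sm[terms, "Estimate"]),
    ci_low = unname(ci[terms, 1]),
    ci_high = unname(ci[terms, 2]),
    p = unname(sm[terms, "Pr(>|t|)"]),
    reference = reference,
    n = nrow(dat)
  )
}

#' Thickness-cognition association in gene carriers
#'
#' Multiple linear regression of a neuroimaging outcome (e.g. regional
#' cortical thickness) on a cognitive domain Z-score in gene carriers only,
#' adjusted for covariates entered in one block (default: age, gender,
#' education, CAG repeat length). Reports the unstandardized coefficient B
#' of the predictor, its SE, the two-sided p value, and partial eta squared
#' computed from the drop-one (Type-III) sum of squares:
#' `SS_predictor / (SS_predictor + SS_residual)`.
#'
#' @param table Cohort tibble; rows with `group == "control"` are excluded
#'   automatically.
#' @param outcome Outcome column name (string).
#' @param predictor Predictor column name (string), e.g. a `z_<domain>`
#'   column from [compound_zscore()].
#' @param covariates Covariate column names.
#' @param groups Gene-carrier groups to include (default premanifest and
#'   manifest).
#' @param conf_level Confidence level for the B interval (default 0.95).
#' @return A one-row tibble: `outcome`, `predictor`, `B`, `SE`, `ci_low`,
#'   `ci_high`, `partial_eta_sq`, `p`, `n`.
#' @export
association_regression <- function(table, outcome, predictor,
                                   covariates = c("age", "gender",
                                                  "education", "cag"),
                                   groups = c("premanifest", "manifest"),
                                   conf_level = 0.95) {
  stopifnot(is.data.frame(table), outcome %in% names(table),
            predictor %in% names(table))
  if (predictor %in% covariates) {
    stop("predictor '", predictor, "' duplicated among the covariates",
         call. = FALSE)
  }
  missing <- setdiff(covariates, names(table))
  if (length(missing)) {
    stop("missing covariate columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dat <- as.data.frame(table[table$group %in% groups, , drop = FALSE])
  keep <- stats::complete.cases(dat[c(outcome, predictor, covariates)])
  dat <- droplevels(dat[keep, , drop = FALSE])
  fml <- stats::reformulate(c(predictor, covariates), response = outcome)
  mm <- stats::model.matrix(fml, data = dat)
  if (qr(mm)$rank < ncol(mm)) {
    stop("model matrix is rank deficient (collinear terms?)", call. = FALSE)
  }
  fit <- stats::lm(fml, data = dat)
  sm <- summary(fit)$coefficients
  ss_res <- sum(stats::residuals(fit)^2)
  # drop-one SS for the (1 df) predictor
  fml0 <- stats::reformulate(covariates, response = outcome)
  fit0 <- stats::lm(fml0, data = dat)
  ss_pred <- sum(stats::residuals(fit0)^2) - ss_res
  ci <- stats::confint(fit, predictor, level = conf_level)
  tibble::tibble(
    outcome = outcome,
    predictor = predictor,
    B = sm[predictor, "Estimate"],
    SE = sm[predictor, "Std. Error"],
    ci_low = ci[1],
    ci_high = ci[2],
    partial_eta_sq = ss_pred / (ss_pred + ss_res),
    p = sm[predictor, "Pr(>|t|)"],
    n = nrow(dat)
  )
}

#' Bonferroni-adjusted alpha
#'
#' Familywise significance threshold `alpha / m` for `m` comparisons.
#'
#' @param alpha Nominal alpha (default 0.05).
#' @param m Number of comparisons in the family (>= 1).
#' @return The adjusted alpha.
#' @examples
#' bonferroni_alpha(0.05, 12)  # 0.00417, printed thresholds round to .004
#' @export
bonferroni_alpha <- function(alpha = 0.05, m) {
  stopifnot("alpha must be in (0, 1]" = alpha > 0 && alpha <= 1,
            "m must be a count >= 1" = is.numeric(m) && length(m) == 1 &&
              m >= 1 && m == round(m))
  alpha / m
}
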