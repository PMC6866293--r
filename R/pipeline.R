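#' Pipeline configuration
#'
#' A nested configuration driving the full synthetic pipeline: paradigm
#' timing, per-subject synthesis, GLM options, reactivity-stage parameters,
#' and group-statistics choices. Serialises to/from YAML. A seed is
#' mandatory: every stochastic stage derives its own stream from it.
#'
#' `make_demo_config()` returns a small complete configuration (3 subjects
#' per group on a 10 x 10 x 6 grid) suitable for a quick end-to-end run.
#'
#' @param out_dir Output directory for [run_pipeline()].
#' @param seed Integer seed.
#' @return A named list of class `pipeline_config`.
#' @export
make_demo_config <- function(out_dir = tempfile("vasoreact_demo_"),
                             seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    paradigm = paradigm_to_config(stimulus_paradigm()),
    subjects = list(
      n_per_group = list(control = 3, premanifest = 3, manifest = 3),
      grid_shape = c(10, 10, 6),
      amplitude_pct = list(control = 1.0, premanifest = 1.0,
                           manifest = 1.0),
      t_peak_s = 6, t_return_s = 28,
      active_fraction = 0.2, noise_sd = 5, drift_amplitude = 0,
      baseline_level = 1000
    ),
    glm = list(highpass_s = NULL),
    reactivity = list(fraction = 0.2, threshold_pct = 3,
                      grid_resolution_s = 0.25, refine = TRUE),
    stats = list(
      covariates_contrast = c("age", "gender", "education"),
      covariates_association = c("age", "gender", "education", "cag"),
      reference_group = "control",
      n_comparisons = 12
    )
  ), class = "pipeline_config")
}

#' @rdname make_demo_config
#' @param path YAML file path.
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  write_atomically(path, function(tmp) {
    yaml::write_yaml(unclass(config), tmp)
  })
  invisible(path)
}

#' @rdname make_demo_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(structure(cfg, class = "pipeline_config"))
}

validate_pipeline_config <- function(config) {
  if (is.null(config$seed) || is.na(suppressWarnings(as.integer(config$seed)))) {
    stop("pipeline config requires an integer seed for stochastic synthesis",
         call. = FALSE)
  }
  config$seed <- as.integer(config$seed)
  if (is.null(config$paradigm)) {
    stop("pipeline config requires a paradigm block", call. = FALSE)
  }
  paradigm_from_config(config$paradigm)  # validates timing
  config
}

#' Run the full synthetic pipeline
#'
#' Executes simulate, subject-level GLM + reactivity fitting, and group
#' statistics as configured: simulates one BOLD run per subject with a
#' planted trapezoid, fits the vascular reactivity report for each, merges
#' the per-subject metrics with a simulated cohort table, computes compound
#' cognitive Z-scores, ANCOVA group contrasts on thickness, reactivity and
#' cognition outcomes, and thickness-cognition association regressions.
#'
#' All outputs are written atomically under `config$out_dir`; a manifest
#' (JSON) records the configuration, seed, package version, per-stage
#' outputs and warnings. Identical config + seed reproduce identical
#' numeric outputs.
#'
#' @param config A [make_demo_config()]-shaped `pipeline_config`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paradigm <- paradigm_from_config(config$paradigm)
  sub_cfg <- config$subjects
  warnings_log <- character()
  note <- function(...) {
    warnings_log <<- c(warnings_log, sprintf(...))
  }

  groups <- names(sub_cfg$n_per_group)
  subject_seeds <- with_seed(config$seed, {
    n_total <- sum(unlist(sub_cfg$n_per_group))
    sample.int(.Machine$integer.max - 1, n_total)
  })

  reports <- list()
  metrics <- list()
  k <- 0
  for (g in groups) {
    for (i in seq_len(sub_cfg$n_per_group[[g]])) {
      k <- k + 1
      sid <- sprintf("%s%02d", g, i)
      truth <- subject_truth(
        params = trapezoid_params(0, sub_cfg$amplitude_pct[[g]],
                                  sub_cfg$t_peak_s, sub_cfg$t_return_s),
        active_fraction = sub_cfg$active_fraction,
        noise_sd = sub_cfg$noise_sd,
        drift_amplitude = sub_cfg$drift_amplitude,
        baseline_level = sub_cfg$baseline_level,
        seed = subject_seeds[k])
      run <- simulate_subject_run(paradigm, truth,
                                  grid_shape = unlist(sub_cfg$grid_shape))
      rep_k <- withCallingHandlers(
        tryCatch(
          fit_subject(run, paradigm,
                      fraction = config$reactivity$fraction,
                      threshold = config$reactivity$threshold_pct,
                      grid_resolution = config$reactivity$grid_resolution_s,
                      refine = isTRUE(config$reactivity$refine),
                      highpass = config$glm$highpass_s),
          error = function(e) {
            stop("reactivity stage failed for subject ", sid, ": ",
                 conditionMessage(e), call. = FALSE)
          }),
        warning = function(w) {
          note("subject %s: %s", sid, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      if (length(rep_k$discarded_indices)) {
        note("subject %s: discarded block(s) %s", sid,
             paste(rep_k$discarded_indices, collapse = ", "))
      }
      write_fit_report(rep_k, file.path(out_dir,
                                        paste0("report_", sid, ".json")))
      reports[[sid]] <- rep_k
      metrics[[sid]] <- dplyr::bind_cols(
        tibble::tibble(subject = sid, group = g), tidy(rep_k))
    }
  }
  metrics_tbl <- dplyr::bind_rows(metrics)
  write_cohort_csv(metrics_tbl, file.path(out_dir, "reactivity_metrics.csv"))

  # cohort statistics
  cohort <- simulate_cohort(cohort_spec(seed = config$seed))
  cohort <- compound_zscore(cohort,
                            reference = config$stats$reference_group)
  write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))

  regions <- unique(default_thickness_effects()$region)
  contrasts <- dplyr::bind_rows(lapply(
    c(paste0("thickness_", regions),
      paste0("z_", unique(default_test_battery()$domain))),
    function(oc) {
      dplyr::bind_cols(tibble::tibble(outcome = oc),
                       ancova_contrast(cohort, oc,
                                       covariates =
                                         config$stats$covariates_contrast,
                                       reference =
                                         config$stats$reference_group))
    }))
  write_cohort_csv(contrasts, file.path(out_dir, "group_contrasts.csv"))

  associations <- dplyr::bind_rows(lapply(
    paste0("thickness_", regions), function(oc) {
      dplyr::bind_rows(lapply(
        paste0("z_", unique(default_test_battery()$domain)),
        function(pr) {
          association_regression(cohort, oc, pr,
                                 covariates =
                                   config$stats$covariates_association)
        }))
    }))
  associations$alpha_adjusted <-
    bonferroni_alpha(0.05, config$stats$n_comparisons)
  write_cohort_csv(associations, file.path(out_dir, "associations.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("vasoreact")),
    seed = config$seed,
    config = unclass(config),
    outputs = list(
      reports = paste0("report_", names(reports), ".json"),
      reactivity_metrics = "reactivity_metrics.csv",
      cohort = "cohort.csv",
      group_contrasts = "group_contrasts.csv",
      associations = "associations.csv"
    ),
    n_subjects = length(reports),
    warnings = warnings_log
  )
  write_atomically(file.path(out_dir, "manifest.json"), function(tmp) {
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
  invisible(manifest)
}
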