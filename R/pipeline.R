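#' End-to-end pipeline configuration
#'
#' Bundles the trial generator, the cohort specification, and the analysis
#' options into one reproducible unit. The seed is mandatory; all
#' randomness in a pipeline run derives from it.
#'
#' @param generator A \code{\link{generator_config}}.
#' @param cohort A \code{\link{cohort_spec}}.
#' @param alpha Significance level used when summarising group tests
#'   (default 0.05).
#' @param k_floor Floor for the log transform of k (default 1e-4 /s).
#' @param conf_level Confidence level of reported intervals (default 0.95).
#' @param seed Integer seed (mandatory).
#' @return A \code{dd_pipeline_config} object.
#' @export
pipeline_config <- function(generator = generator_config(),
                            cohort = cohort_spec(),
                            alpha = 0.05, k_floor = 1e-4,
                            conf_level = 0.95, seed = NULL) {
  stopifnot(inherits(generator, "dd_generator_config"),
            inherits(cohort, "dd_cohort_spec"))
  if (is.null(seed)) abort("`seed` is mandatory in a pipeline config.",
                           class = "dd_validation_error")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie strictly in (0, 1).")
  structure(list(generator = generator, cohort = cohort, alpha = alpha,
                 k_floor = k_floor, conf_level = conf_level,
                 seed = as.integer(seed)),
            class = "dd_pipeline_config")
}

run_group_tests <- function(subjects, conf_level) {
  # report effects as patients vs controls when the standard labels are used
  if (setequal(unique(subjects$group), c("HC", "AN")))
    subjects$group <- factor(subjects$group, levels = c("HC", "AN"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("group test '%s' failed: %s", name, conditionMessage(e)),
            parent = e)
    })
  }
  n_nontie <- subjects$n_ss_optimal + subjects$n_ll_optimal
  binom_tests <- list(
    prop_ss = list(s = round(subjects$prop_ss * subjects$n_valid_trials),
                   t = subjects$n_valid_trials),
    prop_optimal = list(s = round(subjects$prop_optimal * n_nontie), t = n_nontie),
    prop_ss_given_ss_optimal = list(
      s = round(subjects$prop_ss_given_ss_optimal * subjects$n_ss_optimal),
      t = subjects$n_ss_optimal),
    prop_ll_given_ll_optimal = list(
      s = round(subjects$prop_ll_given_ll_optimal * subjects$n_ll_optimal),
      t = subjects$n_ll_optimal)
  )
  gauss_outcomes <- c("auc", "log_k", "d_prime", "beta")
  rows <- list()
  for (nm in names(binom_tests)) {
    bt <- binom_tests[[nm]]
    res <- stage(nm, binomial_group_model(bt$s, bt$t, subjects$group,
                                          subjects$age, conf_level))
    res$outcome <- nm; res$model <- "binomial"
    rows[[nm]] <- res
  }
  for (nm in gauss_outcomes) {
    res <- stage(nm, gaussian_group_model(subjects[[nm]], subjects$group,
                                          subjects$age, conf_level))
    res$outcome <- nm; res$model <- "gaussian"
    rows[[nm]] <- res
  }
  out <- dplyr::bind_rows(rows)
  out$q <- bh_fdr(out$p)   # FDR family: the co-reported outcome tests of one run
  out[, c("outcome", "model", "term", "estimate", "odds_ratio", "statistic",
          "df", "p", "q", "ci_low", "ci_high")]
}

run_sensitivity <- function(subjects) {
  an <- subjects[subjects$group == "AN", , drop = FALSE]
  if (nrow(an) < 3L) return(NULL)
  combos <- expand.grid(outcome = c("prop_ss", "prop_ss_given_ss_optimal"),
                        covariate = c("bmi_sds", "bdi", "edi"),
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    res <- covariate_association(an[[combos$outcome[i]]], an[[combos$covariate[i]]])
    cbind(tibble(outcome = combos$outcome[i], covariate = combos$covariate[i]), res)
  })
  as_tibble(do.call(rbind, rows))
}

#' Run the full simulation-and-analysis pipeline
#'
#' Simulates (or ingests) a cohort of choice logs, applies the
#' reaction-time filter, computes per-subject discounting and
#' optimality/SDT measures, runs the group tests with an age covariate and
#' FDR correction, and reports within-patient covariate sensitivity
#' associations. Fully reproducible from (config, seed).
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param logs Optional pre-existing multi-subject choice log (e.g. from
#'   \code{\link{read_choice_log}}); when supplied, the cohort covariate
#'   table must be given as \code{cohort}. Otherwise a synthetic cohort is
#'   simulated.
#' @param cohort Optional cohort covariate table matching \code{logs}.
#' @return A \code{dd_report} list: \code{subjects} (per-subject measures
#'   joined with covariates), \code{group_tests}, \code{sensitivity},
#'   \code{schedule}, \code{cohort}, \code{logs}, and \code{provenance}
#'   (config hash, seed, package version, trial counts).
#' @export
run_pipeline <- function(config, logs = NULL, cohort = NULL) {
  stopifnot(inherits(config, "dd_pipeline_config"))
  gen <- calibrate_generator(config$generator, pilot_n = 0L)
  if (is.null(logs)) {
    sim <- simulate_cohort(config$cohort, gen, seed = config$seed)
    cohort <- sim$cohort
    logs <- sim$logs
  } else if (is.null(cohort)) {
    abort("`cohort` covariate table is required when `logs` are supplied.",
          class = "dd_validation_error")
  }
  if (is.null(logs) || nrow(logs) == 0L)
    abort("pipeline produced no trials (empty cohort?).", class = "dd_validation_error")
  n_before <- nrow(logs)
  valid <- filter_valid_trials(logs)
  disc <- analyze_discounting(valid, k_floor = config$k_floor)
  opti <- analyze_optimality(valid)
  subjects <- dplyr::inner_join(cohort, dplyr::inner_join(disc, opti, by = "subject_id"),
                                by = "subject_id")
  group_tests <- run_group_tests(subjects, config$conf_level)
  provenance <- list(
    config_hash = rlang::hash(config[c("generator", "cohort", "alpha",
                                       "k_floor", "conf_level")]),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("ddgame")),
    n_subjects = nrow(subjects),
    n_trials = n_before,
    n_trials_removed = attr(valid, "n_removed")
  )
  structure(list(subjects = subjects,
                 group_tests = group_tests,
                 sensitivity = run_sensitivity(subjects),
                 schedule = schedule_summary(valid),
                 cohort = cohort,
                 logs = logs,
                 provenance = provenance),
            class = "dd_report")
}

#' @export
print.dd_report <- function(x, ...) {
  cat("<dd_report>\n")
  cat(sprintf("  %d subjects, %d trials (%d removed by RT filter)\n",
              x$provenance$n_subjects, x$provenance$n_trials,
              x$provenance$n_trials_removed))
  cat(sprintf("  mean trials/subject: %.1f\n",
              x$provenance$n_trials / max(1L, x$provenance$n_subjects)))
  cat("  group tests (", nrow(x$group_tests), " outcomes, BH-FDR q):\n", sep = "")
  print(as.data.frame(x$group_tests[, c("outcome", "estimate", "odds_ratio", "p", "q")]),
        digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write the report bundle to an output directory
#'
#' Emits subjects.csv, group_tests.json, sensitivity.csv, schedule.csv,
#' choice_log.csv, cohort.csv, and provenance.json.
#'
#' @param report A \code{dd_report} from \code{\link{run_pipeline}}.
#' @param dir Output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "dd_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$subjects, file.path(dir, "subjects.csv"))
  jsonlite::write_json(report$group_tests, file.path(dir, "group_tests.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(report$sensitivity))
    readr::write_csv(report$sensitivity, file.path(dir, "sensitivity.csv"))
  readr::write_csv(report$schedule, file.path(dir, "schedule.csv"))
  write_choice_log(report$logs, file.path(dir, "choice_log.csv"))
  readr::write_csv(report$cohort, file.path(dir, "cohort.csv"))
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
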