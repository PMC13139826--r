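choice_log_columns <- c("subject_id", "group", "block", "trial_id",
                        "d_ss", "d_ll", "r_ss", "r_ll", "choice", "rt",
                        "trial_duration", "t_elapsed_at_start", "loot_after")

#' Write a choice log to CSV
#'
#' One row per trial with the documented schema (this is also the ingestion
#' format for real data): subject_id, group, block, trial_id, d_ss, d_ll,
#' r_ss, r_ll, choice, rt, trial_duration, t_elapsed_at_start, loot_after.
#'
#' @param logs Choice-log tibble (e.g. from \code{\link{simulate_cohort}}).
#' @param path Output file.
#' @export
write_choice_log <- function(logs, path) {
  missing <- setdiff(choice_log_columns, names(logs))
  if (length(missing))
    abort(paste("choice log is missing columns:", paste(missing, collapse = ", ")))
  readr::write_csv(logs[, choice_log_columns], path)
  invisible(path)
}

#' Read and validate a choice log CSV
#'
#' Checks the schema, recomputes the derived delays \code{t = d *
#' seconds_per_square}, cross-checks any delay columns present in the file,
#' and labels each trial's optimal side.
#'
#' @param path CSV file with the documented choice-log schema.
#' @param seconds_per_square Avatar speed used to derive delays
#'   (default 1.3).
#' @return A validated choice-log tibble including \code{t_ss, t_ll,
#'   optimal_side}.
#' @export
read_choice_log <- function(path, seconds_per_square = 1.3) {
  logs <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(choice_log_columns, names(logs))
  if (length(missing))
    abort(paste("choice log is missing columns:", paste(missing, collapse = ", ")),
          class = "dd_parse_error")
  num <- c("block", "trial_id", "d_ss", "d_ll", "r_ss", "r_ll", "rt",
           "trial_duration", "t_elapsed_at_start", "loot_after")
  for (col in num) {
    if (!is.numeric(logs[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(logs[[col]]))))[1L]
      abort(sprintf("column `%s` is not numeric (first bad row: %d).", col, bad),
            class = "dd_parse_error")
    }
  }
  if (!all(logs$choice %in% c("SS", "LL")))
    abort(sprintf("column `choice` must be 'SS' or 'LL' (first bad row: %d).",
                  which(!logs$choice %in% c("SS", "LL"))[1L]),
          class = "dd_parse_error")
  for (side in c("ss", "ll")) {
    tcol <- paste0("t_", side); dcol <- paste0("d_", side)
    derived <- logs[[dcol]] * seconds_per_square
    if (tcol %in% names(logs)) {
      bad <- which(abs(logs[[tcol]] - derived) > 1e-6)
      if (length(bad))
        abort(sprintf("row %d: %s = %g inconsistent with %s x %g s/square.",
                      bad[1L], tcol, logs[[tcol]][bad[1L]], dcol, seconds_per_square),
              class = "dd_parse_error")
    }
    logs[[tcol]] <- derived
  }
  logs$optimal_side <- label_optimal(logs)
  logs
}

#' Write a trial schedule to TSV
#'
#' @param trials Tibble from \code{\link{generate_trials}}.
#' @param path Output file.
#' @export
write_trials <- function(trials, path) {
  readr::write_tsv(trials, path)
  invisible(path)
}

#' Read a trial schedule from TSV
#'
#' @param path TSV with header trial_id, d_ss, d_ll, r_ss, r_ll, t_ss,
#'   t_ll, optimal_side.
#' @return Trial tibble.
#' @export
read_trials <- function(path) {
  trials <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("trial_id", "d_ss", "d_ll", "r_ss", "r_ll", "t_ss", "t_ll", "optimal_side")
  missing <- setdiff(need, names(trials))
  if (length(missing))
    abort(paste("trial schedule is missing columns:", paste(missing, collapse = ", ")),
          class = "dd_parse_error")
  trials
}

#' Serialize a generator config to JSON
#'
#' @param config A \code{\link{generator_config}}.
#' @param path Output JSON file. The seed is mandatory for a reproducible
#'   file.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "dd_generator_config"))
  if (is.null(config$seed)) abort("a seed is required to serialize a config.")
  fields <- config[setdiff(names(config), "calibration")]
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a generator config from JSON
#'
#' @param path JSON file written by \code{\link{write_generator_config}}.
#' @return A \code{\link{generator_config}}.
#' @export
read_generator_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$seed)) abort("config file must contain a seed.", class = "dd_parse_error")
  generator_config(
    distance_diff_support = x$distance_diff_support,
    distance_diff_weights = x$distance_diff_weights,
    ss_distance_support = x$ss_distance_support,
    reward_diff_support = x$reward_diff_support,
    reward_diff_weights = x$reward_diff_weights,
    max_reward_units = x$max_reward_units,
    seconds_per_square = x$seconds_per_square,
    ll_optimal_target_rate = x$ll_optimal_target_rate,
    euros_per_reward_unit = x$euros_per_reward_unit,
    points_per_eurocent = x$points_per_eurocent,
    seed = x$seed
  )
}
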