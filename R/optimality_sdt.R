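#' Score per-trial optimality of choices
#'
#' A choice is optimal when it matches the side with the strictly higher
#' reward rate. Trials whose two options have exactly equal rates (ties,
#' possible in externally supplied logs) are excluded and counted.
#'
#' @param log A (filtered) choice log with \code{choice} and either an
#'   \code{optimal_side} column or the fields needed by
#'   \code{\link{label_optimal}}.
#' @return One-row tibble: \code{prop_optimal},
#'   \code{prop_ss_given_ss_optimal}, \code{prop_ll_given_ll_optimal}
#'   (\code{NA} when the conditioning subset is empty), counts per class,
#'   and \code{n_ties_excluded}.
#' @export
score_optimality <- function(log) {
  if (nrow(log) == 0L) abort("empty choice log.")
  side <- if ("optimal_side" %in% names(log)) log$optimal_side else label_optimal(log)
  tie <- side == "tie"
  side <- side[!tie]; choice <- log$choice[!tie]
  if (length(side) == 0L) abort("no non-tie trials to score.")
  ss_opt <- side == "SS"; ll_opt <- side == "LL"
  tibble(
    prop_optimal = mean(choice == side),
    prop_ss_given_ss_optimal = if (any(ss_opt)) mean(choice[ss_opt] == "SS") else NA_real_,
    prop_ll_given_ll_optimal = if (any(ll_opt)) mean(choice[ll_opt] == "LL") else NA_real_,
    n_ss_optimal = sum(ss_opt),
    n_ll_optimal = sum(ll_opt),
    n_ties_excluded = sum(tie)
  )
}

#' Signal-detection counts from a choice log
#'
#' Convention: an LL-optimal trial is a signal and choosing LL is a "yes".
#' Hits are LL choices on LL-optimal trials; false alarms are LL choices on
#' SS-optimal trials. Tie trials are excluded.
#'
#' @param log A (filtered) choice log.
#' @return One-row tibble with \code{hits, misses, false_alarms,
#'   correct_rejections}.
#' @export
sdt_counts <- function(log) {
  if (nrow(log) == 0L) abort("empty choice log.")
  side <- if ("optimal_side" %in% names(log)) log$optimal_side else label_optimal(log)
  keep <- side != "tie"
  side <- side[keep]; choice <- log$choice[keep]
  if (!any(side == "LL") || !any(side == "SS"))
    abort("both an LL-optimal and an SS-optimal trial are required; d'/beta are undefined otherwise.",
          class = "dd_sdt_undefined")
  tibble(
    hits = sum(side == "LL" & choice == "LL"),
    misses = sum(side == "LL" & choice == "SS"),
    false_alarms = sum(side == "SS" & choice == "LL"),
    correct_rejections = sum(side == "SS" & choice == "SS")
  )
}

#' Standard normal quantile
#'
#' Inverse standard normal CDF with explicit domain checking, as used by the
#' signal-detection transforms.
#'
#' @param p Probability strictly between 0 and 1.
#' @return z such that \code{pnorm(z) = p}.
#' @export
normal_quantile <- function(p) {
  if (any(p <= 0) || any(p >= 1)) abort("`p` must lie strictly between 0 and 1.")
  qnorm(p)
}

#' Discriminability and response bias from signal-detection counts
#'
#' Rates exactly 0 or 1 are replaced by \code{1/(2N)} or \code{1 - 1/(2N)}
#' for that class's N before the z-transform. Then
#' \code{d' = z(hit rate) - z(false-alarm rate)},
#' \code{beta = exp((z_FA^2 - z_H^2)/2)} (likelihood-ratio criterion), and
#' the criterion location \code{c = -(z_H + z_FA)/2} is also reported. Under
#' the LL-optimal-as-signal, choose-LL-as-yes convention, beta > 1 marks a
#' conservative criterion (responses pushed toward SS) and beta < 1 a
#' liberal one (responses pushed toward LL); an additive SS bias therefore
#' raises beta.
#'
#' @param hits,misses,false_alarms,correct_rejections Non-negative counts.
#' @return One-row tibble with counts, corrected rates, \code{d_prime},
#'   \code{beta}, \code{criterion_c}, and \code{correction_applied}.
#' @export
dprime_beta <- function(hits, misses, false_alarms, correct_rejections) {
  counts <- c(hits, misses, false_alarms, correct_rejections)
  if (any(counts < 0) || any(counts != round(counts)))
    abort("counts must be non-negative integers.")
  n_signal <- hits + misses
  n_noise <- false_alarms + correct_rejections
  if (n_signal == 0L || n_noise == 0L)
    abort("both classes need at least one trial.", class = "dd_sdt_undefined")
  correct_rate <- function(x, n) {
    r <- x / n
    if (r == 0) r <- 1 / (2 * n) else if (r == 1) r <- 1 - 1 / (2 * n)
    r
  }
  hr <- correct_rate(hits, n_signal)
  fr <- correct_rate(false_alarms, n_noise)
  corrected <- (hits %in% c(0L, n_signal)) || (false_alarms %in% c(0L, n_noise))
  zh <- normal_quantile(hr); zf <- normal_quantile(fr)
  tibble(hits = hits, misses = misses, false_alarms = false_alarms,
         correct_rejections = correct_rejections,
         hit_rate = hr, fa_rate = fr,
         d_prime = zh - zf,
         beta = exp((zf^2 - zh^2) / 2),
         criterion_c = -(zh + zf) / 2,
         correction_applied = corrected)
}

#' Optimality and signal-detection measures for every subject
#'
#' @param logs A choice log with a \code{subject_id} column.
#' @return Tibble, one row per subject: optimality proportions, SDT counts,
#'   \code{d_prime}, \code{beta}, \code{criterion_c},
#'   \code{correction_applied}.
#' @export
analyze_optimality <- function(logs) {
  stopifnot("subject_id" %in% names(logs))
  ids <- unique(logs$subject_id)
  rows <- lapply(ids, function(id) {
    log <- logs[logs$subject_id == id, , drop = FALSE]
    opt <- score_optimality(log)
    cnt <- sdt_counts(log)
    sdt <- dprime_beta(cnt$hits, cnt$misses, cnt$false_alarms, cnt$correct_rejections)
    cbind(tibble(subject_id = id), opt,
          sdt[, c("hits", "misses", "false_alarms", "correct_rejections",
                  "d_prime", "beta", "criterion_c", "correction_applied")])
  })
  as_tibble(do.call(rbind, rows))
}
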