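#' Summary statistics of one group
#'
#' @param mean Group mean.
#' @param sd Group standard deviation (\code{>= 0}).
#' @param n Group size (\code{>= 2}).
#' @return A \code{dd_summary_stats} object.
#' @export
summary_stats <- function(mean, sd, n) {
  if (sd < 0) abort("`sd` must be >= 0.")
  if (n < 2) abort("`n` must be >= 2.")
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "dd_summary_stats")
}

#' Welch's t-test from group summary statistics
#'
#' \code{t = (mean_a - mean_b) / sqrt(sd_a^2/n_a + sd_b^2/n_b)} with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value, as used
#' to compare published group summaries.
#'
#' @param a,b \code{\link{summary_stats}} objects.
#' @param conf_level Confidence level for the mean-difference CI
#'   (default 0.95).
#' @return One-row tibble: \code{estimate, t, df, p, ci_low, ci_high}.
#' @examples
#' welch_t(summary_stats(20.89, 2.10, 80), summary_stats(14.66, 1.42, 80))
#' @export
welch_t <- function(a, b, conf_level = 0.95) {
  stopifnot(inherits(a, "dd_summary_stats"), inherits(b, "dd_summary_stats"))
  ua <- a$sd^2 / a$n
  ub <- b$sd^2 / b$n
  if (ua + ub == 0) abort("both groups have zero variance; t is undefined.",
                          class = "dd_degenerate")
  se <- sqrt(ua + ub)
  t <- (a$mean - b$mean) / se
  df <- (ua + ub)^2 / (ua^2 / (a$n - 1) + ub^2 / (b$n - 1))
  half <- qt(1 - (1 - conf_level) / 2, df) * se
  tibble(estimate = a$mean - b$mean, t = t, df = df,
         p = 2 * pt(-abs(t), df),
         ci_low = a$mean - b$mean - half, ci_high = a$mean - b$mean + half)
}

#' Power of a two-sample t-test
#'
#' Noncentral-t power with \code{ncp = d * sqrt(n/2)} and
#' \code{df = 2n - 2}.
#'
#' @param d Cohen's d.
#' @param n_per_group Sample size per group.
#' @param alpha Significance level (default 0.05).
#' @param sided \code{"one"} (default) or \code{"two"}.
#' @return Power in [0, 1].
#' @examples
#' power_two_sample(0.5, 80) # ~0.93
#' @export
power_two_sample <- function(d, n_per_group, alpha = 0.05,
                             sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie strictly in (0, 1).")
  if (n_per_group < 2) abort("`n_per_group` must be >= 2.")
  df <- 2 * n_per_group - 2
  ncp <- d * sqrt(n_per_group / 2)
  if (sided == "one") {
    1 - pt(qt(1 - alpha, df), df, ncp = ncp)
  } else {
    crit <- qt(1 - alpha / 2, df)
    1 - pt(crit, df, ncp = ncp) + pt(-crit, df, ncp = ncp)
  }
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Adjusted q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    abort("p-values must lie in [0, 1].")
  p.adjust(pvalues, method = "BH")
}

group_result_row <- function(term, fit, link = c("identity", "logit"),
                             conf_level = 0.95) {
  link <- match.arg(link)
  cf <- summary(fit)$coefficients
  est <- cf[term, 1L]; se <- cf[term, 2L]
  stat <- cf[term, 3L]; p <- cf[term, 4L]
  z <- qnorm(1 - (1 - conf_level) / 2)
  df <- if (inherits(fit, "glm") && fit$family$family == "binomial") NA_real_ else fit$df.residual
  half <- if (is.na(df)) z * se else qt(1 - (1 - conf_level) / 2, df) * se
  tibble(term = term, estimate = est,
         odds_ratio = if (link == "logit") exp(est) else NA_real_,
         statistic = stat, df = df, p = p,
         ci_low = if (link == "logit") exp(est - half) else est - half,
         ci_high = if (link == "logit") exp(est + half) else est + half)
}

#' Binomial logistic regression of per-subject proportions on group
#'
#' Fits \code{cbind(successes, totals - successes) ~ group + age} and
#' reports the group effect as an odds ratio with a Wald confidence
#' interval. Complete separation is reported as an error.
#'
#' @param successes,totals Per-subject counts.
#' @param group Factor-like group labels (the effect reported is for the
#'   second level vs the first).
#' @param age Optional age covariate; dropped with a warning if constant.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: log-odds estimate, odds ratio, z, p, CI.
#' @export
binomial_group_model <- function(successes, totals, group, age = NULL,
                                 conf_level = 0.95) {
  if (any(successes < 0) || any(successes > totals))
    abort("`successes` must lie in [0, totals].")
  group <- factor(group)
  if (nlevels(group) != 2L || any(table(group) < 2L))
    abort("two groups with at least two subjects each are required.")
  dat <- data.frame(s = successes, f = totals - successes, group = group)
  form <- cbind(s, f) ~ group
  if (!is.null(age)) {
    if (var(age) == 0) {
      warn("age covariate is constant; dropping it from the model.")
    } else {
      dat$age <- age
      form <- cbind(s, f) ~ group + age
    }
  }
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = dat,
        control = list(epsilon = 1e-8, maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  term <- paste0("group", levels(group)[2L])
  if (sep || abs(coef(fit)[term]) > 15)
    abort("complete or quasi-complete separation: the group log-odds are not identifiable.",
          class = "dd_separation")
  group_result_row(term, fit, link = "logit", conf_level = conf_level)
}

#' Gaussian linear model of a per-subject measure on group
#'
#' Fits \code{y ~ group + age} by least squares and reports the group
#' effect.
#'
#' @param y Per-subject outcome (e.g. AUC, log k, d').
#' @param group Two-level group labels.
#' @param age Optional age covariate; dropped with a warning if constant.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble with the group estimate, t, df, p, CI.
#' @export
gaussian_group_model <- function(y, group, age = NULL, conf_level = 0.95) {
  group <- factor(group)
  if (nlevels(group) != 2L || any(table(group) < 3L))
    abort("two groups with at least three subjects each are required.")
  dat <- data.frame(y = y, group = group)
  form <- y ~ group
  if (!is.null(age)) {
    if (var(age) == 0) {
      warn("age covariate is constant; dropping it from the model.")
    } else {
      dat$age <- age
      form <- y ~ group + age
    }
  }
  fit <- lm(form, data = dat)
  if (any(is.na(coef(fit)))) abort("collinear design; model is not identifiable.")
  group_result_row(paste0("group", levels(group)[2L]), fit,
                   link = "identity", conf_level = conf_level)
}

#' Within-group association of a behavioural measure with a covariate
#'
#' Simple linear regression of a per-subject measure on one clinical
#' covariate (e.g. SS-choice proportion on BMI-SDS within the patient
#' group).
#'
#' @param y Outcome values.
#' @param x Covariate values (non-constant).
#' @return One-row tibble: slope, t, df, p, n.
#' @export
covariate_association <- function(y, x) {
  if (length(y) < 3L) abort("at least three subjects are required.")
  if (var(x) == 0) abort("`x` has zero variance.")
  fit <- lm(y ~ x)
  cf <- summary(fit)$coefficients
  tibble(slope = cf["x", 1L], t = cf["x", 3L], df = fit$df.residual,
         p = cf["x", 4L], n = length(y))
}

#' Optimal pairwise age matching (assignment problem)
#'
#' Selects, for each case, a distinct control from the pool so that the sum
#' of absolute age differences within pairs is minimal. Because the cost is
#' the absolute difference of scalars, the optimal assignment is
#' order-preserving after sorting, and an exact dynamic program over the
#' sorted lists solves the assignment problem in O(cases x pool).
#'
#' @param case_ages Ages of the cases.
#' @param control_pool_ages Ages of the available controls (pool size must
#'   be at least the number of cases).
#' @return List with \code{pairs} (tibble: case, control indices into the
#'   original vectors, both ages, abs_diff), \code{total_abs_age_diff} and
#'   \code{max_abs_age_diff}.
#' @export
match_pairs <- function(case_ages, control_pool_ages) {
  n <- length(case_ages); m <- length(control_pool_ages)
  if (m < n) abort("control pool is smaller than the case list.")
  if (n == 0L)
    return(list(pairs = tibble(case = integer(), control = integer(),
                               age_case = numeric(), age_control = numeric(),
                               abs_diff = numeric()),
                total_abs_age_diff = 0, max_abs_age_diff = 0))
  oa <- order(case_ages); ob <- order(control_pool_ages)
  a <- case_ages[oa]; b <- control_pool_ages[ob]
  INF <- Inf
  # C[i+1, j+1]: min cost matching first i sorted cases into first j controls
  C <- matrix(INF, n + 1L, m + 1L)
  C[1L, ] <- 0
  for (i in seq_len(n)) {
    for (j in i:m) {
      C[i + 1L, j + 1L] <- min(C[i + 1L, j], C[i, j] + abs(a[i] - b[j]))
    }
  }
  # backtrack
  pairs <- integer(n)
  j <- m
  for (i in n:1) {
    while (j > i && C[i + 1L, j + 1L] == C[i + 1L, j]) j <- j - 1L
    pairs[i] <- j
    j <- j - 1L
  }
  case_idx <- oa
  control_idx <- ob[pairs]
  diffs <- abs(case_ages[case_idx] - control_pool_ages[control_idx])
  list(pairs = tibble(case = case_idx, control = control_idx,
                      age_case = case_ages[case_idx],
                      age_control = control_pool_ages[control_idx],
                      abs_diff = diffs),
       total_abs_age_diff = sum(diffs),
       max_abs_age_diff = max(diffs))
}
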