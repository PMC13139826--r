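test_that("welch_t reproduces published group comparisons from summaries", {
  bmi <- welch_t(summary_stats(20.89, 2.10, 80), summary_stats(14.66, 1.42, 80))
  expect_lt(abs(bmi$t - 22.00), 0.05)
  expect_lt(abs(bmi$df - 138.78), 0.5)
  age <- welch_t(summary_stats(16.27, 2.51, 80), summary_stats(16.26, 2.48, 80))
  expect_lt(abs(age$df - 157.98), 0.05)
})

test_that("welch_t basic identities and oracle agreement", {
  a <- summary_stats(5, 1, 20)
  same <- welch_t(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  b <- summary_stats(4.2, 1.7, 31)
  ab <- welch_t(a, b); ba <- welch_t(b, a)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$df, ba$df)
  expect_error(welch_t(summary_stats(1, 0, 5), summary_stats(2, 0, 5)),
               class = "dd_degenerate")
  # oracle: t.test on raw data scaled to the exact summary moments
  set.seed(3)
  x <- rnorm(20); x <- (x - mean(x)) / sd(x) * 1.0 + 5
  y <- rnorm(31); y <- (y - mean(y)) / sd(y) * 1.7 + 4.2
  tt <- t.test(x, y)
  expect_equal(ab$t, unname(tt$statistic), tolerance = 1e-8)
  expect_equal(ab$df, unname(tt$parameter), tolerance = 1e-8)
  expect_equal(ab$p, tt$p.value, tolerance = 1e-8)
})

test_that("power_two_sample matches the noncentral-t oracle and is monotone", {
  for (d in c(0.2, 0.5, 0.8)) {
    expect_equal(power_two_sample(d, 80, sided = "one"),
                 power.t.test(n = 80, delta = d, sd = 1, sig.level = 0.05,
                              alternative = "one.sided")$power,
                 tolerance = 1e-6)
    # power.t.test neglects the opposite-tail rejection region, so agreement
    # is only to ~2e-3 in absolute terms for small effects
    expect_lt(abs(power_two_sample(d, 40, sided = "two") -
                    power.t.test(n = 40, delta = d, sd = 1, sig.level = 0.05,
                                 alternative = "two.sided")$power),
              5e-3)
  }
  expect_equal(power_two_sample(0, 50, alpha = 0.05), 0.05, tolerance = 1e-9)
  grid_d <- power_two_sample(seq(0.1, 1, by = 0.1), 30)
  expect_true(all(diff(grid_d) > 0))
  grid_n <- vapply(c(10, 20, 40, 80, 160), power_two_sample, numeric(1), d = 0.3)
  expect_true(all(diff(grid_n) > 0))
  expect_error(power_two_sample(0.5, 80, alpha = 0), "alpha")
})

test_that("bh_fdr equals the hand-applied step-up rule", {
  expect_equal(bh_fdr(0.04), 0.04)
  # hand computation: p_(i) * m / i, cumulative minimum from the largest rank
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.005, 0.04, 0.2, 0.9)),
               c(0.005 * 4 / 1, 0.04 * 4 / 2, 0.2 * 4 / 3, 0.9))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.3, 0.001, 0.07, 0.02)
  o <- order(p)
  expect_equal(bh_fdr(p)[o], bh_fdr(p[o]))
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("binomial_group_model recovers a known group odds ratio", {
  set.seed(21)
  n <- 80; trials <- 140
  covered <- logical(100)
  for (r in seq_len(100)) {
    group <- rep(c("HC", "AN"), each = n)
    age <- runif(2 * n, 12, 26)
    logit <- -1 + log(1.5) * (group == "AN") + 0.02 * (age - 16)
    s <- rbinom(2 * n, trials, plogis(logit))
    fit <- binomial_group_model(s, rep(trials, 2 * n),
                                factor(group, c("HC", "AN")), age)
    covered[r] <- fit$ci_low <= 1.5 && 1.5 <= fit$ci_high
  }
  expect_gte(mean(covered), 0.90)
})

test_that("binomial_group_model nulls and failure modes", {
  set.seed(4)
  s <- rbinom(60, 100, 0.4)
  g <- rep(c("a", "b"), 30)
  fit <- binomial_group_model(s, rep(100, 60), g, age = runif(60, 12, 26))
  expect_lt(abs(fit$odds_ratio - 1), 0.15)
  expect_gt(fit$p, 0.05)
  # complete separation: all successes in one group
  expect_error(
    binomial_group_model(c(rep(0, 10), rep(5, 10)), rep(5, 20), rep(c("a", "b"), each = 10)),
    class = "dd_separation")
  expect_error(binomial_group_model(c(2, 3), c(5, 5), c("a", "b")), "two groups")
})

test_that("gaussian_group_model recovers an injected shift and handles degeneracy", {
  set.seed(31)
  n <- 80
  group <- rep(c("HC", "AN"), each = n)
  age <- runif(2 * n, 12, 26)
  y <- 0.6 + 0.5 * (group == "AN") - 0.01 * age + rnorm(2 * n, 0, 0.15)
  fit <- gaussian_group_model(y, factor(group, c("HC", "AN")), age)
  expect_true(fit$ci_low <= 0.5 && 0.5 <= fit$ci_high)
  expect_lt(fit$p, 0.001)
  # identical outcomes: zero estimate (perfect-fit summary warning expected)
  null <- suppressWarnings(gaussian_group_model(rep(1, 20), rep(c("a", "b"), 10)))
  expect_equal(null$estimate, 0)
  # constant age dropped with a warning
  expect_warning(gaussian_group_model(rnorm(20), rep(c("a", "b"), 10), age = rep(16, 20)),
                 "constant")
})

test_that("covariate_association behaves on trivial and degenerate inputs", {
  x <- c(1, 2, 3, 4, 5)
  flat <- suppressWarnings(covariate_association(rep(2, 5), x))
  expect_equal(flat$slope, 0)
  expect_error(covariate_association(rnorm(5), rep(1, 5)), "zero variance")
  set.seed(8)
  xx <- rnorm(50); yy <- 2 - 3 * xx + rnorm(50, 0, 0.1)
  fit <- covariate_association(yy, xx)
  expect_lt(abs(fit$slope + 3), 0.1)
  expect_lt(fit$p, 1e-10)
})

test_that("match_pairs equals brute-force assignment cost on small instances", {
  brute <- function(a, b) {
    pm <- function(v) if (length(v) <= 1) list(v) else {
      out <- list()
      for (i in seq_along(v)) for (p in pm(v[-i])) out <- c(out, list(c(v[i], p)))
      out
    }
    best <- Inf
    for (cc in combn(length(b), length(a), simplify = FALSE))
      for (p in pm(cc)) best <- min(best, sum(abs(a - b[p])))
    best
  }
  set.seed(17)
  for (r in 1:40) {
    n <- sample(1:4, 1); m <- n + sample(0:2, 1)
    a <- round(runif(n, 12, 26), 1)
    b <- round(runif(m, 12, 26), 1)
    res <- match_pairs(a, b)
    expect_equal(res$total_abs_age_diff, brute(a, b), tolerance = 1e-9)
    expect_equal(sum(res$pairs$abs_diff), res$total_abs_age_diff)
    expect_equal(anyDuplicated(res$pairs$control), 0L)
  }
})

test_that("match_pairs edge cases and greedy dominance", {
  same <- match_pairs(c(14, 15, 16), c(16, 14, 15))
  expect_equal(same$total_abs_age_diff, 0)
  expect_equal(same$max_abs_age_diff, 0)
  empty <- match_pairs(numeric(0), c(1, 2))
  expect_equal(nrow(empty$pairs), 0L)
  expect_error(match_pairs(c(1, 2, 3), c(1, 2)), "smaller")
  # never worse than greedy nearest-neighbour matching
  set.seed(23)
  for (r in 1:200) {
    n <- sample(2:8, 1); m <- n + sample(0:4, 1)
    a <- runif(n, 12, 26); b <- runif(m, 12, 26)
    pool <- b; greedy <- 0
    for (x in a) {
      i <- which.min(abs(pool - x)); greedy <- greedy + abs(pool[i] - x)
      pool <- pool[-i]
    }
    expect_lte(match_pairs(a, b)$total_abs_age_diff, greedy + 1e-9)
  }
})
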