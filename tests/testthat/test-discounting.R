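test_that("reaction-time filter keeps the closed interval [0.3, 15] and is idempotent", {
  log <- make_log(d_ss = 2L, d_ll = 3L, r_ss = 2L, r_ll = 8L,
                  choice = rep("LL", 5), rt = c(0.2, 0.3, 1.4, 15.0, 15.1))
  kept <- filter_valid_trials(log)
  expect_equal(nrow(kept), 3L)
  expect_equal(attr(kept, "n_removed"), 2L)
  expect_equal(kept$rt, c(0.3, 1.4, 15.0))
  again <- filter_valid_trials(kept)
  expect_equal(attr(again, "n_removed"), 0L)
  expect_equal(as.data.frame(again), as.data.frame(kept), ignore_attr = TRUE)
  expect_error(filter_valid_trials(log[0, ]), "empty")
  # simulated sessions never produce out-of-range reaction times
  sim <- quick_session(k = 0.15, tau = 1.75, seed = 3)
  expect_equal(attr(filter_valid_trials(sim), "n_removed"), 0L)
})

test_that("a fixed-threshold responder yields indifference points at the threshold", {
  log <- threshold_log(function(delay) rep(0.5, length(delay)))
  pts <- estimate_indifference_points(log)
  expect_equal(nrow(pts), 4L)
  expect_equal(pts$delay_diff, c(1.3, 2.6, 5.2, 9.1))
  expect_lt(max(abs(pts$theta - 0.5)), 0.07)
})

test_that("indifference points recover the generative hyperbola", {
  k <- 0.1
  log <- do.call(rbind, lapply(1:4, function(s)
    quick_session(k = k, tau = 25, seed = 400 + s)))
  pts <- estimate_indifference_points(log)
  expected <- 1 / (1 + k * pts$delay_diff)
  expect_lt(max(abs(pts$theta - expected)), 0.06)
})

test_that("constant responders are clipped and flagged", {
  all_ll <- make_log(d_ss = 3L, d_ll = 5L, r_ss = rep(1:9, 2), r_ll = 10L,
                     choice = "LL")
  pts <- estimate_indifference_points(all_ll)
  expect_equal(pts$theta, 1)
  expect_true(pts$clipped)
  all_ss <- make_log(d_ss = 3L, d_ll = 5L, r_ss = rep(1:9, 2), r_ll = 10L,
                     choice = "SS")
  pts2 <- estimate_indifference_points(all_ss)
  expect_equal(pts2$theta, 0)
  expect_true(pts2$clipped)
  # low-trial levels are flagged
  few <- make_log(d_ss = 3L, d_ll = 5L, r_ss = c(2L, 8L), r_ll = 10L,
                  choice = c("LL", "SS"))
  expect_true(all(estimate_indifference_points(few)$low_n))
  expect_error(estimate_indifference_points(few[0, ]), "empty")
})

test_that("theta always stays inside [0, 1]", {
  set.seed(5)
  for (r in 1:20) {
    n <- 40
    log <- make_log(d_ss = 3L, d_ll = sample(c(4L, 10L), n, TRUE),
                    r_ss = sample(1:9, n, TRUE), r_ll = 10L,
                    choice = sample(c("SS", "LL"), n, TRUE))
    pts <- estimate_indifference_points(log)
    expect_true(all(pts$theta >= 0 & pts$theta <= 1))
  }
})

test_that("fit_hyperbolic_k recovers an exact generative k and boundary cases", {
  delays <- c(1.3, 2.6, 5.2, 9.1)
  pts <- tibble::tibble(delay_diff = delays, theta = 1 / (1 + 0.2 * delays))
  fit <- fit_hyperbolic_k(pts)
  expect_lt(abs(fit$k - 0.2), 1e-3)
  expect_lt(fit$fit_sse, 1e-10)
  flat <- tibble::tibble(delay_diff = delays, theta = rep(1, 4))
  expect_equal(fit_hyperbolic_k(flat)$k, 0)
  expect_error(fit_hyperbolic_k(pts[1, ]), class = "dd_insufficient_data")
})

test_that("log_k applies the floor", {
  expect_equal(log_k(1), 0)
  expect_equal(log_k(0), log(1e-4))
  expect_equal(log_k(0), -9.2103, tolerance = 1e-4)
  expect_equal(log_k(0.2), -1.6094, tolerance = 1e-4)
  expect_error(log_k(-0.1), ">= 0")
})

test_that("compute_auc matches trapezoid arithmetic", {
  delays <- c(1.3, 2.6, 5.2, 9.1)
  expect_equal(compute_auc(tibble::tibble(delay_diff = delays, theta = rep(1, 4))), 1)
  two <- tibble::tibble(delay_diff = c(0.5, 1.0), theta = c(0.5, 0.25))
  expect_equal(compute_auc(two), 0.5 * (1 + 0.5) / 2 + 0.5 * (0.5 + 0.25) / 2)
  expect_equal(compute_auc(two), 0.5625)
  one <- tibble::tibble(delay_diff = 2.6, theta = 0)
  expect_equal(compute_auc(one), 0.5)
  # order invariance
  expect_equal(compute_auc(two[2:1, ]), compute_auc(two))
  expect_error(compute_auc(two[0, ]), "at least one")
})

test_that("proportion_ss counts SS choices", {
  log <- make_log(d_ss = 2L, d_ll = 3L, r_ss = 2L, r_ll = 8L,
                  choice = rep(c("SS", "LL"), 10))
  expect_equal(proportion_ss(log), 0.5)
  expect_equal(proportion_ss(log[log$choice == "SS", ]), 1)
  expect_error(proportion_ss(log[0, ]), "empty")
  # a coin-flip agent sits near one half
  flips <- do.call(rbind, lapply(1:3, function(s) quick_session(k = 0.1, tau = 0, seed = s)))
  expect_lt(abs(proportion_ss(flips) - 0.5), 0.05)
})

test_that("recovered k is accurate and monotone across the k grid", {
  k_grid <- c(0.02, 0.05, 0.1, 0.3)
  recover <- function(k, seed) {
    log <- quick_session(k = k, tau = 8, seed = seed)
    discounting_measures(log)$result$k
  }
  rec <- lapply(k_grid, function(k)
    vapply(1:8, function(s) recover(k, 7000 + 13 * s + round(1000 * k)), numeric(1)))
  med <- vapply(rec, median, numeric(1))
  expect_true(all(abs(med - k_grid) / k_grid < 0.25))
  truth <- rep(k_grid, each = 8)
  expect_gt(cor(truth, unlist(rec), method = "spearman"), 0.9)
})

test_that("AUC and k are inversely monotone across a cohort", {
  set.seed(12)
  ks <- exp(rnorm(24, log(0.12), 0.8))
  res <- lapply(seq_along(ks), function(i) {
    log <- quick_session(k = ks[i], tau = 3, seed = 300 + i)
    discounting_measures(log)$result
  })
  res <- do.call(rbind, res)
  expect_true(all(res$auc >= 0 & res$auc <= 1))
  expect_lt(cor(res$k, res$auc, method = "spearman"), -0.8)
})

test_that("analyze_discounting emits one row per subject with theta columns", {
  logs <- rbind(quick_session(k = 0.1, tau = 2, seed = 1, subject_id = "a"),
                quick_session(k = 0.3, tau = 2, seed = 2, subject_id = "b"))
  res <- analyze_discounting(logs)
  expect_equal(res$subject_id, c("a", "b"))
  expect_true(all(c("theta_1_3", "theta_2_6", "theta_5_2", "theta_9_1",
                    "clipped_1_3", "n_9_1") %in% names(res)))
  expect_true(all(res$prop_ss >= 0 & res$prop_ss <= 1))
})
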