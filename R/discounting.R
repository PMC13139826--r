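#' Keep only trials with a valid reaction time
#'
#' Retains trials with \code{0.3 <= rt <= 15} seconds (the exclusion rule
#' removes reaction times below 0.3 s and exceeding 15 s; the bounds
#' themselves are valid). Idempotent; the number of removed trials is
#' attached as attribute \code{n_removed}.
#'
#' @param log A choice log (tibble with an \code{rt} column).
#' @return The filtered log.
#' @export
filter_valid_trials <- function(log) {
  if (nrow(log) == 0L) abort("empty choice log.")
  keep <- log$rt >= 0.3 & log$rt <= 15
  out <- log[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

# Delay-difference level of each trial, rounded to 0.1 s so ingested data
# with floating-point delays bin onto the design support.
delay_level <- function(log) round(log$t_ll - log$t_ss, 1)

#' Estimate indifference points per delay-difference level
#'
#' For each delay-difference level, the probability of choosing the SS
#' option is fitted as a logistic function of the value ratio
#' \code{v = r_ss / r_ll}; the indifference point \code{theta} is the ratio
#' at which the fitted probability crosses 0.5. \code{theta} is clipped to
#' [0, 1] and flagged when the crossing lies outside the observed ratio
#' range or when responses are constant (all-LL gives \code{theta = 1},
#' all-SS gives \code{theta = 0}). Levels with fewer than 4 trials are
#' flagged low-n.
#'
#' @param log A (filtered) choice log for one subject.
#' @return A tibble with one row per level: \code{delay_diff, theta,
#'   n_trials, clipped, low_n, se}.
#' @export
estimate_indifference_points <- function(log) {
  if (nrow(log) == 0L) abort("empty choice log.")
  lev <- delay_level(log)
  v <- log$r_ss / log$r_ll
  ss <- log$choice == "SS"
  out <- lapply(sort(unique(lev)), function(L) {
    sel <- lev == L
    vi <- v[sel]; si <- ss[sel]
    n <- sum(sel)
    theta <- NA_real_; clipped <- FALSE; se <- NA_real_
    if (all(si)) {            # always SS: crossing below the observed range
      theta <- 0; clipped <- TRUE
    } else if (!any(si)) {    # always LL: crossing above the observed range
      theta <- 1; clipped <- TRUE
    } else {
      fit <- suppressWarnings(glm(si ~ vi, family = binomial()))
      a <- coef(fit)[1L]; b <- coef(fit)[2L]
      if (!is.finite(a) || !is.finite(b) || b <= 0) {
        # non-monotone or degenerate psychometric curve: fall back on the
        # empirical midpoint between ratios favouring each side
        theta <- min(max((max(vi[!si]) + min(vi[si])) / 2, 0), 1)
        clipped <- TRUE
      } else {
        theta <- -a / b
        V <- suppressWarnings(vcov(fit))
        if (all(is.finite(V))) {
          g <- c(-1 / b, a / b^2)   # delta method for -a/b
          se <- sqrt(drop(t(g) %*% V %*% g))
        }
        if (theta < min(vi) || theta > max(vi)) clipped <- TRUE
        if (theta < 0) { theta <- 0; clipped <- TRUE }
        if (theta > 1) { theta <- 1; clipped <- TRUE }
      }
    }
    tibble(delay_diff = L, theta = theta, n_trials = n,
           clipped = clipped, low_n = n < 4L, se = se)
  })
  do.call(rbind, out)
}

#' Fit the hyperbolic discount rate to indifference points
#'
#' Least-squares fit of \code{theta(delay) = 1 / (1 + k * delay)} over
#' \code{k} in \code{[0, k_max]}: a log-spaced grid search followed by local
#' refinement with \code{\link[stats]{optimize}} (tolerance 1e-6).
#'
#' @param points Tibble from \code{\link{estimate_indifference_points}}
#'   (needs \code{delay_diff} and \code{theta}); at least two distinct
#'   delays.
#' @param k_max Upper search bound, 1/s (default 10).
#' @param grid_n Number of grid points (default 2000).
#' @return List with \code{k} (1/s) and \code{fit_sse}.
#' @export
fit_hyperbolic_k <- function(points, k_max = 10, grid_n = 2000L) {
  pts <- points[is.finite(points$theta) & is.finite(points$delay_diff), , drop = FALSE]
  if (length(unique(pts$delay_diff)) < 2L)
    abort("at least two indifference points with distinct delays are required.",
          class = "dd_insufficient_data")
  sse <- function(k) sum((pts$theta - 1 / (1 + k * pts$delay_diff))^2)
  grid <- c(0, 10^seq(log10(1e-4), log10(k_max), length.out = grid_n - 1L))
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  if (lo < hi) {
    opt <- optimize(sse, c(lo, hi), tol = 1e-6)
    if (opt$objective <= vals[i]) return(list(k = opt$minimum, fit_sse = opt$objective))
  }
  list(k = grid[i], fit_sse = vals[i])
}

#' Log-transformed discount rate
#'
#' \code{ln(max(k, k_floor))}; the floor keeps zero estimates finite.
#'
#' @param k Discount rate(s), 1/s, \code{>= 0}.
#' @param k_floor Floor applied before the log (default 1e-4 /s).
#' @return Natural log of the floored rate.
#' @export
log_k <- function(k, k_floor = 1e-4) {
  if (any(k < 0)) abort("`k` must be >= 0.")
  log(pmax(k, k_floor))
}

#' Area under the indifference-point curve
#'
#' Trapezoid area under \code{(x, theta)} with the anchor point (0, 1)
#' prepended and delays normalised by the largest delay difference. At zero
#' delay difference the two options differ only in reward, so the normative
#' indifference ratio is 1. Lower AUC means steeper discounting.
#'
#' @param points Tibble with \code{delay_diff} and \code{theta}; at least
#'   one point.
#' @return AUC in [0, 1].
#' @export
compute_auc <- function(points) {
  pts <- points[is.finite(points$theta), , drop = FALSE]
  if (nrow(pts) == 0L) abort("at least one indifference point is required.")
  o <- order(pts$delay_diff)
  x <- c(0, pts$delay_diff[o] / max(pts$delay_diff))
  y <- c(1, pmin(pmax(pts$theta[o], 0), 1))
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Proportion of smaller-sooner choices
#'
#' @param log A (filtered) choice log.
#' @return Fraction of trials on which the SS option was chosen.
#' @export
proportion_ss <- function(log) {
  if (nrow(log) == 0L) abort("empty choice log.")
  mean(log$choice == "SS")
}

#' Per-subject discounting measures from a choice log
#'
#' Applies the reaction-time filter, estimates indifference points, fits the
#' hyperbolic discount rate, and computes AUC and the SS-choice proportion.
#'
#' @param log A choice log for one subject.
#' @param k_floor Floor for the log transform of k (default 1e-4 /s).
#' @return A list with \code{result} (one-row tibble: subject_id, k, log_k,
#'   auc, prop_ss, n_valid_trials, fit_sse) and \code{points} (the
#'   indifference-point table).
#' @export
discounting_measures <- function(log, k_floor = 1e-4) {
  valid <- filter_valid_trials(log)
  if (nrow(valid) == 0L) abort("no valid trials after reaction-time filtering.")
  pts <- estimate_indifference_points(valid)
  fit <- fit_hyperbolic_k(pts)
  res <- tibble(
    subject_id = if ("subject_id" %in% names(valid)) valid$subject_id[1L] else NA_character_,
    k = fit$k,
    log_k = log_k(fit$k, k_floor),
    auc = compute_auc(pts),
    prop_ss = proportion_ss(valid),
    n_valid_trials = nrow(valid),
    fit_sse = fit$fit_sse
  )
  list(result = res, points = pts)
}

#' Discounting measures for every subject in a multi-subject log
#'
#' @param logs A choice log containing a \code{subject_id} column.
#' @param k_floor Floor for the log transform of k.
#' @return A tibble with one row per subject: the discounting measures plus
#'   one \code{theta_<delay>/clipped_<delay>/n_<delay>} column triple per
#'   delay level.
#' @export
analyze_discounting <- function(logs, k_floor = 1e-4) {
  stopifnot("subject_id" %in% names(logs))
  ids <- unique(logs$subject_id)
  rows <- lapply(ids, function(id) {
    m <- discounting_measures(logs[logs$subject_id == id, , drop = FALSE], k_floor)
    wide <- m$points
    res <- m$result
    for (j in seq_len(nrow(wide))) {
      lab <- gsub("\\.", "_", format(wide$delay_diff[j]))
      res[[paste0("theta_", lab)]] <- wide$theta[j]
      res[[paste0("clipped_", lab)]] <- wide$clipped[j]
      res[[paste0("n_", lab)]] <- wide$n_trials[j]
    }
    res
  })
  dplyr::bind_rows(rows)
}
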