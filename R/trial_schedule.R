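#' Configuration of the trial generator
#'
#' Describes the statistical contingencies of the avatar task: the support of
#' the distance difference between the LL and SS coins (in grid squares), the
#' support of the SS coin's own distance, the reward-difference support (in
#' abstract reward units; one unit corresponds to the smallest 0.005 EUR
#' coin), the avatar speed, and the target fraction of trials on which the
#' LL option is objectively optimal.
#'
#' Rewards are integer units on 1..\code{max_reward_units}; the SS reward is
#' drawn uniformly from \code{1..(max_reward_units - reward_diff)} so the LL
#' coin never exceeds the largest coin.
#'
#' @param distance_diff_support Integer distances (squares) by which the LL
#'   coin is farther than the SS coin. Default \code{c(1, 2, 4, 7)}.
#' @param distance_diff_weights Sampling weights for
#'   \code{distance_diff_support}; default uniform.
#' @param ss_distance_support Possible SS distances in squares; default
#'   \code{2:6}.
#' @param reward_diff_support Reward differences (units) between LL and SS;
#'   default \code{c(1, 3, 5, 7, 9)}.
#' @param reward_diff_weights Sampling weights for
#'   \code{reward_diff_support}; default uniform.
#' @param max_reward_units Largest coin in reward units (default 10, i.e.
#'   0.05 EUR at 0.005 EUR/unit).
#' @param seconds_per_square Avatar travel time per square, seconds
#'   (default 1.3).
#' @param ll_optimal_target_rate Target probability that the LL option has
#'   the strictly higher reward rate (default 0.60).
#' @param euros_per_reward_unit EUR value of one reward unit (default 0.005).
#' @param points_per_eurocent On-screen points per eurocent (default 20).
#' @param seed Integer seed; mandatory for reproducible generation.
#' @return An object of class \code{dd_generator_config}.
#' @examples
#' cfg <- generator_config(seed = 1)
#' trials <- generate_trials(cfg, 5)
#' @export
generator_config <- function(distance_diff_support = c(1L, 2L, 4L, 7L),
                             distance_diff_weights = NULL,
                             ss_distance_support = 2:6,
                             reward_diff_support = c(1L, 3L, 5L, 7L, 9L),
                             reward_diff_weights = NULL,
                             max_reward_units = 10L,
                             seconds_per_square = 1.3,
                             ll_optimal_target_rate = 0.60,
                             euros_per_reward_unit = 0.005,
                             points_per_eurocent = 20L,
                             seed = NULL) {
  if (length(distance_diff_support) < 1L || any(distance_diff_support < 1))
    abort("`distance_diff_support` must be a non-empty set of positive distances.")
  if (length(ss_distance_support) < 1L || any(ss_distance_support < 1))
    abort("`ss_distance_support` must be a non-empty set of positive distances.")
  if (length(reward_diff_support) < 1L || any(reward_diff_support < 1))
    abort("`reward_diff_support` must be a non-empty set of positive reward differences.")
  if (is.null(distance_diff_weights))
    distance_diff_weights <- rep(1, length(distance_diff_support))
  if (is.null(reward_diff_weights))
    reward_diff_weights <- rep(1, length(reward_diff_support))
  for (w in list(distance_diff_weights, reward_diff_weights))
    if (any(w < 0) || sum(w) <= 0)
      abort("sampling weights must be non-negative with positive sum.")
  if (length(distance_diff_weights) != length(distance_diff_support) ||
      length(reward_diff_weights) != length(reward_diff_support))
    abort("weights must match the length of their support.")
  if (seconds_per_square <= 0) abort("`seconds_per_square` must be > 0.")
  if (ll_optimal_target_rate <= 0 || ll_optimal_target_rate >= 1)
    abort("`ll_optimal_target_rate` must lie strictly between 0 and 1.",
          class = "dd_calibration_error")
  if (any(reward_diff_support >= max_reward_units))
    abort("every reward difference must leave room for an SS reward of at least 1 unit.")
  structure(
    list(
      distance_diff_support = as.integer(distance_diff_support),
      distance_diff_weights = distance_diff_weights / sum(distance_diff_weights),
      ss_distance_support = as.integer(ss_distance_support),
      reward_diff_support = as.integer(reward_diff_support),
      reward_diff_weights = reward_diff_weights / sum(reward_diff_weights),
      max_reward_units = as.integer(max_reward_units),
      seconds_per_square = seconds_per_square,
      ll_optimal_target_rate = ll_optimal_target_rate,
      euros_per_reward_unit = euros_per_reward_unit,
      points_per_eurocent = as.integer(points_per_eurocent),
      seed = if (is.null(seed)) NULL else as.integer(seed),
      calibration = NULL
    ),
    class = "dd_generator_config"
  )
}

#' @export
print.dd_generator_config <- function(x, ...) {
  cat("<dd_generator_config>\n")
  cat("  distance diff (squares):", paste(x$distance_diff_support, collapse = ", "), "\n")
  cat("  reward diff (units):    ", paste(x$reward_diff_support, collapse = ", "), "\n")
  cat("  LL-optimal target rate: ", x$ll_optimal_target_rate, "\n")
  cat("  calibrated:             ", !is.null(x$calibration), "\n")
  invisible(x)
}

# Enumerate the atom table: every admissible (dd, dr, d_ss, r_ss, side) cell
# with its exact sampling probability. Branch weights are solved so that the
# (dd, dr) pair marginal equals the configured product weights while the
# LL-optimal rate equals the target exactly; reward-rate ties are excluded
# (the generator guarantees strict optimality).
build_atom_table <- function(config) {
  q <- config$ll_optimal_target_rate
  pairs <- expand.grid(dd = config$distance_diff_support,
                       dr = config$reward_diff_support,
                       KEEP.OUT.ATTRS = FALSE)
  m <- as.vector(outer(config$distance_diff_weights, config$reward_diff_weights))
  npair <- nrow(pairs)
  cells_ll <- cells_ss <- vector("list", npair)
  n_ll <- n_ss <- integer(npair)
  for (i in seq_len(npair)) {
    dd <- pairs$dd[i]; dr <- pairs$dr[i]
    r_max <- config$max_reward_units - dr
    cells <- expand.grid(d_ss = config$ss_distance_support, r_ss = seq_len(r_max),
                         KEEP.OUT.ATTRS = FALSE)
    # LL-optimal iff r_ll/t_ll > r_ss/t_ss iff (r_ss+dr)*d_ss > r_ss*(d_ss+dd)
    cross <- (cells$r_ss + dr) * cells$d_ss - cells$r_ss * (cells$d_ss + dd)
    cells_ll[[i]] <- cells[cross > 0, , drop = FALSE]
    cells_ss[[i]] <- cells[cross < 0, , drop = FALSE]
    n_ll[i] <- nrow(cells_ll[[i]]); n_ss[i] <- nrow(cells_ss[[i]])
  }
  if (any(bad <- (n_ll == 0 & n_ss == 0 & m > 0)))
    abort(paste0("pairs with no strictly optimal cell: ",
                 paste(sprintf("(dd=%d, dr=%d)", pairs$dd[bad], pairs$dr[bad]),
                       collapse = ", ")),
          class = "dd_calibration_error")
  only_ll <- n_ll > 0 & n_ss == 0
  only_ss <- n_ss > 0 & n_ll == 0
  dual <- n_ll > 0 & n_ss > 0
  m_oll <- sum(m[only_ll]); m_oss <- sum(m[only_ss]); m_dual <- sum(m[dual])
  if (m_oll > q + 1e-12)
    abort(sprintf(paste0("target LL-optimal rate %.3f unreachable: pairs that can only be ",
                         "LL-optimal carry probability mass %.3f > target."), q, m_oll),
          class = "dd_calibration_error")
  if (m_oss > (1 - q) + 1e-12)
    abort(sprintf(paste0("target LL-optimal rate %.3f unreachable: pairs that can only be ",
                         "SS-optimal carry probability mass %.3f > 1 - target."), q, m_oss),
          class = "dd_calibration_error")
  # pair weight inside each label branch: q*w_ll + (1-q)*w_ss = m per pair
  lambda <- if (m_dual > 0) (1 - m_oss / (1 - q)) / m_dual else 0
  w_ss <- ifelse(only_ss, m / (1 - q), ifelse(dual, lambda * m, 0))
  w_ll <- ifelse(only_ll, m / q, ifelse(dual, m * (1 - (1 - q) * lambda) / q, 0))
  if (any(w_ll < -1e-12) || any(w_ss < -1e-12))
    abort("target LL-optimal rate unreachable under the configured pair weights.",
          class = "dd_calibration_error")
  rows <- vector("list", 2L * npair)
  for (i in seq_len(npair)) {
    if (w_ll[i] > 0 && n_ll[i] > 0)
      rows[[2L * i - 1L]] <- cbind(cells_ll[[i]], dd = pairs$dd[i], dr = pairs$dr[i],
                                   optimal_side = "LL",
                                   prob = q * w_ll[i] / n_ll[i])
    if (w_ss[i] > 0 && n_ss[i] > 0)
      rows[[2L * i]] <- cbind(cells_ss[[i]], dd = pairs$dd[i], dr = pairs$dr[i],
                              optimal_side = "SS",
                              prob = (1 - q) * w_ss[i] / n_ss[i])
  }
  atoms <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(atoms) <- NULL
  as_tibble(atoms)
}

#' Calibrate the trial generator to its target LL-optimal rate
#'
#' Solves, in closed form, per-(distance-difference, reward-difference) pair
#' sampling weights such that trials hit the configured LL-optimal rate
#' exactly while the pair marginals keep their configured weights, then runs
#' a pilot simulation to verify the empirical rate.
#'
#' @param config A \code{\link{generator_config}}.
#' @param tol Allowed absolute deviation of the pilot LL-optimal fraction
#'   from the target (default 0.02).
#' @param pilot_n Number of pilot trials (default 20000); set to 0 to skip
#'   the pilot check.
#' @return The config with calibration tables attached.
#' @export
calibrate_generator <- function(config, tol = 0.02, pilot_n = 20000L) {
  stopifnot(inherits(config, "dd_generator_config"))
  if (tol <= 0) abort("`tol` must be > 0.")
  config$calibration <- list(atoms = build_atom_table(config))
  if (pilot_n > 0) {
    seed <- if (is.null(config$seed)) 104729L else config$seed
    pilot <- generate_trials(config, pilot_n, seed = seed)
    rate <- mean(pilot$optimal_side == "LL")
    if (abs(rate - config$ll_optimal_target_rate) > tol)
      abort(sprintf("pilot LL-optimal fraction %.4f misses target %.3f by more than tol %.3f",
                    rate, config$ll_optimal_target_rate, tol),
            class = "dd_calibration_error")
    config$calibration$pilot_rate <- rate
  }
  config
}

#' Generate task trials
#'
#' Draws independent trials from the calibrated design: a smaller-sooner coin
#' at distance \code{d_ss} worth \code{r_ss} units and a larger-later coin at
#' \code{d_ll > d_ss} worth \code{r_ll > r_ss} units, with delays
#' \code{t = d * seconds_per_square} and a strict objectively optimal side.
#'
#' @param config A \code{\link{generator_config}} (calibrated on the fly if
#'   needed).
#' @param n Number of trials.
#' @param seed Seed; defaults to the config seed, which must then be set.
#' @return A tibble with columns \code{trial_id, d_ss, d_ll, r_ss, r_ll,
#'   t_ss, t_ll, optimal_side}.
#' @export
generate_trials <- function(config, n, seed = config$seed) {
  stopifnot(inherits(config, "dd_generator_config"))
  if (n < 0) abort("`n` must be >= 0.")
  if (is.null(seed)) abort("a seed is required (set it in the config or pass `seed`).")
  if (is.null(config$calibration)) config$calibration <- list(atoms = build_atom_table(config))
  atoms <- config$calibration$atoms
  n <- as.integer(n)
  empty <- tibble(trial_id = integer(), d_ss = integer(), d_ll = integer(),
                  r_ss = integer(), r_ll = integer(), t_ss = numeric(),
                  t_ll = numeric(), optimal_side = character())
  if (n == 0L) return(empty)
  idx <- with_seed(seed, sample.int(nrow(atoms), n, replace = TRUE, prob = atoms$prob))
  sps <- config$seconds_per_square
  d_ss <- atoms$d_ss[idx]; d_ll <- d_ss + atoms$dd[idx]
  r_ss <- atoms$r_ss[idx]; r_ll <- r_ss + atoms$dr[idx]
  tibble(trial_id = seq_len(n),
         d_ss = as.integer(d_ss), d_ll = as.integer(d_ll),
         r_ss = as.integer(r_ss), r_ll = as.integer(r_ll),
         t_ss = d_ss * sps, t_ll = d_ll * sps,
         optimal_side = atoms$optimal_side[idx])
}

#' Label the objectively optimal side of trials
#'
#' The optimal option is the one with the strictly greater reward rate
#' (reward magnitude divided by the avatar's travel time to it). The
#' comparison is done on the cross products \code{r_ll * t_ss} vs
#' \code{r_ss * t_ll}; equal rates (to a relative tolerance of 1e-9, which
#' absorbs floating-point noise in delays derived as distance times speed)
#' are reported as \code{"tie"}.
#'
#' @param trials A data frame with columns \code{r_ss, t_ss, r_ll, t_ll}.
#' @return Character vector: \code{"SS"}, \code{"LL"}, or \code{"tie"}.
#' @examples
#' label_optimal(data.frame(r_ss = 2, t_ss = 2.6, r_ll = 8, t_ll = 5.2))
#' @export
label_optimal <- function(trials) {
  need <- c("r_ss", "t_ss", "r_ll", "t_ll")
  if (!all(need %in% names(trials)))
    abort(paste("`trials` must have columns", paste(need, collapse = ", ")))
  with(trials, {
    if (any(r_ss <= 0 | r_ll <= 0 | t_ss <= 0 | t_ll <= 0))
      abort("invalid trial: rewards and delays must be positive.",
            class = "dd_invalid_trial")
    cross <- r_ll * t_ss - r_ss * t_ll
    tol <- 1e-9 * (r_ll * t_ss + r_ss * t_ll)
    ifelse(abs(cross) <= tol, "tie", ifelse(cross > 0, "LL", "SS"))
  })
}

#' Summarise the design statistics of a trial schedule
#'
#' @param trials A tibble from \code{\link{generate_trials}} (or a read
#'   schedule with the same columns).
#' @return A one-row tibble: n, mean/SD of the delay difference (s), mean/SD
#'   of the reward difference (units), LL-optimal fraction, and its odds.
#'   SD fields are \code{NA} (flagged by \code{sd_defined = FALSE}) with
#'   fewer than two trials.
#' @export
schedule_summary <- function(trials) {
  n <- nrow(trials)
  if (n == 0L) abort("empty trial schedule.")
  ddiff <- trials$t_ll - trials$t_ss
  rdiff <- trials$r_ll - trials$r_ss
  side <- if ("optimal_side" %in% names(trials)) trials$optimal_side else label_optimal(trials)
  frac <- mean(side == "LL")
  tibble(
    n_trials = n,
    delay_diff_mean = mean(ddiff),
    delay_diff_sd = if (n >= 2) sd(ddiff) else NA_real_,
    reward_diff_mean = mean(rdiff),
    reward_diff_sd = if (n >= 2) sd(rdiff) else NA_real_,
    ll_optimal_frac = frac,
    ll_optimal_odds = frac / (1 - frac),
    sd_defined = n >= 2
  )
}
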