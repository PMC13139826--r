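#' Generative parameters of a simulated participant
#'
#' An agent discounts the larger-later reward hyperbolically over the extra
#' waiting time it imposes (the delay difference; the smaller-sooner receipt
#' is the temporal reference point), chooses by a softmax over the subjective
#' value difference with an additive smaller-sooner bias, and produces
#' lognormal reaction times clamped to the task's valid range.
#'
#' @param k Hyperbolic discount rate, 1/s; \code{k >= 0}.
#' @param tau Choice sensitivity (inverse temperature), 1/reward-unit;
#'   \code{tau >= 0}.
#' @param ss_bias Additive preference for the SS option on the value scale,
#'   reward units. Positive values favour SS.
#' @param rt_meanlog,rt_sdlog Log-scale parameters of the reaction-time
#'   model, seconds; samples are clamped to [0.3, 15] s so the task's
#'   reaction-time exclusion filter removes nothing.
#' @param subject_id Identifier.
#' @param group Group label, \code{"HC"} or \code{"AN"}.
#' @return An object of class \code{dd_agent}.
#' @examples
#' a <- agent_params(k = 0.1, tau = 2)
#' @export
agent_params <- function(k, tau, ss_bias = 0,
                         rt_meanlog = log(1.4), rt_sdlog = 0.35,
                         subject_id = "agent", group = c("HC", "AN")) {
  group <- match.arg(group)
  if (k < 0) abort("`k` must be >= 0.")
  if (tau < 0) abort("`tau` must be >= 0.")
  if (rt_sdlog < 0) abort("`rt_sdlog` must be >= 0.")
  structure(list(k = k, tau = tau, ss_bias = ss_bias,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
                 subject_id = subject_id, group = group),
            class = "dd_agent")
}

#' Hyperbolic subjective value
#'
#' \code{V = amount / (1 + k * delay)}.
#'
#' @param amount Reward magnitude (units), \code{>= 0}.
#' @param delay Delay in seconds, \code{>= 0}.
#' @param k Discount rate, 1/s, \code{>= 0}.
#' @return Subjective value in reward units.
#' @examples
#' subjective_value(10, 5, 0.1) # 10 / 1.5
#' @export
subjective_value <- function(amount, delay, k) {
  if (any(amount < 0) || any(delay < 0) || any(k < 0))
    abort("`amount`, `delay` and `k` must all be non-negative.")
  amount / (1 + k * delay)
}

#' Probability that an agent chooses the larger-later option
#'
#' \code{P(LL) = logistic(tau * (V_LL - V_SS - ss_bias))}, where
#' \code{V_LL = subjective_value(r_ll, t_ll - t_ss, k)} (the LL reward
#' discounted over the extra wait) and \code{V_SS = r_ss} (the reference).
#'
#' @param trials Data frame with columns \code{r_ss, r_ll, t_ss, t_ll}.
#' @param agent A \code{\link{agent_params}} object.
#' @return Numeric vector of LL-choice probabilities in [0, 1].
#' @export
choice_probability <- function(trials, agent) {
  stopifnot(inherits(agent, "dd_agent"))
  v_ll <- subjective_value(trials$r_ll, trials$t_ll - trials$t_ss, agent$k)
  v_ss <- subjective_value(trials$r_ss, 0, agent$k)
  plogis(agent$tau * (v_ll - v_ss - agent$ss_bias))
}

rt_sample <- function(agent, n) {
  pmin(pmax(rlnorm(n, agent$rt_meanlog, agent$rt_sdlog), 0.3), 15)
}

#' Simulate one timed session of the avatar task
#'
#' Trials are drawn sequentially from the calibrated generator. A new trial
#' starts only while the block's elapsed time is below \code{block_duration};
#' a trial in flight at the deadline runs to completion and scores. Each
#' trial lasts \code{rt + chosen distance * seconds_per_square +
#' feedback_duration} seconds and the chosen reward is added to a cumulative
#' loot.
#'
#' @param agent A \code{\link{agent_params}} object.
#' @param config A calibrated \code{\link{generator_config}}.
#' @param seed Integer seed for this session.
#' @param n_blocks Number of blocks (default 3).
#' @param block_duration Block length in seconds (default 480, i.e. 8 min).
#' @param feedback_duration Post-collection feedback time, seconds
#'   (default 0.8).
#' @return A tibble (one row per completed trial) with the trial fields plus
#'   \code{subject_id, group, block, choice, rt, trial_duration,
#'   t_elapsed_at_start, loot_after}. Attributes \code{total_points} and
#'   \code{total_euros} carry the session payout.
#' @export
simulate_session <- function(agent, config, seed,
                             n_blocks = 3L, block_duration = 480,
                             feedback_duration = 0.8) {
  stopifnot(inherits(agent, "dd_agent"), inherits(config, "dd_generator_config"))
  if (is.null(config$calibration))
    config$calibration <- list(atoms = build_atom_table(config))
  seeds <- derive_seeds(seed, n_blocks + 1L)
  sps <- config$seconds_per_square
  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    recs <- NULL
    elapsed <- 0
    chunk <- 64L
    sub <- derive_seeds(seeds[b], 1000L)
    draw <- 0L
    while (elapsed < block_duration) {
      draw <- draw + 1L
      trials <- generate_trials(config, chunk, seed = sub[draw])
      piece <- with_seed(sub[draw + 500L], {
        p_ll <- choice_probability(trials, agent)
        ll <- rbinom(chunk, 1L, p_ll) == 1L
        rt <- rt_sample(agent, chunk)
        dist <- ifelse(ll, trials$d_ll, trials$d_ss)
        out <- trials
        out$choice <- ifelse(ll, "LL", "SS")
        out$rt <- rt
        out$reward <- ifelse(ll, trials$r_ll, trials$r_ss)
        out$trial_duration <- rt + dist * sps + feedback_duration
        out
      })
      piece$t_elapsed_at_start <- elapsed + cumsum(c(0, piece$trial_duration[-chunk]))
      keep <- piece$t_elapsed_at_start < block_duration
      recs <- rbind(recs, piece[keep, , drop = FALSE])
      if (!all(keep)) break
      elapsed <- piece$t_elapsed_at_start[chunk] + piece$trial_duration[chunk]
      if (draw >= 400L) abort("session simulation failed to exhaust the block budget.")
    }
    if (!is.null(recs) && nrow(recs) > 0L) {
      recs$block <- b
      blocks[[b]] <- recs
    }
  }
  out <- do.call(rbind, blocks[!vapply(blocks, is.null, logical(1))])
  if (is.null(out)) {
    out <- tibble(trial_id = integer(), d_ss = integer(), d_ll = integer(),
                  r_ss = integer(), r_ll = integer(), t_ss = numeric(),
                  t_ll = numeric(), optimal_side = character(),
                  choice = character(), rt = numeric(), reward = integer(),
                  trial_duration = numeric(), t_elapsed_at_start = numeric(),
                  block = integer())
  }
  out$trial_id <- seq_len(nrow(out))
  out$loot_after <- cumsum(out$reward)
  out$subject_id <- agent$subject_id
  out$group <- agent$group
  out <- out[, c("subject_id", "group", "block", "trial_id",
                 "d_ss", "d_ll", "r_ss", "r_ll", "t_ss", "t_ll",
                 "optimal_side", "choice", "rt", "trial_duration",
                 "t_elapsed_at_start", "loot_after")]
  points_per_unit <- config$euros_per_reward_unit * 100 * config$points_per_eurocent
  total_points <- if (nrow(out)) out$loot_after[nrow(out)] * points_per_unit else 0
  attr(out, "total_points") <- total_points
  attr(out, "total_euros") <- total_points / (config$points_per_eurocent * 100)
  out
}

#' Specification of a synthetic two-group cohort
#'
#' Defaults emulate the study sample: two groups of 80 female participants
#' (healthy controls, HC, and acutely underweight patients, AN) aged 12-26,
#' with clinical covariates drawn from the published group summaries
#' (BMI-SDS, BDI-II, EDI-2 total). Agents share the same discounting (k) and
#' sensitivity (tau) distributions across groups; the AN group additionally
#' receives a positive SS bias whose magnitude increases with depressive
#' symptoms and decreases with BMI-SDS. Effect magnitudes are design choices
#' of the simulator, not published estimates.
#'
#' @param n_per_group Participants per group (default 80).
#' @param k_meanlog,k_sdlog Lognormal parameters of the discount rate
#'   (defaults log(0.15), 0.5; 1/s).
#' @param tau_meanlog,tau_sdlog Lognormal parameters of choice sensitivity
#'   (defaults log(1.75), 0.3).
#' @param an_ss_bias_mean,an_ss_bias_sd Mean and residual SD of the AN
#'   group's SS bias (reward units; defaults 0.15 and 0.08). HC bias is 0.
#' @param an_bias_bmi_beta,an_bias_bdi_beta Standardised links from BMI-SDS
#'   (negative) and BDI-II (positive) to the AN SS bias (defaults -0.15 and
#'   0.15 units per SD).
#' @param covariates Per-group list of covariate means/SDs and truncation
#'   ranges; see defaults in the source.
#' @param seed Integer seed.
#' @return An object of class \code{dd_cohort_spec}.
#' @export
cohort_spec <- function(n_per_group = 80L,
                        k_meanlog = log(0.15), k_sdlog = 0.5,
                        tau_meanlog = log(1.75), tau_sdlog = 0.3,
                        an_ss_bias_mean = 0.15, an_ss_bias_sd = 0.08,
                        an_bias_bmi_beta = -0.15, an_bias_bdi_beta = 0.15,
                        covariates = NULL, seed = NULL) {
  if (n_per_group < 0) abort("`n_per_group` must be >= 0.")
  if (is.null(covariates)) {
    covariates <- list(
      HC = list(age = c(16.27, 2.51), bmi_sds = c(0.05, 0.64),
                bdi = c(4.57, 5.05), edi = c(132.81, 25.35)),
      AN = list(age = c(16.26, 2.48), bmi_sds = c(-3.24, 1.07),
                bdi = c(26.29, 10.61), edi = c(221.92, 44.18))
    )
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 k_meanlog = k_meanlog, k_sdlog = k_sdlog,
                 tau_meanlog = tau_meanlog, tau_sdlog = tau_sdlog,
                 an_ss_bias_mean = an_ss_bias_mean, an_ss_bias_sd = an_ss_bias_sd,
                 an_bias_bmi_beta = an_bias_bmi_beta,
                 an_bias_bdi_beta = an_bias_bdi_beta,
                 covariates = covariates,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "dd_cohort_spec")
}

rnorm_trunc <- function(n, mean, sd, lower, upper, seed_done = TRUE) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  tries <- 0L
  while (length(bad) > 0L && tries < 1000L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
    tries <- tries + 1L
  }
  pmin(pmax(x, lower), upper)
}

#' Simulate a synthetic cohort with session logs
#'
#' Draws per-subject covariates and generative parameters according to the
#' cohort specification, then plays a full timed session for every subject.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param config A calibrated \code{\link{generator_config}}.
#' @param seed Seed; defaults to the spec seed, which must then be set.
#' @param ... Passed on to \code{\link{simulate_session}} (e.g. block
#'   timing).
#' @return A list with \code{cohort} (one row per subject: id, group,
#'   covariates, true generative parameters) and \code{logs} (all session
#'   records bound together).
#' @export
simulate_cohort <- function(spec, config, seed = spec$seed, ...) {
  stopifnot(inherits(spec, "dd_cohort_spec"), inherits(config, "dd_generator_config"))
  if (is.null(seed)) abort("a seed is required (set it in the spec or pass `seed`).")
  if (is.null(config$calibration))
    config$calibration <- list(atoms = build_atom_table(config))
  n <- spec$n_per_group
  empty_cohort <- tibble(subject_id = character(), group = character(),
                         age = numeric(), bmi_sds = numeric(), bdi = numeric(),
                         edi = numeric(), true_k = numeric(), true_tau = numeric(),
                         true_ss_bias = numeric())
  if (n == 0L) return(list(cohort = empty_cohort, logs = NULL))
  seeds <- derive_seeds(seed, 2L * n + 1L)
  cohort <- with_seed(seeds[1L], {
    rows <- lapply(c("HC", "AN"), function(g) {
      cv <- spec$covariates[[g]]
      age <- rnorm_trunc(n, cv$age[1], cv$age[2], 12, 26)
      bmi <- rnorm_trunc(n, cv$bmi_sds[1], cv$bmi_sds[2],
                         cv$bmi_sds[1] - 3 * cv$bmi_sds[2],
                         cv$bmi_sds[1] + 3 * cv$bmi_sds[2])
      bdi <- rnorm_trunc(n, cv$bdi[1], cv$bdi[2], 0, 63)
      edi <- rnorm_trunc(n, cv$edi[1], cv$edi[2], 64, 384)
      k <- rlnorm(n, spec$k_meanlog, spec$k_sdlog)
      tau <- rlnorm(n, spec$tau_meanlog, spec$tau_sdlog)
      bias <- if (g == "AN") {
        pmax(0, spec$an_ss_bias_mean +
                  spec$an_bias_bmi_beta * (bmi - cv$bmi_sds[1]) / cv$bmi_sds[2] +
                  spec$an_bias_bdi_beta * (bdi - cv$bdi[1]) / cv$bdi[2] +
                  rnorm(n, 0, spec$an_ss_bias_sd))
      } else rep(0, n)
      tibble(subject_id = sprintf("%s%03d", g, seq_len(n)), group = g,
             age = age, bmi_sds = bmi, bdi = bdi, edi = edi,
             true_k = k, true_tau = tau, true_ss_bias = bias)
    })
    do.call(rbind, rows)
  })
  logs <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    ag <- agent_params(k = cohort$true_k[i], tau = cohort$true_tau[i],
                       ss_bias = cohort$true_ss_bias[i],
                       subject_id = cohort$subject_id[i],
                       group = cohort$group[i])
    logs[[i]] <- simulate_session(ag, config, seed = seeds[1L + i], ...)
  }
  list(cohort = cohort, logs = do.call(rbind, logs))
}
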