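# Shared fixtures: a calibrated default generator and small hand-built logs.

default_config <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- calibrate_generator(generator_config(seed = 42), pilot_n = 0L)
    cfg
  }
})

# A minimal choice log built by hand: one row per (delay level, value ratio,
# choice) combination requested.
make_log <- function(d_ss, d_ll, r_ss, r_ll, choice, rt = 1, subject_id = "s1",
                     group = "HC", sps = 1.3) {
  n <- max(length(d_ss), length(d_ll), length(r_ss), length(r_ll), length(choice))
  tibble::tibble(
    subject_id = subject_id, group = group, block = 1L, trial_id = seq_len(n),
    d_ss = rep_len(d_ss, n), d_ll = rep_len(d_ll, n),
    r_ss = rep_len(r_ss, n), r_ll = rep_len(r_ll, n),
    t_ss = rep_len(d_ss, n) * sps, t_ll = rep_len(d_ll, n) * sps,
    choice = rep_len(choice, n), rt = rep_len(rt, n),
    trial_duration = rep_len(rt, n) + rep_len(d_ss, n) * sps + 0.8,
    t_elapsed_at_start = cumsum(c(0, rep_len(rt, n)[-n])),
    loot_after = cumsum(ifelse(rep_len(choice, n) == "SS",
                               rep_len(r_ss, n), rep_len(r_ll, n)))
  )
}

# Log of a deterministic responder: chooses SS iff value ratio v exceeds a
# per-level threshold theta(level). Spans the design's delay levels and a
# spread of ratios.
threshold_log <- function(theta_fun, reps = 3L) {
  grid <- expand.grid(dd = c(1L, 2L, 4L, 7L), r_ss = 1:9, dr = c(1L, 3L, 5L, 7L, 9L))
  grid <- grid[grid$r_ss + grid$dr <= 10L, ]
  grid <- grid[rep(seq_len(nrow(grid)), reps), ]
  v <- grid$r_ss / (grid$r_ss + grid$dr)
  choice <- ifelse(v > theta_fun(grid$dd * 1.3), "SS", "LL")
  make_log(d_ss = 3L, d_ll = 3L + grid$dd, r_ss = grid$r_ss,
           r_ll = grid$r_ss + grid$dr, choice = choice)
}

# Simulate a full-length session for one agent with the default config.
quick_session <- function(k, tau, ss_bias = 0, seed = 1, subject_id = "s1",
                          group = "HC", ...) {
  ag <- agent_params(k = k, tau = tau, ss_bias = ss_bias,
                     subject_id = subject_id, group = group)
  simulate_session(ag, default_config(), seed = seed, ...)
}
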