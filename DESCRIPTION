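Package: ddgame
Title: Simulation and Analysis of an Experiential Gamified Delay-Discounting Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for an avatar-based intertemporal-choice paradigm with a
    fixed overall time budget, in which each trial offers a smaller-sooner
    and a larger-later coin and one side is objectively optimal (higher
    reward per second of travel). Provides a calibrated trial generator
    matching the task's design statistics, a generative participant model
    (hyperbolic discounting, softmax choice noise, smaller-sooner bias,
    lognormal reaction times) that plays timed sessions, per-subject
    discounting estimation (indifference points, hyperbolic k, area under
    the curve, choice proportions), signal-detection decomposition of
    optimality (d-prime and beta), and the group-level statistics used to
    compare a patient cohort with matched controls (Welch t-tests from
    summaries, binomial and Gaussian models with an age covariate, FDR
    correction, noncentral-t power, optimal pairwise age matching).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
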