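---
title: "Modelling an experiential gamified delay-discounting task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling an experiential gamified delay-discounting task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddgame)
```

## The task and why optimality is well defined

In the paradigm this package models, a participant repeatedly chooses
between two coins on a grid: a smaller coin close to the avatar
(smaller-sooner, SS) and a larger coin farther away (larger-later, LL).
After the choice, the avatar travels autonomously at 1.3 s per square, so a
coin `d` squares away is received after `t = 1.3 * d` seconds, and its value
is added to a cumulative loot. The session, not the number of trials, is
time-limited (three blocks of 8 minutes), so waiting for a distant coin has
a real opportunity cost: it delays every subsequent decision. Because total
time is the fixed budget, each trial has an objectively optimal option — the
one with the higher reward per second of travel — and the design keeps both
SS-optimal and LL-optimal trials frequent (40% / 60%).

This structure lets the analysis separate three things that ordinary
intertemporal-choice tasks confound: the discounting rate (how fast
subjective value falls with delay), a response bias (a preference for one
side regardless of value), and choice acuity (how reliably the better option
is identified).

## The trial generator and its calibration

A trial is parameterised by the SS distance `d_ss` (squares), the distance
difference `dd = d_ll - d_ss`, the SS reward `r_ss` (integer units, one
unit = 0.005 EUR, largest coin 10 units), and the reward difference
`dr = r_ll - r_ss`. Defaults:

* `dd` uniform on {1, 2, 4, 7}: delay differences of 1.3–9.1 s with mean
  4.55 s and SD 2.98 s;
* `dr` uniform on {1, 3, 5, 7, 9}: mean 5.0 units, SD 2.83 units;
* `d_ss` uniform on {2..6}; `r_ss` uniform on {1..(10 - dr)};
* target LL-optimal rate 0.60.

Reward differences are expressed in abstract units rather than eurocents: a
printed difference of "5.0 (2.8)" is incompatible with a coin range of
0.5–5 eurocents, so the design treats rewards as integer units 1–10 with a
fixed unit-to-euro mapping that reproduces the coin range.

`calibrate_generator()` makes the LL-optimal rate exact without distorting
the marginals. For every `(dd, dr)` pair it enumerates the `(d_ss, r_ss)`
cells in which LL (or SS) is strictly rate-optimal — LL is optimal iff
`(r_ss + dr) * d_ss > r_ss * (d_ss + dd)` — and then solves, in closed
form, per-pair sampling weights for the two label branches such that

* the marginal probability of each `(dd, dr)` pair equals its configured
  weight, and
* the probability of an LL-optimal label is exactly the target.

Sampling is then a single categorical draw over this "atom table", which
makes generation fast, exactly reproducible, and tie-free by construction.
An iterative pilot adjustment is unnecessary (the achieved rate is exact up
to Monte-Carlo error); a pilot run is retained as a verification step. The
target is infeasible when the probability mass of pairs that can only ever
produce one label exceeds that label's share; this is reported as a
calibration error with the offending mass (for example, a reward difference
of 9 units leaves no room for an SS-optimal region).

```{r generator}
cfg <- calibrate_generator(generator_config(seed = 1))
schedule_summary(generate_trials(cfg, 20000))
```

## The generative agent

Each simulated participant is a hyperbolic discounter with softmax choice
noise and an additive SS bias:

* subjective value `V = A / (1 + k * D)` with `k` in 1/s;
* the SS receipt is the temporal reference point: the LL reward is
  discounted over the extra wait `D = t_ll - t_ss`, and the SS reward is
  taken at face value. This convention makes the generative model coherent
  with the estimator, which models indifference points as a function of the
  delay difference;
* `P(choose LL) = logistic(tau * (V_LL - V_SS - ss_bias))`, with `tau` in
  1/reward-unit and `ss_bias` in reward units (positive favours SS);
* reaction times are lognormal (`meanlog = log 1.4`, `sdlog = 0.35`),
  clamped to [0.3, 15] s so the analysis-side reaction-time filter removes
  nothing, as in the study sample;
* a trial lasts `rt + 1.3 * chosen distance + 0.8` s (decision, travel,
  feedback). A new trial starts only while block time < 480 s; a trial in
  flight at the deadline completes and scores.

Defaults were chosen once so that sessions match the study's structure:
with `k ~ lognormal(log 0.15, 0.5)` and `tau ~ lognormal(log 1.75, 0.3)`,
mean trial duration is about 10 s and a full three-block session completes
about 143 trials. The discount rates are per second — an order of magnitude
that is typical for experiential tasks with delays of a few seconds and not
comparable to the per-day or per-week rates of questionnaire tasks.

The synthetic cohort (80 participants per group by default) draws ages and
clinical covariates (BMI-SDS, BDI-II, EDI-2) from the published group
summary statistics, truncated to plausible instrument ranges. Both groups
share the same `k` and `tau` distributions; the patient group receives an
SS bias of 0.15 units on average, increasing with depressive symptoms and
decreasing with BMI-SDS (0.15 units per SD each). These magnitudes are free
parameters of the simulator chosen to reproduce the qualitative pattern of
the clinical findings; they are not published estimates.

## Discounting estimation

Per delay-difference level (1.3, 2.6, 5.2, 9.1 s for generated data;
observed differences rounded to 0.1 s for ingested data), the probability
of choosing SS is fitted as a logistic function of the value ratio
`v = r_ss / r_ll`, and the indifference point `theta` is the ratio at which
the fit crosses 0.5. This is robust to unbalanced ratio sampling and
degrades gracefully: constant responding is clipped (always-LL gives
`theta = 1`, the non-discounter limit; always-SS gives `theta = 0`) and
flagged, as are crossings outside the observed ratio range and levels with
fewer than 4 trials.

The discount rate is the least-squares fit of `theta(D) = 1 / (1 + k D)`
over `k` in [0, 10] /s (log-spaced 2000-point grid plus local refinement,
tolerance 1e-6). `log k` applies a floor of 1e-4 /s so non-discounters stay
finite. AUC is the trapezoid area under the indifference curve with delays
normalised by the largest delay and an anchor at (0, 1) — at zero delay
difference the options differ only in reward, so the normative indifference
ratio is 1.

Parameter recovery holds across the plausible range: for agents with `k`
between 0.02 and 0.3 /s and low choice noise, full-length sessions recover
the generative `k` with median error under 25% and rank correlation above
0.9 (see the test suite).

## Optimality and signal detection

Choices are scored against the rate-optimal side; ties (possible only in
ingested data; the generator excludes them) are dropped and counted. With
LL-optimal trials as signals and choosing LL as a "yes", hits and false
alarms give `d' = z(H) - z(F)` and the likelihood-ratio criterion
`beta = exp((z_F^2 - z_H^2) / 2)`; rates of exactly 0 or 1 are replaced by
`1/(2N)` or `1 - 1/(2N)` for that class. The criterion location
`c = -(z_H + z_F)/2` is emitted alongside, since reported SDT analyses do
not always state which bias index they used.

Under this convention `beta > 1` is a conservative criterion — responses
pushed toward SS — and `beta < 1` a liberal one. An additive SS bias
therefore *raises* beta while leaving `d'` essentially unchanged (shift
below 10% at a matched `tau`); this dissociation is what lets the analysis
distinguish a side preference from better discrimination. Note that
unbiased *value-maximising* agents do not sit at `beta = 1`: their decision
variable is subjective value, not optimality evidence, so their hit and
false-alarm rates are asymmetric (typically liberal toward LL). `beta = 1`
is recovered exactly for policies whose noise is symmetric with respect to
the optimality classes, and the test suite checks it in that setting.

A useful consequence of the design, verified by simulation: a patient
value-maximiser (`tau` large, `k = 0`, no bias) always takes the larger
reward and is therefore *suboptimal* on the 40% of trials where SS pays
better per second. Value maximisation and rate maximisation genuinely
dissociate here.

## Group-level statistics

`run_pipeline()` reproduces the study's analysis chain on a synthetic (or
ingested) cohort: reaction-time filtering, per-subject discounting and
SDT measures, then

* binomial logistic models on per-subject success/total counts (SS
  choices, optimal choices, and the two conditional proportions) with age
  as a covariate, reporting odds ratios with Wald intervals. Counts are
  aggregated per subject rather than modelled per trial, avoiding
  unmodelled within-subject correlation in the likelihood; note that
  between-subject heterogeneity still makes these tests anticonservative,
  a property shared with the corresponding published analysis choice;
* Gaussian linear models with age for AUC, log k, d' and beta;
* Benjamini-Hochberg adjustment across the co-reported outcomes of one
  run (the FDR family);
* within-patient covariate associations of SS-choice measures with
  BMI-SDS, BDI-II and EDI-2.

`welch_t()` works from published summary statistics (mean, SD, n) with
Welch-Satterthwaite degrees of freedom. `power_two_sample()` uses the
noncentral-t distribution; one-sided alpha = 0.05 is the default because it
is the only setting consistent with all three published power figures (93%,
60%, 35% for d = 0.5, 0.3, 0.2 at n = 80 per group). `match_pairs()`
solves the case-control age-matching assignment problem exactly: because
the cost is an absolute difference of scalars, the optimal assignment is
order-preserving after sorting, and a dynamic program over the sorted lists
minimises the total within-pair age difference.

```{r inference}
welch_t(summary_stats(20.89, 2.10, 80), summary_stats(14.66, 1.42, 80))
round(c(d_0.5 = power_two_sample(0.5, 80), d_0.3 = power_two_sample(0.3, 80),
        d_0.2 = power_two_sample(0.2, 80)), 3)
```

## Numerical choices and degenerate inputs

* Reward-rate comparisons use cross products with a relative tolerance of
  1e-9, absorbing floating-point noise in delays derived as distance times
  speed; exact ties are flagged, never silently resolved.
* Logistic fits for indifference points tolerate separation (the crossing
  remains defined); a non-monotone fitted psychometric function falls back
  to the empirical midpoint between the ratios favouring each side, and is
  flagged.
* `k = 0` is a valid boundary solution (flat indifference curve); the grid
  search includes it explicitly.
* The binomial group model reports complete separation as an error rather
  than returning a divergent estimate; a constant age covariate is dropped
  with a warning.
* All randomness flows from named integer seeds; cohorts, sessions and
  pipelines are bit-reproducible given (config, seed).

## What the simulator does and does not show

The generator reproduces the task's *design statistics* (delay and reward
difference moments, the 60% LL-optimal rate, session length) and the agent
reproduces the *qualitative* clinical pattern when given an SS bias: more
SS choices overall and when SS is optimal, stronger in simulated patients
with lower BMI-SDS and higher depression scores. The published effect
magnitudes (13%/7%/23% odds differences) depend on the unavailable
participant data and are deliberately not targeted.

Two qualifications are worth stating plainly. First, an additive SS bias
necessarily also lowers LL choices on LL-optimal trials and shifts beta;
in the published data both of those contrasts were null. With the
trial-aggregated binomial tests, those "nulls" cannot hold at the type-I
error level under any bias large enough to reproduce the SS-choice effect —
the published nulls most plausibly reflect subject-level power, which a
single simulated mechanism cannot replicate exactly. The test suite
therefore checks replicate-averaged *directions* of the injected effects
and near-zero effects for discriminability and discounting, not the full
significance pattern. Second, simulated participants do not learn, fatigue,
or adapt within a session, and reaction times carry no information about
choice difficulty; none of the analyses here depend on those features.

Problem sizes used in the checked examples — 100,000 trials for design
statistics, 160 full sessions for session length, six replicate cohorts of
40 per group for the direction checks — were chosen as the smallest sizes
at which Monte-Carlo error is negligible relative to the tolerances tested.
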