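---
title: "Modelling patch-leaving decisions in probabilistic foraging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling patch-leaving decisions in probabilistic foraging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foragehazard)
library(dplyr)
```

## The task and its generative model

A forager shuttles between two reward ports. A *trial* is one visit to a
port (entry to exit of its region of interest, ROI); each nose-poke inside
the port is rewarded probabilistically. Reward probability is reset at
trial start and decays exponentially with poke number at a shared rate but
one of three initial amplitudes (patch qualities), drawn uniformly and
never cued:

$$P(o_n = 1 \mid t_i) = A_i \, e^{-(n-1)/\tau}, \qquad
A = (0.5,\ 0.75,\ 1),\ \tau = 5,$$

with the probability forced to zero after the 20th poke and during *error
trials* (returns to the same port instead of alternating). These constants
live in `reward_schedule()` and are the package's defaults throughout.

Because the patch type is latent, an ideal observer tracks a posterior
over the three types from the outcome history and derives the *subjective
next-reward probability*

$$P(o_{n+1}=1 \mid o_1,\dots,o_n) = \sum_{i=1}^3
P(o_{n+1}=1 \mid t_i)\, P(t_i \mid o_1,\dots,o_n),$$

implemented in `posterior_over_types()` and `next_reward_probability()`.
We fold the 20-poke truncation into the per-poke likelihood, so a history
longer than the cap is rejected rather than silently renormalized. Error
trials are excluded from all model fitting, consistent with the task
setting their reward probability to zero.

## The leaving model

The core model is a discrete-time proportional-hazards model of the
decision to leave the patch. Leaving decisions are taken only after
*omissions* (unrewarded pokes). The hazard after the $n$-th consecutive
omission since the last reward is a baseline $\lambda_0(n)$, scaled on the
odds scale by covariates:

$$\frac{\lambda(n)}{1-\lambda(n)} = e^{\beta x}\,
\frac{\lambda_0(n)}{1-\lambda_0(n)},$$

where $x$ contains the photostimulation indicator, the port side, and the
position of the previous reward. Rewards *reset* the count $n$; each trial
therefore decomposes into reward-bracketed *runs* of omissions
(`segment_runs()`), with runs ending in a reward censored and the final
run ending in the observed leave. In discrete time this is exactly a
logistic regression of the per-omission leave indicator on a one-hot
baseline over $n$ plus the scalar covariates, which is how `fit_ph()`
estimates it (`stats::glm`, binomial family, log-likelihood tolerance
`1e-10`).

Numerical conventions, all chosen where the model itself is silent:

- **Baseline binning.** The top bin pools all positions from the first
  $n$ with fewer than 5 observations upward (widened downward until the
  pool holds at least 5). An explicit `n_cap` overrides the rule.
- **Separation.** All-leave or all-stay bins are legitimate in small
  samples; fitted baseline probabilities are clamped to
  $[10^{-6}, 1-10^{-6}]$ with a warning rather than failing.
- **Covariates without variation** (e.g. photostimulation in a control
  animal fit) are dropped with a message and reported as `NA`.
- **Cap censoring.** Simulated trials end mechanically at the 20-poke
  cap. A trial-final omission at the cap ends the trial whichever way the
  stay/leave draw went, so that decision is unobservable and its
  likelihood contribution is 1; `build_observations()` therefore censors
  (drops) that single row by default. Scoring it as a leave instead
  produces a small but systematic upward distortion of the high-$n$
  baseline, visible in fit–simulate–refit experiments.
- **`last_reward_position`** enters linearly on the log-odds scale as a
  poke index (0 before the first reward), unstandardized. Elapsed time
  would be an alternative scale; the poke index is the one the rest of
  the package uses for positions.
- **Trials whose final poke was rewarded** yield stay rows but no leave
  event (terminal `leave_after_reward`); the model defines decisions only
  after omissions, so these trials are censored rather than events.

The alternative model is the stochastic form of the marginal value
theorem's prediction (`fit_mvt_logistic()`): the leave odds are
$e^{\beta_0 + \beta_1 P_{\text{rew}}(n+1) + \beta_2 s}$ with no resetting
— the subjective next-reward probability is the sole dynamic driver.
`compare_models()` fits both per subject on the odd-indexed trials and
scores mean held-out log-likelihood per observation on the even-indexed
trials. The odd/even split is deterministic so results are reproducible
without an extra random stream; the comparison criterion (held-out mean
log-likelihood) penalizes the hazard model's larger parameter count
naturally. The signature behavioral contrast between the two model
classes is the *win-stay curve* (`win_stay_curve()`): under resetting,
the probability of poking again after a reward is flat in the reward's
position (and equals 1 under our omission-only decision convention — the
informative statistic is the positional slope, which is negative for
belief-driven agents because a late lucky reward does not restore a low
belief).

## What the synthetic generator emulates

No mouse data ship with the package, so `simulate_sessions()` generates
complete experiments with the structure the analyses assume: 10 opsin + 6
control subjects, 10 sessions of 60 trials, three equiprobable patch
types, photostimulation on 50% of correct trials, error trials, ~3 s
travel times, and a 10 s post-poke timeout. Defaults mirror the task
constants above; quantities the task does not pin down were fixed once at
values a behavioral scientist would call realistic:

- **Baseline hazard** $\lambda_0(n) = \text{logistic}((n-6)/1.5)$, capped
  at $n = 15$: a rising hazard giving ~10 pokes/trial.
- **Subject heterogeneity.** Each subject shifts the whole baseline by a
  frailty term on the log-odds scale (SD 0.5), and each opsin subject
  draws its stimulation coefficient from $\mathcal N(-0.3, 0.05)$;
  controls are exactly 0. Without real between-subject variability the
  across-mice regressions (simulated vs. source poking, stimulation
  effects, coefficient rank tests) would be exercises in pure noise.
- **Poke timing** follows a duty-cycle construction: each poke occupies a
  log-normal cycle (mean 0.5 s, SD 0.15 s) split into duration and
  preceding inter-poke interval by the omission duty cycle
  ODC $= a - b\,\lambda$ plus Gaussian noise (a = 0.9, b = 0.5,
  SD 0.03, clipped to (0, 1)). This gives the vigor analyses a
  recoverable ground truth in which stimulation affects vigor *only
  through the hazard* — the construction behind the conditional-null
  check below. Real poke timing is of course not generated this way;
  passing these tests shows the estimators work, not that mouse vigor is
  a noisy linear readout.
- **Error trials** occur with probability 0.05, repeat the previous side,
  contain 1–2 always-unrewarded pokes, and are dropped by the standard
  more-than-two-pokes filter, as in the real pipeline.
- **Travel** is log-normal with mean 3.32 s, SD 1.70 s; dwell after the
  last poke is log-normal (mean 3.8 s, SD 2.0 s) and draws beyond 10 s
  flag the trial as a timeout, feeding the travel-analysis exclusions.

Two rule-based agents complement the hazard agent:
`simulate_mvt_agent()` leaves after the first omission whose subjective
next-reward probability falls below a threshold (with per-subject
threshold jitter, SD 0.03, for the same heterogeneity reason), and
`simulate_mvt_logistic_agent()` draws a leave decision after *every* poke
from the MVT-logistic odds — the model equation defines the switch
probability after any poke, rewarded or not, and it is precisely this
non-resetting behavior that separates the two model classes in the
win-stay and model-comparison analyses.

`shuffle_dataset()` implements the null in which fresh potential reward
sequences are paired with trial lengths resampled (with replacement —
the marginal is what matters) from each subject's empirical lengths:
patch-type differences in poking vanish while differences in the leaving
belief appear, the mirror image of near-optimal behavior.

## Preprocessing and statistics

`prepare_sessions()` relabels correct/error by side alternation (first
trial correct by convention — it has no predecessor), truncates each
session to its first 60 trials, and drops trials with fewer than 3 pokes.
Group statistics take subject-level means as units (one-way ANOVA across
subject-by-type means, $F(2, 3S-3)$; Wilcoxon tests for the smaller
stimulation contrasts), never pooled trials. The average reward rate
divides a session's rewards by its full span (first ROI entry to last ROI
exit, travel and error time included); the rate at leaving divides each
trial's leaving belief by its final poke's duration, averaged within then
across subjects.

One caution established during validation: the more-than-two-pokes filter
conditions on the realized trial length and therefore *biases* the
parameters of the decision models when the target is the generative
truth. Model comparison is unaffected (both models face the same data),
and the hazard model's flexible baseline absorbs most of it, but the
recovery checks for the MVT-logistic agent's coefficients are run with
`min_pokes = 1` for this reason.

`mvt_self_consistency()` finds the threshold at which a threshold agent
forages at its own average reward rate, by fixed-point iteration
(threshold ← average rate × mean final-poke duration, 3 iterations, then
evaluation on a fresh seed). At the fixed point the rate at leaving and
the average rate agree to within a few percent — the optimality equality
the marginal value theorem predicts.

## Problem sizes and determinism

All validation runs use cohorts of 16 subjects × 10 sessions × 60 trials
(~60,000 pokes), the study's own scale; Monte-Carlo oracles (geometric
trial lengths, per-poke reward frequencies) use 10,000 trials; the
fit–simulate–refit consistency check uses ~48,000 simulated trials. Every
stochastic routine takes a single integer seed and produces byte-identical
output when rerun; derived seeds are small fixed offsets of it.

## Known limitations

- The hazard and MVT-logistic fits are independent per-subject fits, not
  a hierarchical model; small subjects give noisy coefficients.
- The generator's 20-poke cap on poking is a simulation convenience (the
  task caps only the reward probability); cap censoring in
  `build_observations()` compensates, but analyses of very long trials
  are outside the generator's reach.
- ODC analyses exclude rewarded pokes (consumption inflates duration) and
  the first poke of each trial (no preceding interval); profiles within
  ±5 pokes of the last reward are reported, further positions being
  sparse.
- `simulate_from_fit()` returns trial-level results (lengths, rewards,
  realized outcome strings), not full timed poke logs; the round-trip
  analyses need nothing more.
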