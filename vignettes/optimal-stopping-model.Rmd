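---
title: "An optimal-observer model of the stop-signal task: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An optimal-observer model of the stop-signal task: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopsignal)
```

## The task and the two models

In the stop-signal task a subject discriminates a go stimulus on every
trial (here, a two-alternative choice: left vs. right), but on a minority
of trials an auditory stop signal arrives after a variable delay (the
stop-signal delay, SSD) and instructs the subject to withhold the
response. Behavior is summarized by go reaction times, discrimination and
omission error rates on go trials, the *inhibition function* (stop-error
rate as a function of SSD), and the *stop-signal reaction time* (SSRT) —
the inferred latency of the stopping process, estimated as the median go
RT minus the SSD at which half of the stop trials end in an error.

The package implements two accounts of this behavior side by side:

* the **classical race model**, in which an independent go process with a
  broad finishing-time distribution races a stop process that finishes at
  SSD + SSRT (`race_params()`, `simulate_race_trials()`,
  `analytic_inhibition()`); and
* a **Bayes-optimal observer**, which continuously updates posterior
  beliefs about both the go stimulus and the stop signal, and decides at
  each moment between responding and waiting by minimizing expected cost
  (`task_params()`, `solve_policy()`, `simulate_cohort()`).

The race model assumes go and stop processing are independent, so
degrading the go stimulus should leave stop-side quantities such as SSRT
untouched. The optimal observer makes the opposite prediction: go
difficulty enters the joint inference and the decision policy, so go and
stop behavior co-vary. The package exists to compute those predictions
and to analyze trial data (simulated or human) with the field's standard
measures.

## Generative model and belief updates

Each trial carries hidden variables: the go identity $d \in \{0, 1\}$,
the stop-trial indicator $s \in \{0, 1\}$ (prior $r$), and — on stop
trials — an onset step $\theta$ with geometric prior
$P(\theta = t) = q(1-q)^{t-1}$, so the expected onset step is $1/q$.
Time advances in discrete steps. At step $t$ the observer receives two
conditionally independent binary samples: go evidence $x^t$ (equal to 1
with probability $q_d$ under $d = 1$, $1 - q_d$ under $d = 0$) and stop
evidence $y^t$ (equal to 1 with probability $q_s$ once the signal is on,
$1 - q_s$ before). $q_d \in [0.5, 1]$ is the go-stimulus
signal-to-noise: 0.5 is pure noise (hardest), values near 1 are easy.
The published description of the Bernoulli rates does not pin down which
hidden state maps to which rate; we adopt the convention above. The
model is symmetric under relabeling, so no behavioral quantity depends
on this choice.

The observer tracks

* $p_d^t = P(d = 1 \mid x^{1:t})$, updated by `update_pd()`;
* $p_z^t = P(\text{signal on by } t \mid y^{1:t})$, updated by
  `update_pz()` using the onset hazard
  $h(t) = r q (1-q)^{t-1} / (r(1-q)^{t-1} + 1 - r)$ (`hazard()`);
* $p_s^t = P(s = 1 \mid y^{1:t})$, derived from $(p_z, t)$ by
  `prob_stop_trial()`.

We carry $(p_d, p_z)$ as the state and derive $p_s$ wherever it is
needed: $p_s$ is a deterministic function of $(p_z, t)$, so gridding it
separately would add a dimension without adding information. Posterior
ratios are guarded by a $10^{-12}$ floor on denominators; certainty
($p = 0$ or $1$) is absorbing, as it should be.

`posterior_oracle()` computes the same posteriors by brute-force
enumeration over all latent configurations. It exists purely as an
independent cross-check of the recursion and refuses sequences longer
than 14 steps; the test suite verifies agreement to $10^{-10}$ over
every length-6 observation pair under randomly drawn parameters.

## Cost function and the dynamic-programming policy

Responding at step $t$ with choice $\delta$ incurs loss
$c\,t + c_s \mathbf{1}\{s = 1\} + \mathbf{1}\{\delta \neq d, s = 0\}$,
and waiting to the deadline $D$ incurs $c\,D + \mathbf{1}\{s = 0\}$: a
delay cost $c$ per step, a stop-error penalty $c_s$, and a unit cost for
go errors (all error costs normalized to the go-error cost). The
Q-factors over the belief state are

$$Q_g^t = c\,t + c_s p_s^t + (1 - p_s^t)\min(p_d^t, 1 - p_d^t), \qquad
  V^D = c\,D + (1 - p_s^D),$$

and $Q_w^t$ is the expectation of $V^{t+1}$ over the four possible next
observation pairs, whose predictive law factorizes as
$p(x \mid p_d)\, p(y \mid p_z, t)$ (`predictive_obs_dist()`).
`solve_policy()` computes $V^t = \min(Q_g^t, Q_w^t)$ backward from
$t = D - 1$ on a discretized belief grid. Default resolution is
200 × 200 with cell centers at $(i - 0.5)/n$, matching the reference
analysis; updated beliefs falling between centers are located by
bilinear interpolation (nearest-neighbor is available via `interp`, but
bilinear visibly reduces grid artifacts at this resolution). Exact ties
$Q_g = Q_w$ wait: waiting preserves the option to respond later, and the
tie set has measure zero.

Two details deserve a note:

* **Deadline branch.** At $t = D - 1$ the wait value is
  $c\,D + 1 - p_s$. One can read the $p_s$ here either at the current
  step or after advancing $p_z$ through the onset hazard to step $D$.
  The two readings are algebraically identical — the posterior of the
  static variable $s$ is a martingale, and the hazard-advanced $p_z$
  combined with the step-$D$ survival term reproduces $p_s^t$ exactly —
  so the `deadline_ps` flag changes nothing numerically; a test asserts
  the equality. We default to the carried form.
* **Topology.** The solved policy has two Go lobes at extreme $p_d$ and
  low $p_z$, a central Wait region, and Go regions that grow as the
  deadline approaches (deadline pressure). The test suite asserts this
  structure and the monotone growth of `go_region_area()` at 100 × 100
  resolution for all three reference $q_d$ values.

## Simulating subjects, and the time step

The reference condition set is $r = 0.25$, $q_s = 0.72$, $D = 50$,
$c_s = 0.4$, $c = 0.002$, with go reliability $q_d \in
\{0.55, 0.62, 0.70\}$ for the low/mid/high discriminability conditions.
The experiment being emulated has an 1100 ms response deadline, so one
model step is $1100 / 50 = 22$ ms (`ms_to_steps()` documents the
rounding rule). SSDs map to onset steps by the same rule.

The experiment draws SSDs uniformly from {100, ..., 600} ms, while the
observer's internal model assumes a geometric onset. This model–world
mismatch is deliberate and configurable: `sim_config(ssd_mode =
"empirical")` reproduces the experimental SSD grid, and the observer's
hazard parameter defaults to $q = 22/350 \approx 0.063$ so that the
assumed mean onset ($1/q$ steps ≈ 350 ms) matches the mean of the
empirical grid. For the model-prediction analyses (the cohort runs in
the tests and the acceptance script) we instead sample the world from
the observer's own generative model (`ssd_mode = "geometric"`): this is
the self-consistent reading of the simulation, and it places stop trials
across the full SSD range, so every subject's inhibition function spans
its 50% point and SSRT is estimable in all conditions. With the
100–600 ms grid, hard-condition inhibition functions often stay below
0.5 within the grid and SSRT is flagged as undefined — the flag, not a
fabricated value, is the intended behavior.

Trials are allocated stratified by default (exact 25% stop trials per
subject, SSDs balanced), mirroring blocked designs and reducing
variance; independent Bernoulli allocation is available. Every
subject-condition block derives its own seed from the root seed, so
cohorts are reproducible and order-invariant. The response side at a Go
decision is the more probable one ($p_d$ vs. $1 - p_d$), with a fair
coin on exact ties; non-decision time defaults to 0 ms (the model has no
motor stage) and can be offset via `non_decision_ms`.

## Behavioral measures and SSRT estimation

`summarize_condition()` computes the standard per-block measures; median
go RT uses all responded go trials by default (`rt_policy = "correct"`
restricts to correct responses). `estimate_ssrt()` fits a cubic
smoothing spline to the per-SSD stop-error proportions, weighted by
trial counts; the smoothing parameter is chosen by leave-one-out
cross-validation when at least 5 SSD points are available, a fixed
mid-range value with 4, and the fit degenerates to linear interpolation
with 3 (fewer is refused). The fitted curve is evaluated on a fine grid
over the observed SSD support, clipped to [0, 1], and searched
left-to-right for the first upward 0.5 crossing; SSRT is the median go
RT minus that crossing. A curve that starts above 0.5 pins the crossing
to the support's lower edge and is flagged `starts_above`; a curve that
never reaches 0.5 yields `NA` with flag `no_crossing`. We never
extrapolate beyond the observed SSDs.

The estimator's calibration anchor is the race model, where ground truth
exists: with a fixed SSRT the inhibition function is the go finishing
time distribution evaluated at SSD + SSRT (`analytic_inhibition()`), and
it passes 0.5 exactly when SSD + SSRT equals the median go finish. On
race cohorts of 20 subjects × 900 trials with generative SSRT 200 ms the
mean recovered SSRT is required (by the acceptance tests) to fall within
15 ms of truth.

## The synthetic human cohort

`synth_cohort()` emulates the human experiment's structure: 20 subjects,
4 conditions (8%, 15%, 85% motion coherence and a shape task), 225
trials per condition (3 blocks of 75), 25% stop trials, SSDs balanced
over {100, ..., 600} ms, 1100 ms deadline. The per-condition race
parameters (go RT mean 580/560/500/490 ms, lognormal sd 180/170/150/145
ms, SSRT 230/220/200/195 ms, discrimination error 0.20/0.12/0.03/0.02)
are not published quantities; they were fixed once as values typical of
human stop-signal cohorts, with the shape task calibrated to sit near
the easiest coherence. Between-subject heterogeneity adds Gaussian
offsets (sd 30 ms on go RT, 12 ms on SSRT) shared across conditions, so
condition effects are within-subject. Go finishing times are lognormal
by default (right-skewed, as empirical RT distributions are); omission
errors arise only from deadline censoring of the slow tail.

What passing tests on these data do and do not show: they validate the
estimators and tests against a generator whose ground truth is known and
whose structure matches the experiment's design. They do not capture
sequential effects, learning, attentional lapses, or non-stationary RT
distributions present in real data; conclusions about estimator behavior
under those features require real cohorts.

## Statistical reporting

`comparison_report()` aggregates per-subject summaries (never pooled
trials) and runs, for each planned measure and condition pair, a
one-sided paired t-test and a one-sided Wilcoxon signed-rank test.
Zero differences are dropped before ranking (Wilcoxon's original
policy); the null distribution is exact up to 15 nonzero differences and
a continuity-corrected normal approximation beyond. Zero-variance
difference vectors cannot support a t statistic and are flagged
degenerate rather than erroring. Subjects with undefined values (e.g.,
an inestimable SSRT) are dropped pairwise with a logged count. No
multiple-testing correction is applied, matching common reporting
practice for this design; the printed report says so explicitly. The
report always states the direction tested, never inferring a sign
convention from context.

## Problem sizes and numerical choices in the test suite

The packaged tests solve policies at 60–200 grid resolution, simulate
cohorts of 20 subjects × 300 trials per condition for the
model-prediction checks, 20 × 900 for estimator calibration, and 500
replicates of 10-subject null cohorts for the type-I error check; the
full suite runs in about a minute on one CPU. These sizes were chosen to
keep Monte-Carlo error well inside the asserted tolerances: rare-event
measures (omission errors, a few per thousand trials) are asserted on
the extreme condition pair only, since adjacent-condition differences at
this scale sit below sampling noise. Small-instance optimality of the
dynamic program ($D = 3$, 101 × 101 grid) is verified against exhaustive
enumeration of all observation paths and a family of fixed-threshold
comparison policies.

## Known limitations

* The observer's evidence is binary per step; continuous (e.g.,
  Gaussian) evidence variants are out of scope.
* No trial-to-trial learning of $r$ or $q$: every trial is treated with
  fixed priors.
* The policy acts on the nearest grid cell; at very coarse grids the
  induced decision boundary is visibly staircased, and policy
  quality below roughly 50 × 50 is not warranted.
* SSRT in the optimal model is an emergent, estimated quantity, not a
  parameter; its numerical value depends on the SSD sampling scheme and
  the estimator's support, so only within-scheme comparisons are
  meaningful.
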