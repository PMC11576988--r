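---
title: "Methods: iterative decomposition of cognitive task timecourses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iterative decomposition of cognitive task timecourses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idoct)
```

## The problem

Computerised cognitive tasks record a reaction time (RT), a response score
and a trial descriptor for every presentation. Summarising a participant by
mean accuracy or median RT discards this structure and confounds the
targeted cognitive ability with device latency, visuomotor speed,
task-unspecific processing and the speed–accuracy trade-off. When trials
are assigned adaptively (a staircase), naive difficulty calibration is
additionally biased, because hard trials are attempted only by able
participants.

`idoct` addresses both problems with a joint, data-driven estimation of
per-label trial difficulty and per-participant ability, built from two
fixed-point iterations.

## Model and estimation

### Inputs and scoring

A task dataset is a set of records `(participant, trial_label, rt, score,
order, timepoint)`. All RT quantities are in milliseconds and all internal
computation is in double-precision milliseconds. Two scoring modes exist:
*binary* (a correctness indicator) and *continuous* (a graded accuracy in
[0, 1]; ordinal rubrics such as 3/2/1/0 are first mapped linearly onto
[0, 1] by `normalize_graded_accuracy()`). Exactly one mode governs a
dataset. `RTmax` is the maximum RT over all retained records of the task —
a global scaling constant, shared by all participants; it only scales the
speed term, so an outlying `RTmax` compresses but does not reorder the
estimates (outlier filtering beforehand is still recommended, see below).

### Stage 1: difficulty

Performance on a presentation is

\[ P(i,t) = \mathrm{acc}(i,t)\,\bigl(1 - RT(i,t)/RT_{\max}\bigr)\,D(t), \]

zero for a wrong answer in binary mode (an RT on a failed trial carries no
information about ability: participants may labour over a trial they
cannot solve or skip it instantly). A label's difficulty is the group's
mean shortfall over *all* its presentations (repeated presentations to the
same participant count separately):

\[ D(t) = \frac{1}{\sum_i T(i,t)} \sum_i \sum_{j=1}^{T(i,t)} \bigl(1 - P(i,t,j)\bigr). \]

Since \(D\) enters \(P\) and \(P\) enters \(D\), the two are iterated from
\(D(t,0) = 1\) ("all trials maximally difficult"). The update is affine
per label, \(D \leftarrow 1 - m_t D\) with
\(m_t = \operatorname{mean}\bigl(\mathrm{acc}\,(1 - RT/RT_{\max})\bigr) \in [0,1]\),
a contraction whose fixed point \(1/(1+m_t)\) lies in \([0.5, 1]\).
`closed_form_difficulty()` exposes this analytic solution and serves as an
independent oracle for the iterative estimator in the test suite.

### Stage 2: ability and delay

RT is decomposed as \(RT(i,t) = AT(i,t) + DT(i)\): a trial-specific answer
time and a participant-level delay. The answer time is modelled as

\[ AT(i,t) = \bigl(1 - A(i)\bigr)\, D(t)\, \bigl(RT(i,t) - DT_{\max}(i)\bigr), \]

where \(DT_{\max}(i)\), the participant's smallest retained RT, bounds the
delay from above at initialisation: the normalised answer-time fraction
\((1-A)\,D \in [0,1]\) multiplies the available headroom above the fastest
response. Performance is re-expressed through the decomposition,

\[ P(i,t) = \mathrm{acc}\,\Bigl(1 - \tfrac{AT(i,t)}{RT_{\max}} - \tfrac{DT(i)}{RT_{\max}}\Bigr) D(t), \]

clamped to [0, 1] (extreme RT/DT combinations can push the raw expression
outside the unit interval; P is a performance proportion, so clamping is
the appropriate resolution). Ability aggregates performance through
cumulative sums in presentation order:

\[ A(i) = \frac{1}{Q}\sum_{N=1}^{Q} \frac{1}{N}\sum_{t \le N} P(i,t), \]

the mean of the running cumulative means. This weights early trials more
heavily than a plain mean, so the estimate depends on the recorded
presentation order; the package therefore requires an `order` field (file
row order is the documented fallback). The mean-of-cumulative-means form
is used rather than the mean of unnormalised cumulative sums because the
latter grows with the trial count and escapes [0, 1]; the normalised form
preserves the early-trial weighting while keeping \(A \in [0,1]\), which
every downstream quantity assumes.

The first iteration sets the answer-time fraction to its ceiling
(\(ATN = 1\), i.e. \(AT = RT - DT_{\max}\), equivalently \(DT(i,0) =
DT_{\max}(i)\) with ability "assumed maximal"); subsequent iterations use
\((1-A)D\) with the current abilities. Iteration stops when the mean
absolute change in \(A\) across participants falls below the tolerance.
After convergence, \(AT\) and \(DT(i) = \operatorname{mean}_t(RT - AT)\)
are recomputed once at the final abilities so the reported decomposition
is self-consistent. By construction \(AT(i,t) \in [0,\, RT(i,t) -
DT_{\max}(i)]\) and hence \(DT(i) \in [DT_{\max}(i),\,
\operatorname{mean}_t RT(i,t)]\); a tighter upper bound of
\(DT_{\max}(i)\) on the delay would be incompatible with the update
equations (which place \(DT\) *at* \(DT_{\max}\) only when \(AT\) fills
all the headroom), so the estimates are reported unclamped with this
documented range.

### Specific ability and scaled difficulty

The specific performance rescores each presentation using only the answer
time, \(PA = \mathrm{acc}\,(1 - AT/AT_{\max})\,D(t)\) clamped to [0, 1],
with \(AT_{\max}\) the maximum answer time over all retained
presentations — the analogue of \(RT_{\max}\) on the answer-time scale,
computed after the ability stage. The specific ability \(AS(i)\) is the
mean of cumulative means of \(PA\), exactly as \(A\) is built from \(P\).
If every answer time is zero (all participants perfectly flat RTs) the
\(AT/AT_{\max}\) term is dropped with a warning.

The scaled difficulty corrects the difficulty scale for *who* saw each
label:

\[ DS_{\mathrm{pre}}(t) = D(t)\cdot \operatorname{mean}\{AS(i) : i \text{ saw } t\}, \]

the mean running over the distinct participants presented the label. The
pre-scale values are then mapped affinely onto \([\min D, \max D]\), so a
uniform-ability cohort recovers \(D\) exactly and the reported scale stays
comparable to \(D\). With a single label (or constant pre-scale values)
the rescaling is undefined and the pre-scale values are returned with a
warning; they are always attached as the `"pre_scale"` attribute.

### Convergence control

Both stages run until the mean absolute parameter change drops below
`tol` (default `1e-6`) or `max_iter` (default 10) is reached. Ten
iterations reflect the fixed depth at which the decomposition typically
stabilises in practice: the difficulty stage contracts geometrically at
rate \(m_t\), and under the standard simulated conditions below both
stages are inside `1e-3` mean change within ten iterations (the ability
stage typically within three to five). Hitting `max_iter` short of `tol`
flags the result and records the residual change in the iteration trace
rather than raising an error; for oracle-grade comparisons the tests use
`idoct_control(tol = 1e-12, max_iter = 500)`.

Degenerate inputs are handled explicitly: a label whose slope \(m_t\) is
numerically 1 (every presentation correct at effectively zero RT) would
oscillate between 0 and 1, so its analytic fixed point 0.5 is returned
with a warning; a participant with a single trial has \(AT = 0\), \(DT\)
equal to that RT and ability equal to the single performance value;
all-incorrect data yield \(D \equiv 1\), \(A = AS = 0\) and \(DT\) at its
lower bound \(DT_{\max}\). Cumulative sums are accumulated in double
precision, and all reductions are per-participant sums over sorted factor
levels, so results are independent of participant processing order (only
presentation order within a participant matters, by design).

## Preprocessing

Three filters mirror standard hygiene for online trial data, each
returning a `filter_report` whose counts sum to the input size; they are
idempotent and commute:

* `filter_rt_outliers(records, low_ms, high_ms)` — responses outside the
  window are signs of cheating (too fast) or disengagement (too slow).
  Cut-offs are task-specific judgements made on the task's RT
  distribution; the defaults (200 ms, 60 s) are deliberately permissive
  and study configurations should override them.
* `drop_repeat_participants(records)` — a participant observed at more
  than one timepoint is removed entirely, to avoid learning effects.
* `cap_span_trials(records, max_len)` — span trials beyond a plausibility
  cap (10–11 items for typical spatial/digit spans) indicate written-down
  sequences.

Trial labels are composed from raw design columns with
`build_trial_labels()` (deterministic concatenation); continuous
difficulty dimensions (e.g. distance to the previous target) are binned
into equal-width bins by `bin_difficulty_dimension()`, 20 bins by default
— fine enough to preserve the gradient, coarse enough that each bin
retains presentations.

## The synthetic generator

`simulate_task()` generates data from the structural inverse of the
model: latent abilities \(a_i \sim \mathrm{Beta}(4, 2)\), delays
\(\delta_i \sim \Gamma(\text{shape}=16, \text{scale}=50\,\mathrm{ms})\)
(mean 800 ms, positively skewed), difficulties evenly spaced on
\([0.2, 0.95]\), answer times \(AT = (1-a_i)\,d_t\,\tau\,\varepsilon\)
with \(\tau = 800\) ms and unit-mean lognormal noise
(\(\sigma = 0.15\)), \(RT = AT + \delta_i\), and correctness
\(\sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(\kappa(a_i - d_t)))\) with
\(\kappa = 6\); continuous mode draws a three-point rubric from the same
link. These defaults were chosen to emulate large online task batteries —
a positively skewed delay distribution with coefficient of variation
around 0.25, a negatively skewed specific-ability distribution, task-level
accuracy around 50–60% — and to place the difficulty iteration in its
typical operating regime (label slopes \(m_t\) averaging ≈ 0.35), where
ten iterations suffice. All parameters are config-exposed and every
generator is bit-reproducible given its mandatory seed.

`simulate_staircase_task()` implements the span-task convention: labels
are ordered levels; success moves up one level (success at the top level
ends the task), failure repeats the level, and three consecutive failures
terminate. This concentrates hard levels on able participants — the
sampling bias `DS` corrects.

What the generator does *not* emulate: multi-task batteries with
correlated abilities (induced in tests by sharing ability draws across
generator calls), demographic or device covariates, learning and fatigue
within a session, and the structural mismatch of real tasks whose
difficulty dimension is only partly captured by the label. Passing
recovery tests on this generator therefore shows that the estimator
inverts its own generative family at realistic noise levels, not that
real-data estimates are unbiased.

One structural point deserves note: the generator's answer time is scaled
by the constant \(\tau\), while the model's is scaled by the
participant-specific headroom \(RT - DT_{\max}\). Even at zero RT noise
the fitted delay therefore carries a small ability-dependent residual,
and no non-trivial generator can satisfy the model's equations exactly
(solving them self-consistently forces \(AT \equiv 0\)). Delay recovery
at the standard size is accordingly high but not perfect (Spearman ≈
0.97–0.98 in the noiseless limit), which the property tests assert at a
0.95 threshold.

## Psychometric layer

Across several fitted tasks, the per-participant `AS` (or `DT`) vectors
form a sparse participant-by-task score matrix. `pairwise_correlation()`
uses pairwise-complete Pearson correlation with a minimum-overlap
threshold (default 3; pairs below it are reported missing).
`hierarchical_clusters()` applies complete-linkage clustering to
\(1 - r\). `kaiser_nfactors()` counts eigenvalues strictly greater than 1
— strict, so an identity matrix retains zero factors.

Factor extraction is implemented in-package (minimum-residual by default,
principal-axis optionally), with `stats::varimax` for the reported
orthogonal rotation; column signs are fixed so each factor's
largest-magnitude loading is positive, making solutions deterministic.
`schmid_leiman_g()` follows standard higher-order practice: the
first-order solution is rotated *obliquely* (promax) — a second-order
factor is only identified if first-order factors correlate, so the
orthogonal varimax solution cannot feed the Schmid–Leiman step — the
inter-factor correlation matrix is factored by a single second-order
factor (with the conventional equal-loading resolution
\(\sqrt{r_{12}}\) when there are exactly two first-order factors), and
per-task general-factor loadings are the product of first-order pattern
loadings and second-order loadings. The summary statistic is
`pct_g = 100 · ss_g / n_tasks`, reported at full precision; it is the
share of total (unit) task variance carried by the general factor, and
the smaller it is, the more discretely a battery fractionates abilities.

`cohens_f2()` defaults to the reciprocal form \((1 - R^2)/R^2\), the
convention under which values at or below 0.02 are read as negligible
device effects in this workflow; `conventional = TRUE` gives the textbook
\(R^2/(1 - R^2)\). `effect_size_sd()` divides a regression coefficient by
the outcome's standard deviation. The demographic regressions and ANOVA
themselves are ordinary `lm()`/`anova()` territory and are deliberately
not wrapped.

## Problem sizes used in the tests

The suite validates at sizes chosen to make the properties sharp while
remaining quick to run: oracle and transliteration checks on datasets of
up to 6 participants × 5 labels (tolerances 1e-6 and 1e-9); parameter
recovery and distribution-shape checks on the standard balanced
simulation of 1000 participants × 50 labels (Spearman > 0.9 for ability,
delay and difficulty); staircase-bias correction over 50 replicates of
300 participants × 10 levels (scaled difficulty at least as well ranked
as raw difficulty in ≥ 90% of replicates); and subsample stability on
2000 participants × 30 labels with 30 subsamples of 100 (mean AS and DT
correlation with the full-sample fit ≥ 0.9).

## Known limitations

* A single difficulty dimension per task: trials varying several
  cognitive demands at once are collapsed into one label.
* `DT` aggregates device latency, visuomotor speed and unspecific
  cognition; the components are not separable without dedicated
  psychophysical tasks.
* Ability estimates depend on presentation order (early-trial weighting);
  comparing participants assumes comparable trial orders, which holds for
  randomised or fixed-schedule designs.
* `RTmax` and `ATmax` are global sample statistics; estimates from
  different samples are comparable in rank but not in absolute value
  unless the scaling constants are shared (e.g. by passing `rt_max`
  explicitly when scoring a subsample).
* The difficulty of rarely-presented labels is estimated from few
  presentations; `presentation_counts` should be inspected before
  interpreting extreme `D` values.
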