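---
title: "Simulating and analysing rapid motor behaviour tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing rapid motor behaviour tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rapidmotor)
```

## The tasks and the analysis problem

Object-Hit (OH) and Object-Hit-and-Avoid (OHA) are bimanual
object-interception tasks run on robotic exoskeleton platforms. Virtual
objects fall towards the participant from ten invisible bins spread across
a horizontal workspace; the participant strikes them with two 5 cm paddles
attached to their hands. In OH all 300 objects are targets. In OHA, 200
targets are mixed with 100 distractor shapes that must *not* be struck.
Objects are released at an ever-increasing rate and speed, so every
participant is eventually overwhelmed: the trial begins as an easy tracking
exercise and ends as a forced triage. The kinematics of both hands are
recorded at 200 Hz together with an event log giving, for every object, its
bin, shape, role, creation time, outcome (hit, missed, or — for distractors
— avoided), outcome time and the hand used.

The analysis battery built on these recordings spans three levels:

1. **per-trial parameters** — mean hand speed and movement area per hand
   with bilateral biases, hand selection measures, the timing and spatial
   bias of misses, OHA-specific distractor and processing-rate measures,
   the number of targets hit, and the *steady-state rate*: the rate at
   which targets are hit once the participant can no longer keep pace;
2. **strategy summaries** — paddle-velocity cosine similarity per second,
   and a ten-gap running-mean prediction model for inter-contact intervals;
3. **cohort statistics** — per-parameter linear regressions on age,
   male/female mean comparisons, slope-comparison Z-tests between the
   sexes, all judged against a Bonferroni-corrected significance level,
   plus distribution and trade-off checks that validate the tasks
   themselves.

Because raw recordings from clinical platforms are not freely
redistributable, the package pairs this battery with a *simulator* whose
participants have known, injectable ground truth. Every analysis can then
be exercised end-to-end: inject an age-related decline in processing
capacity, simulate a cohort, extract parameters, and verify that the
statistical layer recovers the decline.

## The capacity-limited participant model

The agent is intentionally the smallest mechanism that reproduces the
qualitative structure of real trials — an early phase of near-perfect
accuracy, an overwhelmed phase in which the hit rate saturates, and a
central-bin preference during triage. It has five ingredients:

* **A serial processing bottleneck.** One object decision is committed at
  a time. Each commitment occupies the processor for a Gamma-distributed
  time with mean $1/\lambda$, where $\lambda$ (`capacity_lambda`, Hz) is
  the participant's maximum sustainable rate of correct object
  processing. The Gamma shape of 3 (coefficient of variation 0.58) gives
  the moderate regularity typical of human inter-hit intervals; a memoryless
  exponential produces implausible bursts of very short and very long
  decision times. When targets are plentiful the hit rate therefore
  saturates at (slightly below) $\lambda$; when the creation rate is
  below $\lambda$ the processor idles and every target is engaged.
* **Greedy nearest-feasible selection.** When the processor frees, the
  agent engages the in-flight object whose bin is nearest to a hand that
  can physically reach it (travel at `max_hand_speed`, after
  `reaction_delay`) before it falls past the last-chance interception
  line. Feasibility plus travel cost is what produces the overwhelmed
  central-bin preference: no explicit triage rule is coded.
* **A strike zone.** Objects become strikeable once they fall below
  y = 40 cm and are gone past y = 12 cm (of a 65 cm deep workspace);
  contact happens wherever in that band the hand meets the object. Hands
  are therefore tied up only until contact, not for an object's entire
  fall.
* **Soft hand lateralisation.** The probability of using the right hand
  is logistic in the object's x with midpoint `hand_transition_x` and a
  4 cm scale, constrained to hands that can feasibly reach. This yields
  per-bin hand fractions that cross 0.5 at the participant's transition
  point, with overlap near the boundary.
* **Failure modes.** An engaged target is missed with probability
  `lapse_prob`; each OHA distractor is misclassified as a target (and, if
  engaged, struck) with probability `distractor_error_prob`. Correctly
  classified distractors are simply never engaged and exit as avoided.

What the model deliberately omits: limb dynamics and muscle models,
haptic feedback (the real platform renders a 50 ms force pulse on
contact; only the contact event matters to any analysis), visual
perception, learning across trials, and any handedness effect beyond the
stored covariate.

## Task schedule defaults

The platform's exact creation-rate and speed schedules are proprietary,
so the package fixes a transparent schedule with the same qualitative
structure and makes every element configurable:

| quantity | default | notes |
|---|---|---|
| creation rate | linear ramp 0.5 → 3.5 Hz | spans keep-up → overwhelmed for plausible capacities (roughly 1–3 Hz) |
| creation span | ≈ 150 s | 300 objects at the ramp's 2 Hz mean rate; creation times are the deterministic quantile points of the ramp |
| object speed | linear ramp 10 → 50 cm/s | objects cross the workspace in 6.5 s early, 1.3 s late |
| workspace | 80 × 65 cm | 5200 cm²; x = 0 at the midline, y away from the participant |
| bins | 10, 8 cm apart | each round of 10 drops is a fresh random permutation of the bins, so every bin releases exactly 30 objects |
| paddle / object | 5 cm / 2 cm | contact at centre distance ≤ 3.5 cm |
| sampling | 200 Hz | positions and velocities for both hands |

## Cohort generation

`cohort_spec()` encodes the generative structure the statistics are meant
to recover. Each latent participant parameter is drawn as

$$\theta_i = \beta_0 + \beta_{age}\,a_i + \beta_{sex}\,[{\rm male}_i] +
\varepsilon_i,\qquad \varepsilon_i \sim N(0, \sigma^2_\theta),$$

then clipped to its valid domain. Ages are drawn from per-decade weights
shaped like a typical healthy-control recruitment profile (heaviest in
the 18–29 stratum, a secondary mode in the 60s, thin above 80), sex from
a configurable ratio (default 55% female). Defaults place baseline
processing capacity at 2.6 Hz (age-0 intercept) with 0.3 Hz
between-subject spread, so a cohort spanning ages 18–93 with the
reference decline of −0.0099 Hz/yr covers capacities of roughly 1.5–2.7
Hz — all overwhelmed well before the 3.5 Hz ramp end, as the tasks
intend. Identical `global_seed` values reproduce the cohort exactly, and
the participant-level draw is available without trial simulation via
`cohort_ground_truth()`.

## The steady-state detector

The steady-state rate is computed exactly as in the field's analysis:
target creation and target hit event times are binned into 1 s counts,
both series are smoothed with two iterations of a Kolmogorov–Zurbenko
(moving-average) filter with a 5 s window, and a 5 s window slides over
the difference. The overwhelmed phase begins at the start of the *last*
window in which the median (creation − hit) difference is below 0.1 Hz —
the last moment the participant demonstrably keeps pace. The steady-state
rate is then the raw count of target hits from that onset to the end of
the trial, divided by the elapsed time.

Numerical choices that the original description leaves open, fixed here:

* **Rate-series resolution** is 1 s, which makes the 5 s window exactly
  5 samples and the window stride one sample.
* **KZ edge handling** uses the truncated (shrinking) window convention,
  the standard for this filter; constants pass through unchanged and the
  interior of a linear ramp is preserved.
* **Raw counts, not the smoothed series**, define the final rate: the
  smoothing exists only to locate the onset robustly.
* **Degenerate trials are flagged, never errors**: a participant
  overwhelmed from the very start gets onset 0 and flag
  `never_kept_pace`; one who keeps pace to the end is flagged
  `never_overwhelmed` with the rate computed over the final window; a
  no-hit trial is flagged `no_hits` with rate 0. Batch processing of
  hundreds of trials must not halt on an outlier.

## Parameter-extraction conventions

* **Median error** indexes targets by *creation order*, not time: it is
  the percent of the target sequence elapsed when cumulative misses first
  reach half their total.
* **Object processing rate** uses the creation time of the 240th object
  (80% of 300) as its denominator; "correctly processed" counts targets
  hit by then plus distractors that had fully exited unhit.
* **Hand transition** is estimated from per-bin right-hand fractions,
  made monotone by an isotonic fit and interpolated linearly between bin
  centres. This is deterministic on sparse trials, at the price of a
  resolution bounded by the 8 cm bin grid — recovery of a known logistic
  midpoint is accurate to roughly 1–1.5 cm, not arbitrarily fine.
* **Hand selection overlap** counts chronological left/right alternations
  within each bin's hits, summed and divided by the task's target count.
* **Task score** is the root sum of squares of standardised deviations
  from a normative expectation fitted on a reference cohort (linear in
  age and sex per parameter). Two standardisations are provided:
  plain residual z-scores, and a rank-based inverse-normal transform for
  one-sided or skewed parameters. The published normative machinery for
  these tasks is proprietary; this simplified version preserves its
  contract — 0 is best, larger is worse, orthogonal deviations add in
  quadrature — and is isolated behind `fit_normative()`/`task_score()` so
  it can be swapped.

## Strategy summaries

Per-second similarity uses non-overlapping $[k, k+1)$ s windows aligned
to trial start; samples where either paddle is exactly stationary are
excluded from that second's mean, the cosine being undefined at zero
velocity. The gap model predicts each inter-contact gap as 0.965 times
the mean of the preceding ten gaps; *contacts* are all object/paddle
strikes, distractors included, and prediction errors are expressed as a
percentage of the trial's mean gap, which makes them invariant to time
rescaling. With a constant gap history the prediction error is exactly
−3.5%, a useful built-in check.

## Statistical layer

* Regressions are ordinary least squares with t-based p-values
  (df = n − 2) and 95% CIs.
* The sex comparison is the classic pooled-variance Student t-test
  (Welch available behind `pooled = FALSE`).
* Slope comparisons between independently fitted male and female
  regressions use $Z = (b_m - b_f)/\sqrt{SE_m^2 + SE_f^2}$ with a
  standard-normal two-tailed p. When reconstructing an SE from a printed
  95% CI, the normal quantile 1.96 is used.
* The Bonferroni family size is a *configured* value (default 68, the
  reference battery's count), not inferred from the table at hand.
* Repeat trials from one participant enter regressions as independent
  rows with equal weight; no mixed-effects correction is applied. This
  mirrors the reference analysis of these tasks, which pooled multiple
  trials per participant after establishing the absence of learning
  effects.

## What passing tests do and do not show

The simulator emulates the *statistical structure* the analysis assumes:
event-log bookkeeping, the two-phase trial anatomy, capacity-limited hit
rates, lateralised hand use, and linear age/sex structure on latent
parameters. Its kinematics are schematic (dwell-then-dash paths with a
small sway), so distribution-level kinematic quantities — similarity
medians, gap-error IQRs, absolute movement areas — differ from human
values, and tests on them check internal consistency against independent
oracles, not human realism. Recovery tests demonstrate that the pipeline
detects injected effects of realistic magnitude; extraction compresses
capacity differences slightly (the fitted steady-state slope on a cohort
with an injected −0.0099 Hz/yr capacity decline is typically around
−0.009 Hz/yr), so recovered slopes should be read as attenuated estimates
of the latent ones. None of this says anything about effect sizes in any
real population.

Problem sizes in the shipped tests were chosen to make sampling error
negligible relative to each tolerance: 20-seed replications for detector
and recovery checks, cohorts of 200–800 trials for correlation and power
properties, 100 replicates for CI-coverage calibration.

## Known limitations

* The agent's saturation rate sits a few percent below the nominal
  capacity (travel feasibility and occasional engagement of soon-lost
  objects), so generative capacities are recovered to within ~5%, not
  exactly.
* The hand-transition estimator's resolution is bounded by the bin grid.
* The normative (task-score) machinery is a documented simplification.
* No attempt is made to match the proprietary creation/speed schedules
  beyond their qualitative shape; absolute times and counts in simulated
  trials are internally consistent but platform-specific quantities.
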