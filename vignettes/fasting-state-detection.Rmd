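---
title: "Detecting fasting states and scoring TRE adherence: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fasting states and scoring TRE adherence: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fastsense` infers whether a person is in a fasting or a fed state from two
passive sensor streams — interstitial glucose sampled every 15 minutes and
wrist acceleration sampled at 1 Hz — and scores how well each day's inferred
or logged eating window satisfies a time-restricted-eating (TRE)
prescription. This vignette is the package's account of the underlying
models, the parameters that matter, and the design choices made where the
design was genuinely open.

## The synthetic cohort generator

Real trial streams of this kind are rarely shareable, so the package is built
around a generator (`sim_config()`, `simulate_participant()`,
`simulate_cohort()`) whose records have known ground truth. It emulates:

* **Meal schedules** under five regimes: early TRE (eating 08:00–16:00), late
  TRE (13:00–21:00), a self-selected 8-h window (start drawn once per
  participant between 07:00 and 14:00), religious dry fasting (eating only
  before sunrise, 05:30, and after sunset, 19:30), and habitual eating
  (06:00–23:00). Each day carries 2–4 eating occasions of 10–40 min placed on
  evenly spaced slots with ±20 min of uniform jitter, clipped into the
  regime's admissible range. A uniform draw over 2–4 occasions was chosen as
  the plain reading of "a few meals and snacks per day"; occasion counts are
  overridable (`meals_per_day`), including 0 as a test hook.
* **Glucose**: a fasting baseline (90 mg/dL, participant offsets ±10) plus a
  24-h circadian sinusoid (amplitude 5 mg/dL, trough 03:00) plus one
  postprandial excursion per meal plus Gaussian sensor noise (SD 5 mg/dL),
  floored at 40 mg/dL (the sensor's lower limit). The excursion kernel rises
  linearly to `meal_amplitude` (45 mg/dL) over `meal_peak_minutes` (45 min)
  and decays exponentially with time constant `meal_decay_minutes` (90 min).
  The piecewise linear-rise/exponential-decay form was chosen for closed-form
  testability; the physiology literature offers no canonical meal-response
  shape at this granularity.
* **Type-1 diabetes mode** (`t1dm_mode`): each meal additionally subtracts a
  Gaussian lobe of depth `bolus_undershoot` (15 mg/dL) centred one decay
  time after the excursion peak, with SD equal to the decay time, ramped in
  over the rise so the kernel is exactly zero at meal start. The width was
  fixed at design time so that the *net* kernel dips a few mg/dL below
  baseline two to four hours after a meal — the reactive hypoglycemia that
  makes fasting-glucose thresholds unreliable in insulin-treated diabetes.
  This is a phenomenological stand-in, not an insulin–glucose ODE model: it
  captures the one property that matters here (fed-state glucose crossing
  below the personal fasting threshold) at desk scale.
* **Actigraphy**: per-second axis accelerations drawn around
  `activity_day_level` (0.3 g) while awake (06:00–23:00) and
  `activity_night_level` (0.02 g) during sleep, with bouts at twice the day
  level overlapping eating occasions; Poisson per-second step counts with
  rate proportional to the current level, zero during sleep; a crude lux
  channel. Sleep is fixed at 23:00–06:00 to match the circadian trough.

What the generator does **not** emulate: sensor dropout and compression
artifacts, carbohydrate-dependent excursion sizes, inter-meal insulin
dynamics, naps, or non-wear periods. Passing tests therefore demonstrate
correctness of the pipeline's arithmetic and its qualitative behaviour under
clean, well-posed conditions — not field performance on messy trial data.

## Two notions of "not fasting"

The package deliberately keeps two label conventions apart:

* the **eating-window label** (`label_fasting_state()`): non-fasting on the
  closed daily interval from the first occasion start to the last occasion
  end. This is the classification ground truth, with *no* postprandial
  buffer, and both boundary timestamps inclusive.
* the **fed window** of the threshold heuristic (`fed_fasting_windows()`):
  first occasion start to last occasion end **plus 4 h** of postprandial
  buffer, half-open. The fasting windows are its complement; the personal
  threshold is the pooled arithmetic mean (a grand mean of samples, not a
  mean of daily means) of all glucose readings inside them.

Keeping them distinct makes the heuristic directly comparable to the
supervised models on the same labels, while preserving the heuristic's own
definition of its training window. `hutchison_eval()` can score against
either frame (`truth = "eating_window"` or `"fed_window"`). The
bolus-undershoot degradation is assessed on the fed-window frame: the dips
occur two to four hours after meals, i.e. inside the fed window's buffer,
so that frame is where a threshold method's failure under insulin
interventions is visible. On the buffer-free labels the same dips fall in
nominally-fasting time and mask the effect.

The heuristic classifies `fasting` where glucose is at or below
`threshold + margin`, ties inclusive; fasting is the low-glucose side, and
"latest meal" means the *end* of the last occasion (the postprandial clock
starts when eating stops). All three conventions are configurable. The
default margin is 0 mg/dL. With a noisy sensor and margin 0, roughly half of
all truly fasting samples necessarily sit above the mean-of-fasting
threshold, which caps per-timestamp accuracy near the high-60s% — the
regime the method is known for. When the goal is recovering a known fasting
level from a noisy two-level trace, a margin of about two noise standard
deviations restores near-perfect accuracy; the package's own recovery checks
use exactly that convention and say so.

## Window features

Features are computed over 45-min windows advancing by 15 min (one glucose
sample); each window is labeled by its centre grid point (odd sample count,
so no ties). Glucose: mean, **population** SD (divisor N, matching common
CGM-metric implementations), intraday CV `100·sd/mean`, J-index
`0.001·(mean + sd)`, max, min. The J-index is implemented exactly as the
linear form just given; the glycemic-control literature also uses a squared
variant `0.001·(mean + SD)^2`, exposed via `j_index_squared = TRUE`, with no
claim about which is "right" — the linear form is the package default.
Acceleration: per-axis mean, max, and energy (`mean(a^2)`), mean steps, mean
vector magnitude, and a signal-peak count (strict local maxima of the vector
magnitude above mean + 1 SD of the window, minimum separation 5 s; both
parameters configurable, since activity-recognition practice varies).

Harmonization snaps CGM readings to a midnight-anchored 15-min grid (nearest
grid point within 2 min, otherwise a gap), aggregates the 1 Hz channels into
half-open grid bins (means; steps summed), and drops windows touching a
glucose gap or an empty accelerometer bin — the simplest defensible
missing-data rule.

Recursive feature elimination refits a ranking model and removes the single
least important feature per iteration (|coefficient| for linear rankers,
impurity importance for trees; ties drop the later-registered feature). The
pipeline default ranks with logistic regression and uses per-sensor quotas
(3 glucose + 3 acceleration), protecting a sensor at its quota — the
selection then always lands on the 3 + 3 shape while the identities remain
data-driven.

## The supervised pipeline

Training windows are rebalanced with SMOTE (synthetic minority points
`x + λ(x_nn − x)`, λ ~ U(0,1), among the 5 nearest minority neighbours)
followed by Tomek-link removal; because deleting a link can expose new
mutual nearest-neighbour pairs, removal iterates until an all-pairs scan of
the output finds none. Min-max scaling fits its bounds on the training set
only (constant features map to 0). The split is **grouped by participant**
(70/30): windows of one person are heavily overlapping, so an ungrouped
split would leak. Model families use their library defaults at a fixed seed;
hyperparameter search is out of scope.

Chronological predictions are smoothed per participant with a centred
rolling majority vote, k = 5 windows (75 min); edges use the available
shorter window and exact ties keep the original label. k = 5 is the smallest
window that removes the dominant error mode (isolated flips) without eroding
genuine state changes longer than ~40 min.

Evaluation takes the fed state (`non_fasting`) as the positive class and
reports accuracy, smoothed accuracy, precision, recall, F1, and a seeded
percentile bootstrap 95% CI of the F1 (1000 window resamples by default).
Degenerate 0/0 ratios are defined as 0, and the CI is widened, when
necessary, to contain the point F1 so the report's invariant
`ci_low ≤ f1 ≤ ci_high` holds unconditionally.

## Exact Shapley attributions

`exact_shapley()` enumerates all `2^d` coalitions; the value of a coalition
is the mean model score over a background sample with the coalition's
features set to the instance (the **interventional** expectation —
conditional expectations would require a density model the data cannot
support). Scores are the model's continuous output (probability or SVM
margin), not the hard label. The background is a seeded subsample of up to
200 training rows — enough for stable means at negligible cost. Enumeration
is capped at 12 features (4096 coalitions); the pipeline explains 6. A
permutation-enumeration implementation (`shapley_permutation()`) exists
solely as an independent cross-check of the coalition path.

## Adherence scoring

The prescription "8-h eating window ± 30 min" admits two readings; both are
exposed. The default treats it as an inclusive upper bound
(duration ≤ 510 min — eating *less* than 8 h is not a protocol violation),
`strict = TRUE` enforces the two-sided 480 ± 30 min band. Clock-frame
compliance (window inside the prescribed frame ± 30 min) applies only to
regimes that prescribe clock times (early/late TRE). A day is compliant when
it satisfies the duration rule and, where applicable, the frame rule; days
with no eating window are excluded from the denominator and flagged. Windows
may come from the meal log or from a (preferably smoothed) predicted label
sequence; the two paths agree to one grid step by construction.

## Numerical and degenerate-input conventions

All timestamps are timezone-naive local clock time (stored as UTC, so
arithmetic is DST-free). Glucose outside 40–500 mg/dL is rejected on
ingestion; duplicated timestamps keep the first reading. Threshold ties
classify as fasting; smoothing ties keep the original label; RFE importance
ties drop the later-registered feature. Windows need at least two glucose
samples; single-class inputs to rebalancing or training are errors, as is a
record with no glucose sample in any fasting window.

## Problem sizes

The package's reference experiments use a 10-participant, 14-day early-TRE
cohort: 1,344 CGM points and 1.2 million accelerometer samples per
participant, ~13,400 labeled 45-min windows cohort-wide, grouped 70/30.
Threshold-heuristic properties are replicated over 20 generator seeds;
smoothing properties over 30. These sizes give stable estimates (binomial
SEs below half a percentage point on the window counts involved) while a
full run stays comfortably on a laptop.

## Known limitations

* With the default 90-min excursion decay, glucose remains elevated for
  two to three hours after the last meal. Under the buffer-free
  eating-window labels those windows are fasting, yet their feature
  distribution is identical to interior post-meal windows that are fed —
  and the feature registry deliberately contains no clock-time feature. No
  classifier can separate identically distributed classes, which caps
  held-out F1 for the fed class near 0.78–0.80 on the synthetic cohort
  (precision is the binding side). This is a property of the label
  convention plus generator, not of any particular model: SVM, forest, MLP
  and kNN all plateau within a point of each other across hyperparameters.
  On real data the same ambiguity exists but is softened by behavioural
  correlates of eating that the generator does not model.
* The T1DM mode captures reactive hypoglycemia only; it is not a
  physiological insulin–glucose model and should not be used to draw
  quantitative conclusions about diabetic glucose dynamics.
* The heuristic's accuracy depends strongly on the label frame (see above);
  comparisons across studies should state the frame explicitly.
* Religious dry-fasting days have eating both before sunrise and after
  sunset, so the "daily eating window" spans nearly the whole day; duration
  compliance is not a meaningful notion for that regime and the clock-frame
  rule does not apply.
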