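# fastsense

Passive dietary-adherence assessment for intermittent-fasting studies from
wearable sensor data.

Clinical fasting trials (time-restricted eating, religious fasting) depend on
participants truthfully logging when they ate. `fastsense` implements the
alternative: infer the fasting state passively from a continuous glucose
monitor (CGM, one reading per 15 min) and a wrist actigraph (1 Hz), then score
each day's eating window against the prescription. It is aimed at researchers
running or reanalysing such trials, and ships a synthetic-cohort generator
with known ground truth so every stage is testable without any participant
data.

## What it computes

**Windowed features.** Over 45-min sliding windows (step 15 min) of the
harmonized streams: glucose mean, population SD, intraday CV
(`100 * sd(G)/mean(G)`), J-index (`0.001 * (mean + SD)`), extrema; per-axis
acceleration mean/max/energy (`mean(a^2)`), step counts, vector-magnitude
signal peaks. Recursive feature elimination reduces these to a compact set
(by default 3 glucose + 3 acceleration features).

**Two classifiers of fasting state.**

* *Personalized threshold heuristic*: the mean fasting glucose of a
  participant in a condition, taken over the window beginning 4 h after each
  day's last meal, is the threshold; glucose at or below it is classified as
  fasting. The fed window runs from the first eating occasion to the last
  occasion plus 4 h of postprandial buffer.
* *Supervised models* (SVM-RBF, random forest, MLP, kNN, decision tree,
  logistic regression, linear SGD) trained on the window features after
  SMOTE+Tomek rebalancing and min-max scaling, with a rolling majority vote
  (k = 5 windows, i.e. 75 min) smoothing the chronological prediction
  sequence.

**Explanations.** Exact Shapley values by full coalition enumeration
(interventional expectation over a background sample), satisfying
`baseline + sum(phi) = f(x)` to 1e-10.

**Adherence.** Per-day eating-window duration compliance (8 h + 30 min,
inclusive) and clock-frame compliance (prescribed frame ± 30 min) with
per-participant compliance percentages.

## Worked example

```r
library(fastsense)

cfg <- sim_config("eTRE", n_days = 14, seed = 42)   # eating 08:00-16:00
rec <- simulate_participant(cfg, "P01")
rec
#> <participant_record P01 | eTRE | 1344 CGM points | 36 meals | accel: 1,209,600>

ev <- hutchison_eval(rec, truth = "fed_window")
attr(ev, "model")
#> <hutchison_model P01/eTRE: threshold 87.94 mg/dL (n = 828 fasting samples)>
ev
#> <eval_report n=1344 | accuracy 0.688 | smoothed 0.700 | precision 0.552 | recall 0.996 | F1 0.710 (0.678-0.734)>

glucose_window_features(c(90, 110, 100))
#> glucose_mean  glucose_sd  glucose_cv  glucose_j_index  glucose_max  glucose_min
#>    100.00000     8.16497     8.16497          0.10816    110.00000     90.00000
```

The threshold lands just below the 90 mg/dL fasting baseline (night-time
glucose runs slightly under it), and the heuristic reaches ~0.69 per-timestamp
accuracy against its fed/fasting partition — glucose alone cannot place the
eating window precisely, which is why the supervised models add acceleration
features. The window features reproduce the printed formulas exactly
(population SD; J-index `0.001 * (100 + 8.16497) = 0.10816`).

The full comparison — every supervised model plus the heuristic, one table
sorted by smoothed accuracy, with Shapley attributions and adherence reports
— comes from one call:

```r
res <- run_end_to_end(pipeline_config(
  sim = sim_config("eTRE", n_days = 14, seed = 42), n_participants = 10,
  models = list(model_spec("svm_rbf"), model_spec("logistic"))))
res$comparison
```

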