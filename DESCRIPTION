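Package: fastsense
Title: Fasting-State Detection and Time-Restricted-Eating Adherence from
    Wearable Sensor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating adherence to intermittent-fasting regimes
    from multimodal wearable sensor streams: continuous glucose monitoring
    (15-min cadence), wrist actigraphy (1 Hz) and meal logs. Provides a
    synthetic cohort simulator with known ground truth covering early and
    late time-restricted eating, self-selected windows, religious dry
    fasting and habitual eating (plus a type-1-diabetes bolus-undershoot
    mode); CSV ingestion and harmonization onto the glucose grid; 45-minute
    sliding-window glycemic (mean, SD, intraday CV, J-index, extrema) and
    acceleration (axis statistics, signal energy, step counts, peak counts)
    features with recursive feature elimination; fasting-state classifiers
    (a personalized fasting-glucose threshold heuristic and supervised
    models with SMOTE+Tomek rebalancing, min-max scaling and majority-vote
    label smoothing); exact Shapley-value attributions; and per-day
    eating-duration and clock-frame adherence scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    nnet,
    randomForest,
    rpart,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
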