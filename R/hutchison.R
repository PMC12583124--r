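# Personalized fasting-glucose threshold heuristic.

#' Fed and fasting windows of a meal log
#'
#' For each day with occasions, the fed window runs from the first occasion
#' start to the last occasion end plus `postprandial_hours` (default 4 h, the
#' postprandial buffer); the fasting windows are the complement within the
#' record span, i.e. they begin 4 h after the latest meal and run to the next
#' day's first occasion. Days without occasions fall entirely on the fasting
#' side and are flagged.
#'
#' @param meals A [meal_log()] for one participant.
#' @param span Optional POSIXct `c(start, end)` of the record; defaults to
#'   midnight of the first meal day to midnight after the last.
#' @param postprandial_hours Buffer appended to the last occasion, hours.
#' @return List with data frames `fed` and `fasting` (columns start, end;
#'   half-open intervals) and `flagged_days` (dates without occasions).
#' @export
fed_fasting_windows <- function(meals, span = NULL, postprandial_hours = 4) {
  if (!nrow(meals)) stop_user("meal log has no occasions")
  if (is.null(span)) {
    span <- c(day_start(min(meals$start)),
              day_start(max(meals$end)) + 86400)
  }
  day <- as.Date(meals$start, tz = "UTC")
  fed <- do.call(rbind, lapply(unique(day), function(d) {
    occ <- day == d
    data.frame(start = min(meals$start[occ]),
               end = max(meals$end[occ]) + postprandial_hours * 3600)
  }))
  fed <- fed[order(fed$start), , drop = FALSE]
  # clip to span and merge overlapping fed windows (late dinners cross midnight)
  fed$start <- pmax(fed$start, span[1])
  fed$end <- pmin(fed$end, span[2])
  merged <- fed[1, , drop = FALSE]
  for (i in seq_len(nrow(fed))[-1]) {
    if (fed$start[i] <= merged$end[nrow(merged)]) {
      merged$end[nrow(merged)] <- max(merged$end[nrow(merged)], fed$end[i])
    } else merged <- rbind(merged, fed[i, ])
  }
  # fasting = complement of fed within the span
  bounds <- c(span[1], rbind(merged$start, merged$end), span[2])
  starts <- bounds[seq(1, length(bounds) - 1, by = 2)]
  ends <- bounds[seq(2, length(bounds), by = 2)]
  keep <- ends > starts
  all_days <- seq(as.Date(span[1]), as.Date(span[2] - 1), by = "day")
  structure(list(fed = merged,
                 fasting = data.frame(start = as_utc(starts[keep]),
                                      end = as_utc(ends[keep])),
                 flagged_days = setdiff(all_days, unique(day))),
            class = "fed_fasting_windows")
}

in_intervals <- function(ts, intervals) {
  hit <- rep(FALSE, length(ts))
  for (i in seq_len(nrow(intervals)))
    hit <- hit | (ts >= intervals$start[i] & ts < intervals$end[i])
  hit
}

#' Fit the personalized fasting-glucose threshold
#'
#' The threshold is the arithmetic mean of all glucose samples falling in
#' the fasting windows (beginning `postprandial_hours` after each day's last
#' meal), pooled across all days of the condition.
#'
#' @param glucose A [glucose_series()] or `data.frame(timestamp, glucose)`.
#' @param meals A [meal_log()] for the same participant and condition.
#' @param condition Condition tag stored on the model.
#' @param participant_id Participant tag; defaults to the series attribute.
#' @param postprandial_hours Fed-window buffer, hours.
#' @return A `hutchison_model`: participant_id, condition, threshold
#'   (mg/dL), n_fasting_samples.
#' @export
fit_hutchison <- function(glucose, meals, condition = NULL,
                          participant_id = NULL, postprandial_hours = 4) {
  win <- fed_fasting_windows(meals,
                             span = c(min(glucose$timestamp), max(glucose$timestamp) + 1),
                             postprandial_hours = postprandial_hours)
  mask <- in_intervals(glucose$timestamp, win$fasting)
  if (!any(mask)) stop_user("no glucose samples fall in a fasting window")
  structure(list(participant_id = participant_id %||%
                   attr(glucose, "participant_id") %||% NA_character_,
                 condition = condition %||% attr(meals, "condition") %||% NA_character_,
                 threshold = mean(glucose$glucose[mask]),
                 n_fasting_samples = sum(mask)),
            class = "hutchison_model")
}

#' @export
print.hutchison_model <- function(x, ...) {
  cat(sprintf("<hutchison_model %s/%s: threshold %.2f mg/dL (n = %d fasting samples)>\n",
              x$participant_id, x$condition, x$threshold, x$n_fasting_samples))
  invisible(x)
}

#' Predict fasting state from the threshold
#'
#' Glucose at or below `threshold + margin` is classified `fasting`
#' (equality ties resolve to fasting), above it `non_fasting`.
#'
#' @param model A `hutchison_model`.
#' @param values Glucose values, mg/dL.
#' @param margin Decision margin added to the threshold, mg/dL.
#' @return Factor of fasting labels.
#' @export
predict_hutchison <- function(model, values, margin = 0) {
  stopifnot(inherits(model, "hutchison_model"))
  as_state_factor(ifelse(values <= model$threshold + margin,
                         "fasting", "non_fasting"))
}

#' Fit, predict and score the heuristic on one record
#'
#' Fits the threshold on the record's own glucose and meal log, predicts per
#' 15-min grid point, and scores against the record's eating-window ground
#' truth, optionally after majority-vote smoothing.
#'
#' @param record A `participant_record` (accelerometry not required).
#' @param margin Decision margin, mg/dL.
#' @param k_smooth Odd smoothing window for the smoothed accuracy, or `NULL`
#'   to skip smoothing.
#' @param truth Ground truth to score against: `"eating_window"` uses the
#'   record's daily-eating-window labels (comparable to the supervised
#'   models), `"fed_window"` uses the heuristic's own fed/fasting partition
#'   (fed = first occasion to last occasion + 4 h), the frame in which
#'   insulin-driven glucose dips manifest as misclassified fed hours.
#' @param bootstrap_n,seed Passed to [evaluate()].
#' @return An `eval_report` (see [evaluate()]); the fitted model is attached
#'   as attribute `model`.
#' @export
hutchison_eval <- function(record, margin = 0, k_smooth = 5,
                           truth = c("eating_window", "fed_window"),
                           bootstrap_n = 200L, seed = 1L) {
  truth <- match.arg(truth)
  model <- fit_hutchison(record$glucose, record$meals,
                         condition = record$condition,
                         participant_id = record$participant_id)
  y_true <- if (truth == "eating_window") record$truth$label else {
    win <- fed_fasting_windows(record$meals,
                               span = c(min(record$glucose$timestamp),
                                        max(record$glucose$timestamp) + 1))
    as_state_factor(ifelse(in_intervals(record$glucose$timestamp, win$fed),
                           "non_fasting", "fasting"))
  }
  pred <- predict_hutchison(model, record$glucose$glucose, margin = margin)
  smoothed <- if (is.null(k_smooth)) NULL else smooth_labels(pred, k = k_smooth)
  rep <- evaluate(y_true, pred, smoothed,
                  bootstrap_n = bootstrap_n, seed = seed)
  attr(rep, "model") <- model
  rep
}

#' Serialize a Hutchison model to JSON
#'
#' @param model A `hutchison_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hutchison_json <- function(model, path) {
  stopifnot(inherits(model, "hutchison_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a Hutchison model from JSON
#'
#' @param path JSON file written by [write_hutchison_json()].
#' @return A `hutchison_model`.
#' @export
read_hutchison_json <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "hutchison_model")
}
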