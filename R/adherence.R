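# Eating-duration and clock-frame adherence scoring.

#' Daily eating window
#'
#' The day's eating window, either from a meal log (first occasion start to
#' last occasion end) or from a predicted fasting-label sequence on the
#' 15-min grid (first to last `non_fasting` timestamp of the date, the end
#' extended by one grid step to close the half-open bin).
#'
#' @param source A [meal_log()], or a `data.frame(timestamp, label)` of
#'   predicted labels on the glucose grid.
#' @param date A `Date` (or coercible).
#' @param step_minutes Grid step used when `source` is a label sequence.
#' @return `list(start, end, duration_minutes)` or `NULL` when the day has
#'   no eating.
#' @export
daily_eating_window <- function(source, date, step_minutes = 15) {
  date <- as.Date(date)
  if (inherits(source, "meal_log")) {
    day <- as.Date(source$start, tz = "UTC")
    occ <- which(day == date)
    if (!length(occ)) return(NULL)
    s <- min(source$start[occ]); e <- max(source$end[occ])
  } else {
    stopifnot(all(c("timestamp", "label") %in% names(source)))
    day <- as.Date(source$timestamp, tz = "UTC")
    idx <- which(day == date & as.character(source$label) == "non_fasting")
    if (!length(idx)) return(NULL)
    s <- source$timestamp[min(idx)]
    e <- source$timestamp[max(idx)] + step_minutes * 60
  }
  list(start = s, end = e,
       duration_minutes = as.numeric(difftime(e, s, units = "mins")))
}

#' Eating-duration compliance
#'
#' A day is duration-compliant when its eating window does not exceed the
#' prescribed duration plus tolerance (default 8 h + 30 min = 510 min,
#' boundary inclusive). `strict = TRUE` additionally penalizes windows
#' shorter than the prescription minus tolerance (two-sided 480 +/- 30 min).
#'
#' @param duration_minutes Eating-window duration, minutes (>= 0).
#' @param target_hours Prescribed eating duration, hours.
#' @param tolerance_minutes Allowed slack, minutes.
#' @param strict Two-sided check.
#' @return Logical.
#' @export
#' @examples
#' duration_compliance(c(475, 510, 511)) # TRUE TRUE FALSE
duration_compliance <- function(duration_minutes, target_hours = 8,
                                tolerance_minutes = 30, strict = FALSE) {
  stopifnot(all(duration_minutes >= 0))
  upper <- duration_minutes <= target_hours * 60 + tolerance_minutes
  if (!strict) return(upper)
  upper & duration_minutes >= target_hours * 60 - tolerance_minutes
}

#' Clock-frame compliance
#'
#' A day complies with a prescribed eating time frame when its window starts
#' no earlier than `prescribed_start - tolerance` and ends no later than
#' `prescribed_end + tolerance` (clock times).
#'
#' @param window_start,window_end POSIXct bounds of the day's eating window.
#' @param prescribed_start,prescribed_end Prescribed clock bounds, "HH:MM"
#'   or minutes after midnight.
#' @param tolerance_minutes Allowed slack, minutes.
#' @return Logical.
#' @export
timeframe_compliance <- function(window_start, window_end,
                                 prescribed_start, prescribed_end,
                                 tolerance_minutes = 30) {
  ps <- hm_to_minutes(prescribed_start)
  pe <- hm_to_minutes(prescribed_end)
  if (ps >= pe) stop_user("prescribed start must precede prescribed end")
  ws <- minute_of_day(window_start)
  we <- minute_of_day(window_end)
  we[we == 0 & minute_of_day(window_start) > 0] <- 1440 # window ending at midnight
  ws >= ps - tolerance_minutes & we <= pe + tolerance_minutes
}

#' Prescribed clock frame of a regime
#'
#' @param regime Regime name.
#' @return `c(start, end)` in "HH:MM", or `NULL` for regimes without a
#'   prescribed frame (self-selected, religious dry, habitual).
#' @export
prescribed_timeframe <- function(regime) {
  switch(regime,
    eTRE = c("08:00", "16:00"),
    lTRE = c("13:00", "21:00"),
    NULL)
}

#' Per-day and per-participant adherence report
#'
#' Scores each day's eating window (from the meal log, or from a predicted
#' label sequence such as the smoothed classifier output) against the
#' duration rule and, for regimes with a prescribed clock frame (eTRE,
#' lTRE), the time-frame rule. A day is compliant when it satisfies the
#' duration rule and, where applicable, the frame rule.
#' `percent_compliant_days` counts compliant days among days that have an
#' eating window; window-less days are excluded from the denominator and
#' flagged.
#'
#' @param source A [meal_log()] or `data.frame(timestamp, label)` (see
#'   [daily_eating_window()]).
#' @param regime Regime name (determines the prescribed frame).
#' @param dates Dates to score; defaults to all dates in `source`.
#' @param target_hours,tolerance_minutes,strict Passed to the compliance
#'   rules.
#' @param participant_id Reported identifier.
#' @return An `adherence_report`: participant_id, regime, `days` data
#'   frame (date, window_start, window_end, duration_minutes,
#'   duration_compliant, timeframe_compliant, compliant),
#'   `percent_compliant_days`, `n_days_without_window`.
#' @export
#' @examples
#' ml <- meal_log("P01",
#'   start = as.POSIXct("2024-03-01 08:10", tz = "UTC"),
#'   end = as.POSIXct("2024-03-01 16:05", tz = "UTC"))
#' adherence_report(ml, "eTRE")
adherence_report <- function(source, regime, dates = NULL, target_hours = 8,
                             tolerance_minutes = 30, strict = FALSE,
                             participant_id = NULL) {
  if (is.null(dates)) {
    ts <- if (inherits(source, "meal_log")) source$start else source$timestamp
    dates <- sort(unique(as.Date(ts, tz = "UTC")))
  }
  frame <- prescribed_timeframe(regime)
  rows <- lapply(dates, function(d) {
    w <- daily_eating_window(source, d)
    if (is.null(w)) {
      return(data.frame(date = d, window_start = as_utc(NA), window_end = as_utc(NA),
                        duration_minutes = NA_real_, duration_compliant = NA,
                        timeframe_compliant = NA, compliant = NA))
    }
    dc <- duration_compliance(w$duration_minutes, target_hours,
                              tolerance_minutes, strict)
    tc <- if (is.null(frame)) NA else
      timeframe_compliance(w$start, w$end, frame[1], frame[2], tolerance_minutes)
    data.frame(date = d, window_start = w$start, window_end = w$end,
               duration_minutes = w$duration_minutes, duration_compliant = dc,
               timeframe_compliant = tc,
               compliant = dc & (is.na(tc) | tc))
  })
  days <- do.call(rbind, rows)
  scored <- !is.na(days$compliant)
  if (!any(scored)) stop_user("no days with an eating window")
  pid <- participant_id %||%
    (if (inherits(source, "meal_log")) source$participant_id[1] else NA_character_)
  structure(list(participant_id = pid, regime = regime, days = days,
                 percent_compliant_days = 100 * sum(days$compliant[scored]) / sum(scored),
                 n_days_without_window = sum(!scored)),
            class = "adherence_report")
}

#' @export
print.adherence_report <- function(x, ...) {
  cat(sprintf("<adherence_report %s | %s | %d scored days | %.1f%% compliant>\n",
              x$participant_id, x$regime, sum(!is.na(x$days$compliant)),
              x$percent_compliant_days))
  invisible(x)
}

#' Serialize an adherence report to JSON
#'
#' @param report An `adherence_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_adherence_json <- function(report, path) {
  stopifnot(inherits(report, "adherence_report"))
  out <- unclass(report)
  out$days$date <- as.character(out$days$date)
  out$days$window_start <- format(out$days$window_start, "%Y-%m-%d %H:%M:%S")
  out$days$window_end <- format(out$days$window_end, "%Y-%m-%d %H:%M:%S")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
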