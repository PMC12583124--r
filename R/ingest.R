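# Domain containers -----------------------------------------------------

#' Glucose series container
#'
#' Timestamped CGM trace at nominal 15-min cadence. Timestamps must be
#' strictly increasing; values must lie in the physiological sensor range
#' 40–500 mg/dL.
#'
#' @param participant_id Participant identifier.
#' @param timestamp POSIXct vector, strictly increasing.
#' @param glucose mg/dL values.
#' @return A `glucose_series` data frame (timestamp, glucose).
#' @export
glucose_series <- function(participant_id, timestamp, glucose) {
  stopifnot(length(timestamp) == length(glucose))
  if (length(timestamp) && any(diff(as.numeric(timestamp)) <= 0))
    stop_user("glucose timestamps must be strictly increasing")
  if (any(glucose < 40 | glucose > 500, na.rm = TRUE))
    stop_user("glucose values outside [40, 500] mg/dL")
  structure(data.frame(timestamp = timestamp, glucose = glucose),
            participant_id = participant_id,
            class = c("glucose_series", "data.frame"))
}

#' Actigraphy series container
#'
#' 1 Hz multichannel activity trace. The vector magnitude is computed as
#' `sqrt(x^2 + y^2 + z^2)` when not supplied.
#'
#' @param participant_id Participant identifier.
#' @param timestamp POSIXct vector, strictly increasing.
#' @param x,y,z Axis accelerations, g-units.
#' @param steps Per-second step counts (non-negative integers).
#' @param lux Optional light level.
#' @param vector_magnitude Optional; derived from the axes when `NULL`.
#' @return An `accel_series` data frame.
#' @export
accel_series <- function(participant_id, timestamp, x, y, z,
                         steps = NULL, lux = NULL, vector_magnitude = NULL) {
  n <- length(timestamp)
  stopifnot(length(x) == n, length(y) == n, length(z) == n)
  if (n && any(diff(as.numeric(timestamp)) <= 0))
    stop_user("accel timestamps must be strictly increasing")
  steps <- steps %||% rep(0L, n)
  if (any(steps < 0) || any(steps != as.integer(steps)))
    stop_user("steps must be non-negative integers")
  vm <- vector_magnitude %||% sqrt(x^2 + y^2 + z^2)
  if (any(vm < 0)) stop_user("vector_magnitude must be >= 0")
  df <- data.frame(timestamp = timestamp, x = x, y = y, z = z,
                   steps = as.integer(steps), vector_magnitude = vm)
  df$lux <- if (is.null(lux)) NA_real_ else lux
  structure(df, participant_id = participant_id,
            class = c("accel_series", "data.frame"))
}

#' Meal log container
#'
#' Eating occasions per participant. Occasions must satisfy start < end and
#' are stored sorted; overlapping occasions within a participant are merged
#' (union) by the reader.
#'
#' @param participant_id Participant identifier (scalar or per-occasion).
#' @param start,end POSIXct occasion bounds.
#' @param condition Optional study condition tag.
#' @return A `meal_log` data frame (participant_id, start, end).
#' @export
meal_log <- function(participant_id, start, end, condition = NULL) {
  stopifnot(length(start) == length(end))
  if (any(end <= start)) stop_user("meal occasions require start < end")
  o <- order(start)
  structure(data.frame(participant_id = rep_len(participant_id, length(start))[o],
                       start = start[o], end = end[o]),
            condition = condition,
            class = c("meal_log", "data.frame"))
}

# CSV readers ------------------------------------------------------------

parse_datetime <- function(x, format = NULL) {
  x <- as.character(x)
  fmts <- if (!is.null(format)) format else
    c("%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M",
      "%d.%m.%Y %H:%M:%S", "%d.%m.%Y %H:%M", "%m/%d/%Y %H:%M")
  best <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC", origin = "1970-01-01")
  for (f in fmts) {
    miss <- is.na(best)
    if (!any(miss)) break
    best[miss] <- as_utc(x[miss], format = f)
  }
  best
}

parse_numeric <- function(x, dec = ".") {
  if (is.numeric(x)) return(x)
  x <- as.character(x)
  if (dec == ",") x <- gsub(",", ".", x, fixed = TRUE)
  suppressWarnings(as.numeric(x))
}

#' Read a CGM export CSV
#'
#' Reads a FreeStyle-Libre-style CSV export with at least a timestamp and a
#' glucose column. Column names, datetime format, delimiter and decimal mark
#' are configurable; rows that fail to parse are dropped and counted in the
#' `parse_report` attribute; duplicated timestamps keep the first row;
#' glucose outside 40–500 mg/dL is dropped with a warning.
#'
#' @param path CSV file path.
#' @param timestamp_col,glucose_col Column names.
#' @param datetime_format Optional `strptime` format(s); common ISO and
#'   European dialects are tried by default.
#' @param sep Field delimiter (`"auto"` sniffs).
#' @param dec Decimal mark, `"."` or `","`.
#' @return A [glucose_series()] sorted by time, with attribute
#'   `parse_report` (list of row counts).
#' @export
read_cgm_csv <- function(path, timestamp_col = "timestamp", glucose_col = "glucose",
                         datetime_format = NULL, sep = "auto", dec = ".") {
  dt <- data.table::fread(path, sep = sep, colClasses = "character", data.table = FALSE)
  if (!nrow(dt)) stop_user("empty CGM file: ", path)
  for (col in c(timestamp_col, glucose_col))
    if (!col %in% names(dt)) stop_user("CGM file lacks column '", col, "'")
  ts <- parse_datetime(dt[[timestamp_col]], datetime_format)
  gl <- parse_numeric(dt[[glucose_col]], dec)
  ok <- !is.na(ts) & !is.na(gl)
  n_parse_dropped <- sum(!ok)
  ts <- ts[ok]; gl <- gl[ok]
  in_range <- gl >= 40 & gl <= 500
  n_range_dropped <- sum(!in_range)
  if (n_range_dropped)
    warning(n_range_dropped, " glucose rows outside [40, 500] mg/dL dropped")
  ts <- ts[in_range]; gl <- gl[in_range]
  o <- order(ts)
  ts <- ts[o]; gl <- gl[o]
  dup <- duplicated(ts)
  n_dup <- sum(dup)
  ts <- ts[!dup]; gl <- gl[!dup]
  if (!length(ts)) stop_user("no parseable CGM rows in ", path)
  out <- glucose_series(participant_id = NA_character_, ts, gl)
  attr(out, "parse_report") <- list(n_raw = nrow(dt), n_parse_dropped = n_parse_dropped,
                                    n_range_dropped = n_range_dropped, n_duplicates = n_dup)
  out
}

#' Read an actigraphy export CSV
#'
#' Reads a 1 Hz accelerometer CSV export (timestamp, x, y, z, steps, lux,
#' vector magnitude). The vector magnitude is computed from the axes when the
#' column is absent; a file missing the x, y and z columns is an error.
#'
#' @inheritParams read_cgm_csv
#' @param cols Named list mapping the expected channels (`timestamp`, `x`,
#'   `y`, `z`, `steps`, `lux`, `vector_magnitude`) to file column names.
#' @return An [accel_series()] sorted by time.
#' @export
read_actigraphy_csv <- function(path, cols = list(), datetime_format = NULL,
                                sep = "auto", dec = ".") {
  defaults <- list(timestamp = "timestamp", x = "x", y = "y", z = "z",
                   steps = "steps", lux = "lux", vector_magnitude = "vector_magnitude")
  cols <- utils::modifyList(defaults, cols)
  dt <- data.table::fread(path, sep = sep, colClasses = "character", data.table = FALSE)
  if (!nrow(dt)) stop_user("empty actigraphy file: ", path)
  if (!all(c(cols$x, cols$y, cols$z) %in% names(dt)))
    stop_user("actigraphy file lacks x/y/z acceleration columns")
  ts <- parse_datetime(dt[[cols$timestamp]], datetime_format)
  num <- function(col) if (col %in% names(dt)) parse_numeric(dt[[col]], dec) else NULL
  x <- num(cols$x); y <- num(cols$y); z <- num(cols$z)
  ok <- !is.na(ts) & !is.na(x) & !is.na(y) & !is.na(z)
  o <- order(ts[ok])
  idx <- which(ok)[o]
  steps <- num(cols$steps)
  accel_series(NA_character_, ts[idx], x[idx], y[idx], z[idx],
               steps = if (is.null(steps)) NULL else as.integer(round(steps[idx])),
               lux = (num(cols$lux) %||% rep(NA_real_, length(ts)))[idx],
               vector_magnitude = if (cols$vector_magnitude %in% names(dt))
                 num(cols$vector_magnitude)[idx] else NULL)
}

#' Read a meal log CSV
#'
#' Accepts `(participant, start, end)` or `(participant, start,
#' duration_minutes)` layouts. Rows with `end <= start` are rejected with a
#' warning; overlapping occasions of one participant are merged to their
#' union.
#'
#' @inheritParams read_cgm_csv
#' @param participant_col,start_col,end_col,duration_col Column names.
#' @return A [meal_log()] (possibly covering several participants), sorted by
#'   participant and start.
#' @export
read_meal_log <- function(path, participant_col = "participant_id",
                          start_col = "start", end_col = "end",
                          duration_col = "duration_minutes",
                          datetime_format = NULL, sep = "auto") {
  dt <- data.table::fread(path, sep = sep, colClasses = "character", data.table = FALSE)
  if (!nrow(dt)) stop_user("empty meal log: ", path)
  start <- parse_datetime(dt[[start_col]], datetime_format)
  end <- if (end_col %in% names(dt)) parse_datetime(dt[[end_col]], datetime_format)
         else start + 60 * parse_numeric(dt[[duration_col]])
  pid <- if (participant_col %in% names(dt)) dt[[participant_col]] else NA_character_
  ok <- !is.na(start) & !is.na(end)
  bad <- ok & end <= start
  if (any(bad)) warning(sum(bad), " meal rows with end <= start rejected")
  keep <- ok & !bad
  if (!any(keep)) stop_user("no valid meal rows in ", path)
  merged <- merge_occasions(pid[keep], start[keep], end[keep])
  structure(merged, class = c("meal_log", "data.frame"))
}

# Union of overlapping occasions, per participant.
merge_occasions <- function(pid, start, end) {
  out <- lapply(split(seq_along(start), pid), function(idx) {
    o <- idx[order(start[idx])]
    s <- start[o]; e <- end[o]
    ms <- s[1]; me <- e[1]; rs <- c(); re <- c()
    for (i in seq_along(s)[-1]) {
      if (s[i] <= me) me <- max(me, e[i])
      else { rs <- c(rs, ms); re <- c(re, me); ms <- s[i]; me <- e[i] }
    }
    data.frame(participant_id = pid[o[1]],
               start = as_utc(c(rs, ms)), end = as_utc(c(re, me)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$participant_id, out$start), , drop = FALSE]
}

# Harmonization ----------------------------------------------------------

#' Snap CGM readings onto a 15-min midnight-anchored grid
#'
#' Builds the uniform grid covering the series (anchored at midnight of the
#' first day) and assigns each reading to its nearest grid point when within
#' `tolerance_s` seconds; grid points without a reading are gaps (NA).
#'
#' @param glucose A [glucose_series()].
#' @param grid_minutes Grid spacing, minutes.
#' @param tolerance_s Snap tolerance, seconds.
#' @return `data.frame(timestamp, glucose)` on the uniform grid.
#' @export
snap_to_grid <- function(glucose, grid_minutes = 15, tolerance_s = 120) {
  ts <- as.numeric(glucose$timestamp)
  anchor <- as.numeric(day_start(glucose$timestamp[1]))
  step <- grid_minutes * 60
  last <- as.numeric(day_start(glucose$timestamp[length(ts)])) + 86400 - step
  grid <- seq(anchor, max(last, anchor), by = step)
  slot <- round((ts - anchor) / step)
  okslot <- slot >= 0 & slot < length(grid) & abs(ts - (anchor + slot * step)) <= tolerance_s
  vals <- rep(NA_real_, length(grid))
  keep <- which(okslot)[!duplicated(slot[okslot])] # first reading wins
  vals[slot[keep] + 1] <- glucose$glucose[keep]
  data.frame(timestamp = as_utc(grid, origin = "1970-01-01"), glucose = vals)
}

#' Downsample 1 Hz actigraphy onto the glucose grid
#'
#' Aggregates the accelerometer channels into the half-open grid bins
#' `[t, t + step)`: mean of x, y, z, vector magnitude and lux; sum of steps.
#' Bins containing no accelerometer sample are missing (NA) and flagged via
#' `n_samples = 0`.
#'
#' @param accel An [accel_series()].
#' @param grid POSIXct grid timestamps (uniform spacing, at least the accel
#'   spacing).
#' @return Data frame with one row per grid point: aggregated channels and
#'   `n_samples`.
#' @export
downsample_accel <- function(accel, grid) {
  gs <- as.numeric(grid)
  step <- if (length(gs) > 1) gs[2] - gs[1] else 900
  ats <- as.numeric(accel$timestamp)
  idx <- findInterval(ats, gs)
  inb <- idx >= 1 & ats < gs[pmin(idx, length(gs))] + step & ats >= gs[1]
  idx <- idx[inb]
  n <- length(gs)
  counts <- tabulate(idx, nbins = n)
  agg_mean <- function(v) {
    s <- rep(NA_real_, n)
    r <- rowsum(v[inb], idx, reorder = TRUE)
    s[as.integer(rownames(r))] <- r[, 1]
    out <- s / counts
    out[counts == 0] <- NA_real_
    out
  }
  agg_sum <- function(v) {
    s <- rep(NA_real_, n)
    r <- rowsum(as.numeric(v[inb]), idx, reorder = TRUE)
    s[as.integer(rownames(r))] <- r[, 1]
    s[counts == 0] <- NA_real_
    s
  }
  data.frame(timestamp = grid,
             x = agg_mean(accel$x), y = agg_mean(accel$y), z = agg_mean(accel$z),
             vector_magnitude = agg_mean(accel$vector_magnitude),
             lux = agg_mean(accel$lux),
             steps = agg_sum(accel$steps),
             n_samples = counts)
}

#' Label fasting state from a meal log
#'
#' For each day with logged occasions, grid points on the closed interval
#' from the first occasion start to the last occasion end are `non_fasting`
#' (both boundary timestamps inclusive); all other points, and all points of
#' days without occasions, are `fasting`. This is the daily-eating-window
#' label used as classification ground truth; it deliberately carries no
#' postprandial buffer (the 4-h buffer belongs to the threshold heuristic's
#' fed window, see [fed_fasting_windows()]).
#'
#' @param grid POSIXct timestamps to label.
#' @param meals A [meal_log()] for one participant.
#' @return Factor with levels `fasting`, `non_fasting`, one per grid point.
#' @export
label_fasting_state <- function(grid, meals) {
  lab <- rep("fasting", length(grid))
  if (nrow(meals)) {
    day <- as.Date(meals$start, tz = "UTC")
    for (d in unique(day)) {
      occ <- which(day == d)
      fs <- min(meals$start[occ]); le <- max(meals$end[occ])
      lab[grid >= fs & grid <= le] <- "non_fasting"
    }
  }
  as_state_factor(lab)
}

#' Join the harmonized streams into one aligned dataset
#'
#' Inner-joins the aggregated accelerometer channels onto the glucose grid
#' and attaches the fasting labels. Grid points lacking accelerometer data
#' carry NA channel values (downstream windowing drops windows touching
#' them).
#'
#' @param glucose `data.frame(timestamp, glucose)` on the grid (see
#'   [snap_to_grid()]).
#' @param accel_agg Output of [downsample_accel()] on the same grid, or
#'   `NULL` for glucose-only analyses.
#' @param labels Factor of fasting labels, one per grid point.
#' @param participant_id,condition Metadata attached as attributes.
#' @return An `aligned_dataset` data frame.
#' @export
align_streams <- function(glucose, accel_agg, labels,
                          participant_id = NA_character_, condition = NA_character_) {
  n <- nrow(glucose)
  stopifnot(length(labels) == n)
  out <- data.frame(timestamp = glucose$timestamp, glucose = glucose$glucose)
  if (!is.null(accel_agg)) {
    if (!any(accel_agg$n_samples > 0))
      stop_user("glucose and accelerometer streams do not overlap in time")
    m <- match(as.numeric(out$timestamp), as.numeric(accel_agg$timestamp))
    for (col in c("x", "y", "z", "vector_magnitude", "lux", "steps"))
      out[[col]] <- accel_agg[[col]][m]
    out$accel_n <- ifelse(is.na(m), 0L, accel_agg$n_samples[m])
  }
  out$label <- labels
  structure(out, participant_id = participant_id, condition = condition,
            class = c("aligned_dataset", "data.frame"))
}

#' Harmonize one participant's raw streams
#'
#' Convenience orchestration of [snap_to_grid()], [downsample_accel()],
#' [label_fasting_state()] and [align_streams()].
#'
#' @param glucose A [glucose_series()].
#' @param accel An [accel_series()] or `NULL`.
#' @param meals A [meal_log()].
#' @param participant_id,condition Metadata.
#' @param grid_minutes Grid spacing, minutes.
#' @return An `aligned_dataset`.
#' @export
align_participant <- function(glucose, accel, meals,
                              participant_id = NA_character_,
                              condition = NA_character_, grid_minutes = 15) {
  g <- snap_to_grid(glucose, grid_minutes = grid_minutes)
  agg <- if (is.null(accel)) NULL else downsample_accel(accel, g$timestamp)
  labs <- label_fasting_state(g$timestamp, meals)
  align_streams(g, agg, labs, participant_id = participant_id, condition = condition)
}
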