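#' Simulation configuration
#'
#' Parameters of the synthetic multimodal participant generator. The generator
#' emulates the sensor setup of time-restricted-eating (TRE) trials: a CGM
#' sampling interstitial glucose every 15 minutes, a wrist actigraph sampling
#' acceleration at 1 Hz, and a meal log of eating occasions. Meal timing is
#' constrained by the fasting regime:
#'
#' * `eTRE`   — early TRE, eating confined to 08:00–16:00;
#' * `lTRE`   — late TRE, eating confined to 13:00–21:00;
#' * `selfTRE8h` — a self-selected 8-h eating window (start drawn once per
#'   participant between 07:00 and 14:00);
#' * `religious_dry` — eating only before sunrise and after sunset
#'   (defaults 05:30 / 19:30);
#' * `habitual` — unrestricted eating between 06:00 and 23:00.
#'
#' Glucose is a circadian baseline (24-h sinusoid, trough 03:00) plus one
#' postprandial excursion kernel per meal plus Gaussian sensor noise, floored
#' at 40 mg/dL. In `t1dm_mode` each meal additionally triggers an
#' insulin-bolus undershoot: a negative lobe of depth `bolus_undershoot`
#' centred one decay time after the excursion peak, so glucose transiently
#' dips below the fasting baseline (reactive hypoglycemia) — the behaviour
#' that defeats fasting-glucose threshold heuristics in type-1 diabetes.
#'
#' @param regime Fasting regime, one of `"eTRE"`, `"lTRE"`, `"selfTRE8h"`,
#'   `"religious_dry"`, `"habitual"`.
#' @param n_days Number of simulated days (>= 1).
#' @param baseline_glucose Fasting baseline, mg/dL.
#' @param circadian_amplitude Amplitude of the 24-h sinusoid, mg/dL.
#' @param meal_amplitude Peak height of the postprandial excursion, mg/dL.
#' @param meal_peak_minutes Time from meal start to excursion peak, minutes.
#' @param meal_decay_minutes Exponential decay time constant after the peak,
#'   minutes.
#' @param noise_sd Gaussian sensor noise SD, mg/dL.
#' @param t1dm_mode Logical; add the bolus-undershoot lobe after each meal.
#' @param bolus_undershoot Depth of the undershoot lobe, mg/dL (only used in
#'   `t1dm_mode`).
#' @param activity_day_level Mean acceleration vector magnitude while awake,
#'   g-units.
#' @param activity_night_level Mean vector magnitude during sleep
#'   (23:00–06:00), g-units.
#' @param meal_time_jitter_minutes Uniform jitter applied to scheduled meal
#'   slots, minutes.
#' @param seed Integer RNG seed (`NULL` to use the current RNG state).
#' @param meals_per_day `NULL` to draw 2–4 occasions per day, or a fixed
#'   count (0 allowed as a test hook for meal-free days).
#' @param self_window_start Start of the self-selected window, minutes after
#'   midnight ("HH:MM" accepted); `NULL` draws it per participant.
#' @param sunrise,sunset Clock bounds for `religious_dry` ("HH:MM").
#' @param start_date Calendar date of the first simulated day.
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config("eTRE", n_days = 2, seed = 1)
#' rec <- simulate_participant(cfg, "P01")
sim_config <- function(regime = c("eTRE", "lTRE", "selfTRE8h", "religious_dry", "habitual"),
                       n_days = 14L,
                       baseline_glucose = 90,
                       circadian_amplitude = 5,
                       meal_amplitude = 45,
                       meal_peak_minutes = 45,
                       meal_decay_minutes = 90,
                       noise_sd = 5,
                       t1dm_mode = FALSE,
                       bolus_undershoot = 15,
                       activity_day_level = 0.3,
                       activity_night_level = 0.02,
                       meal_time_jitter_minutes = 20,
                       seed = 1L,
                       meals_per_day = NULL,
                       self_window_start = NULL,
                       sunrise = "05:30",
                       sunset = "19:30",
                       start_date = "2024-03-01") {
  regime <- match.arg(regime)
  if (!is_count(n_days)) stop_user("n_days must be a positive integer")
  nonneg <- c(circadian_amplitude = circadian_amplitude, meal_amplitude = meal_amplitude,
              noise_sd = noise_sd, bolus_undershoot = bolus_undershoot,
              activity_day_level = activity_day_level,
              activity_night_level = activity_night_level,
              meal_time_jitter_minutes = meal_time_jitter_minutes)
  bad <- names(nonneg)[!is.finite(nonneg) | nonneg < 0]
  if (length(bad)) stop_user("parameters must be >= 0: ", paste(bad, collapse = ", "))
  if (meal_peak_minutes <= 0 || meal_decay_minutes <= 0)
    stop_user("meal_peak_minutes and meal_decay_minutes must be positive")
  if (!is.null(meals_per_day) &&
      (length(meals_per_day) != 1L || meals_per_day < 0 || meals_per_day != as.integer(meals_per_day)))
    stop_user("meals_per_day must be NULL or a single non-negative integer")
  structure(list(
    regime = regime, n_days = as.integer(n_days),
    baseline_glucose = baseline_glucose, circadian_amplitude = circadian_amplitude,
    meal_amplitude = meal_amplitude, meal_peak_minutes = meal_peak_minutes,
    meal_decay_minutes = meal_decay_minutes, noise_sd = noise_sd,
    t1dm_mode = isTRUE(t1dm_mode), bolus_undershoot = bolus_undershoot,
    activity_day_level = activity_day_level, activity_night_level = activity_night_level,
    meal_time_jitter_minutes = meal_time_jitter_minutes, seed = seed,
    meals_per_day = meals_per_day,
    self_window_start = if (is.null(self_window_start)) NULL else hm_to_minutes(self_window_start),
    sunrise = hm_to_minutes(sunrise), sunset = hm_to_minutes(sunset),
    start_date = start_date
  ), class = "sim_config")
}

# Admissible meal-time segments (minutes of day) for a regime.
regime_segments <- function(cfg) {
  switch(cfg$regime,
    eTRE = matrix(c(480, 960), nrow = 1),
    lTRE = matrix(c(780, 1260), nrow = 1),
    selfTRE8h = {
      s <- cfg$self_window_start %||% 540 # 09:00 default when not drawn
      matrix(c(s, s + 480), nrow = 1)
    },
    religious_dry = rbind(c(0, cfg$sunrise), c(cfg$sunset, 1439)),
    habitual = matrix(c(360, 1380), nrow = 1)
  )
}

#' Draw one day's eating occasions
#'
#' Schedules 2–4 eating occasions (or `cfg$meals_per_day` if set) inside the
#' regime's admissible clock range. Occasions are placed on evenly spaced
#' slots, given a duration of 10–40 minutes and a uniform start jitter of
#' `+/- meal_time_jitter_minutes`, then clipped into the admissible range.
#' The result is sorted and non-overlapping. Uses the current RNG state; seed
#' beforehand for reproducibility.
#'
#' @param cfg A [sim_config()].
#' @param day_index Zero-based day index in `[0, n_days)`.
#' @return `data.frame(start_min, end_min)`, minutes after the day's
#'   midnight.
#' @export
meal_schedule <- function(cfg, day_index) {
  stopifnot(inherits(cfg, "sim_config"))
  if (day_index < 0 || day_index >= cfg$n_days)
    stop_user("day_index must lie in [0, n_days)")
  m <- cfg$meals_per_day %||% sample(2:4, 1L)
  if (m == 0L) return(data.frame(start_min = numeric(0), end_min = numeric(0)))
  seg <- regime_segments(cfg)
  lens <- seg[, 2] - seg[, 1]
  # distribute occasion slots over segments proportional to their length,
  # at least one slot per segment when enough occasions are available
  k <- if (nrow(seg) == 1L) m else {
    k1 <- max(1L, min(m - 1L, round(m * lens[1] / sum(lens))))
    c(k1, m - k1)
  }
  starts <- ends <- numeric(0)
  for (si in seq_len(nrow(seg))) {
    if (k[si] == 0L) next
    lo <- seg[si, 1]; hi <- seg[si, 2]
    width <- (hi - lo) / k[si]
    centers <- lo + (seq_len(k[si]) - 0.5) * width
    dur <- runif(k[si], 10, 40)
    jit <- runif(k[si], -cfg$meal_time_jitter_minutes, cfg$meal_time_jitter_minutes)
    st <- pmin(pmax(centers - dur / 2 + jit, lo), hi - dur)
    st <- pmax(st, lo) # durations never exceed segment length at defaults
    starts <- c(starts, st)
    ends <- c(ends, pmin(st + dur, hi))
  }
  o <- order(starts)
  starts <- round(starts[o], 2); ends <- round(ends[o], 2)
  # defensive de-overlap for extreme jitter settings
  if (length(starts) > 1L) {
    for (i in 2:length(starts)) {
      if (starts[i] < ends[i - 1]) starts[i] <- ends[i - 1]
    }
    keep <- ends > starts
    starts <- starts[keep]; ends <- ends[keep]
  }
  data.frame(start_min = starts, end_min = ends)
}

#' Postprandial glucose excursion kernel
#'
#' Phenomenological meal response: linear rise from 0 to `meal_amplitude`
#' over `meal_peak_minutes`, then exponential decay with time constant
#' `meal_decay_minutes`. In `t1dm_mode` a negative Gaussian lobe of depth
#' `bolus_undershoot`, centred at `meal_peak_minutes + meal_decay_minutes`
#' with SD `meal_decay_minutes`, is subtracted (ramped in over the rise so
#' the kernel is exactly 0 at `t = 0`), modelling post-bolus reactive
#' hypoglycemia.
#'
#' @param minutes_since_meal Non-negative numeric vector, minutes since meal
#'   start.
#' @param cfg A [sim_config()].
#' @return Glucose increment, mg/dL (negative values possible in
#'   `t1dm_mode`).
#' @export
#' @examples
#' cfg <- sim_config("eTRE")
#' glucose_response(c(0, 45, 500), cfg)
glucose_response <- function(minutes_since_meal, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  t <- minutes_since_meal
  if (any(t < 0)) stop_user("minutes_since_meal must be non-negative")
  pk <- cfg$meal_peak_minutes; dc <- cfg$meal_decay_minutes; A <- cfg$meal_amplitude
  resp <- ifelse(t <= pk, A * t / pk, A * exp(-(t - pk) / dc))
  if (cfg$t1dm_mode) {
    ctr <- pk + dc
    resp <- resp - cfg$bolus_undershoot * exp(-(t - ctr)^2 / (2 * dc^2)) * pmin(1, t / pk)
  }
  resp
}

#' Simulate one participant's multimodal record
#'
#' Generates the coupled streams of one participant: a 15-min CGM trace, a
#' 1 Hz actigraphy trace, the meal log that produced the glucose excursions,
#' and per-CGM-timestamp ground-truth fasting labels (non-fasting on the
#' closed daily interval from first occasion start to last occasion end).
#' Activity is drawn around `activity_day_level` while awake (06:00–23:00)
#' and `activity_night_level` during sleep, with elevated bouts (twice the
#' day level) overlapping eating occasions; per-second step counts are
#' Poisson with rate proportional to the current activity level and zero
#' during sleep.
#'
#' @param cfg A [sim_config()].
#' @param participant_id Participant identifier.
#' @param include_accel Set `FALSE` to skip the (large) 1 Hz actigraphy
#'   stream when only glucose/meals are needed; glucose and meal draws are
#'   unchanged.
#' @return A `participant_record`: list with elements `participant_id`,
#'   `condition`, `glucose` (timestamp, glucose), `accel` (1 Hz channels or
#'   `NULL`), `meals` (participant_id, start, end) and `truth`
#'   (timestamp, label).
#' @export
simulate_participant <- function(cfg, participant_id = "P01", include_accel = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (cfg$regime == "selfTRE8h" && is.null(cfg$self_window_start))
    cfg$self_window_start <- round(runif(1, 420, 840)) # 07:00–14:00
  t0 <- as_utc(cfg$start_date)

  sched <- lapply(seq_len(cfg$n_days) - 1L, function(d) {
    s <- meal_schedule(cfg, d)
    if (nrow(s)) data.frame(start_min = s$start_min + d * 1440,
                            end_min = s$end_min + d * 1440)
    else s
  })
  sched <- do.call(rbind, sched)
  meals <- meal_log(participant_id, # whole seconds so CSV round-trips exactly
                    start = t0 + round(sched$start_min * 60),
                    end = t0 + round(sched$end_min * 60),
                    condition = cfg$regime)

  grid_min <- seq(0, cfg$n_days * 1440 - 15, by = 15)
  grid <- t0 + grid_min * 60
  circ <- -cfg$circadian_amplitude * cos(2 * pi * ((grid_min %% 1440) / 60 - 3) / 24)
  excur <- numeric(length(grid_min))
  for (ms in sched$start_min) {
    idx <- which(grid_min >= ms)
    if (length(idx))
      excur[idx] <- excur[idx] + glucose_response(grid_min[idx] - ms, cfg)
  }
  gl <- cfg$baseline_glucose + circ + excur + rnorm(length(grid_min), 0, cfg$noise_sd)
  gl <- pmax(gl, 40)
  glucose <- glucose_series(participant_id, grid, gl)
  truth <- data.frame(timestamp = grid,
                      label = label_fasting_state(grid, meals))

  accel <- NULL
  if (include_accel) {
    n_sec <- cfg$n_days * 86400L
    sec <- seq.int(0L, n_sec - 1L)
    mod <- sec %% 86400L
    night <- mod >= 23L * 3600L | mod < 6L * 3600L
    level <- ifelse(night, cfg$activity_night_level, cfg$activity_day_level)
    for (i in seq_len(nrow(sched))) { # elevated bouts while eating
      lo <- floor(sched$start_min[i] * 60); hi <- ceiling(sched$end_min[i] * 60)
      idx <- seq.int(max(lo, 0L) + 1L, min(hi, n_sec - 1L) + 1L)
      level[idx] <- 2 * cfg$activity_day_level
    }
    ax <- level / sqrt(3)
    x <- ax * (1 + 0.25 * rnorm(n_sec))
    y <- ax * (1 + 0.25 * rnorm(n_sec))
    z <- ax * (1 + 0.25 * rnorm(n_sec))
    steps <- integer(n_sec)
    wake <- !night
    steps[wake] <- rpois(sum(wake), level[wake])
    lux <- pmax(0, ifelse(night, 0, 180) + rnorm(n_sec, 0, 15))
    accel <- accel_series(participant_id, t0 + sec,
                          x = x, y = y, z = z, steps = steps, lux = lux)
  }

  structure(list(participant_id = participant_id, condition = cfg$regime,
                 config = cfg, glucose = glucose, accel = accel,
                 meals = meals, truth = truth),
            class = "participant_record")
}

#' @export
print.participant_record <- function(x, ...) {
  cat(sprintf("<participant_record %s | %s | %d CGM points | %d meals | accel: %s>\n",
              x$participant_id, x$condition, nrow(x$glucose), nrow(x$meals),
              if (is.null(x$accel)) "none" else format(nrow(x$accel), big.mark = ",")))
  invisible(x)
}

#' Simulate a cohort of participants
#'
#' Per-participant seeds are derived deterministically from `seed`; fasting
#' baselines receive uniform offsets of up to +/- 10 mg/dL to emulate
#' inter-individual variation.
#'
#' @param cfg A [sim_config()] shared by the cohort.
#' @param n_participants Number of participants (>= 1).
#' @param seed Master seed (defaults to `cfg$seed`).
#' @param include_accel Passed to [simulate_participant()].
#' @return List of `participant_record`s, ids `"P01"`, `"P02"`, ...
#' @export
simulate_cohort <- function(cfg, n_participants, seed = cfg$seed, include_accel = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is_count(n_participants)) stop_user("n_participants must be a positive integer")
  set.seed(seed)
  offs <- runif(n_participants, -10, 10)
  seeds <- sample.int(.Machine$integer.max - 1L, n_participants)
  lapply(seq_len(n_participants), function(i) {
    ci <- cfg
    ci$baseline_glucose <- cfg$baseline_glucose + offs[i]
    ci$seed <- seeds[i]
    simulate_participant(ci, sprintf("P%02d", i), include_accel = include_accel)
  })
}

#' Write a participant record as CSV files
#'
#' Emits the same CSV dialects the ingest readers accept, plus the
#' ground-truth label stream: `<id>_cgm.csv` (timestamp, glucose),
#' `<id>_accel.csv` (timestamp, x, y, z, steps, lux, vector_magnitude),
#' `<id>_meals.csv` (participant_id, start, end) and `<id>_labels.csv`
#' (timestamp, label). Round-trips exactly through [read_cgm_csv()],
#' [read_actigraphy_csv()] and [read_meal_log()].
#'
#' @param record A `participant_record`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_participant_csv <- function(record, dir) {
  stopifnot(inherits(record, "participant_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- record$participant_id
  fmt <- function(ts) format(ts, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  paths <- c(cgm = file.path(dir, paste0(id, "_cgm.csv")),
             accel = file.path(dir, paste0(id, "_accel.csv")),
             meals = file.path(dir, paste0(id, "_meals.csv")),
             labels = file.path(dir, paste0(id, "_labels.csv")))
  data.table::fwrite(data.frame(timestamp = fmt(record$glucose$timestamp),
                                glucose = record$glucose$glucose),
                     paths[["cgm"]])
  if (!is.null(record$accel)) {
    a <- record$accel
    data.table::fwrite(data.frame(timestamp = fmt(a$timestamp), x = a$x, y = a$y,
                                  z = a$z, steps = a$steps, lux = a$lux,
                                  vector_magnitude = a$vector_magnitude),
                       paths[["accel"]])
  } else paths <- paths[names(paths) != "accel"]
  data.table::fwrite(data.frame(participant_id = id,
                                start = fmt(record$meals$start),
                                end = fmt(record$meals$end)),
                     paths[["meals"]])
  data.table::fwrite(data.frame(timestamp = fmt(record$truth$timestamp),
                                label = as.character(record$truth$label)),
                     paths[["labels"]])
  invisible(paths)
}
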