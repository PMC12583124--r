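test_that("meal schedules respect the regime's admissible clock range", {
  set.seed(1)
  for (day in 0:9) {
    s <- meal_schedule(sim_config("eTRE", n_days = 10, meal_time_jitter_minutes = 0), day)
    expect_true(all(s$start_min >= 480) && all(s$end_min <= 960))
    s <- meal_schedule(sim_config("lTRE", n_days = 10, meal_time_jitter_minutes = 0), day)
    expect_true(s$start_min[1] >= 780 && s$end_min[nrow(s)] <= 1260)
    s <- meal_schedule(sim_config("habitual", n_days = 10), day)
    expect_true(!is.unsorted(s$start_min) && all(diff(c(rbind(s$start_min, s$end_min))) >= 0))
    cfg <- sim_config("religious_dry", n_days = 10)
    s <- meal_schedule(cfg, day)
    ok <- (s$end_min <= cfg$sunrise) | (s$start_min >= cfg$sunset)
    expect_true(all(ok))
  }
  expect_error(meal_schedule(sim_config("eTRE", n_days = 2), 2), "day_index")
})

test_that("self-selected 8-h regime never exceeds an 8-h daily span", {
  rec <- simulate_participant(sim_config("selfTRE8h", n_days = 14, seed = 5),
                              include_accel = FALSE)
  day <- as.Date(rec$meals$start, tz = "UTC")
  for (d in unique(day)) {
    occ <- day == d
    span <- as.numeric(difftime(max(rec$meals$end[occ]), min(rec$meals$start[occ]),
                                units = "hours"))
    expect_lte(span, 8)
  }
})

test_that("excursion kernel rises to the amplitude and decays to nothing", {
  cfg <- sim_config("eTRE")
  expect_identical(glucose_response(0, cfg), 0)
  expect_equal(glucose_response(cfg$meal_peak_minutes, cfg), cfg$meal_amplitude)
  tail_t <- cfg$meal_peak_minutes + 5 * cfg$meal_decay_minutes
  expect_lt(glucose_response(tail_t, cfg), 0.01 * cfg$meal_amplitude)
  expect_error(glucose_response(-1, cfg), "non-negative")
})

test_that("T1DM mode subtracts a bolus-undershoot lobe that dips below baseline", {
  cfg <- sim_config("eTRE", t1dm_mode = TRUE)
  expect_identical(glucose_response(0, cfg), 0) # ramp keeps the origin fixed
  ctr <- cfg$meal_peak_minutes + cfg$meal_decay_minutes
  base <- sim_config("eTRE")
  expect_equal(glucose_response(ctr, cfg),
               glucose_response(ctr, base) - cfg$bolus_undershoot)
  net <- glucose_response(seq(0, 600), cfg)
  expect_lt(min(net), 0) # reactive hypoglycemia: net kernel crosses baseline
  expect_true(all(glucose_response(seq(0, 600), base) >= 0))
})

test_that("records are bit-identical under the same seed", {
  cfg <- sim_config("eTRE", n_days = 2, seed = 99)
  a <- simulate_participant(cfg, "P01")
  b <- simulate_participant(cfg, "P01")
  expect_identical(a$glucose$glucose, b$glucose$glucose)
  expect_identical(a$accel$x, b$accel$x)
  expect_identical(a$meals$start, b$meals$start)
})

test_that("meal-free records stay at baseline and are labeled all-fasting", {
  cfg <- sim_config("habitual", n_days = 4, seed = 3, meals_per_day = 0L)
  rec <- simulate_participant(cfg, include_accel = FALSE)
  expect_true(all(rec$truth$label == "fasting"))
  n <- nrow(rec$glucose)
  expect_lt(abs(mean(rec$glucose$glucose) - cfg$baseline_glucose),
            3 * cfg$noise_sd / sqrt(n) + cfg$circadian_amplitude / sqrt(n) * 3 + 0.5)
})

test_that("eating windows carry higher glucose than fasting periods", {
  rec <- simulate_participant(sim_config("eTRE", n_days = 7, seed = 2, noise_sd = 0),
                              include_accel = FALSE)
  fed <- rec$truth$label == "non_fasting"
  expect_gt(mean(rec$glucose$glucose[fed]), mean(rec$glucose$glucose[!fed]))
})

test_that("fed-fasting glucose separation is monotone in meal amplitude", {
  sep <- function(seed, amplitude) {
    rec <- simulate_participant(sim_config("eTRE", n_days = 3, seed = seed,
                                           meal_amplitude = amplitude),
                                include_accel = FALSE)
    fed <- rec$truth$label == "non_fasting"
    mean(rec$glucose$glucose[fed]) - mean(rec$glucose$glucose[!fed])
  }
  deltas <- vapply(1:20, function(s) sep(s, 90) - sep(s, 45), numeric(1))
  expect_true(all(deltas >= 0))
})

test_that("simulated series satisfy the grid invariants", {
  rec <- simulate_participant(sim_config("lTRE", n_days = 2, seed = 8))
  expect_true(all(diff(as.numeric(rec$glucose$timestamp)) == 900))
  expect_equal(nrow(rec$glucose), 2 * 96)
  expect_true(all(diff(as.numeric(rec$accel$timestamp)) == 1))
  expect_equal(nrow(rec$accel), 2 * 86400)
  expect_identical(rec$truth$timestamp, rec$glucose$timestamp)
  expect_true(all(rec$accel$vector_magnitude >= 0))
  expect_true(all(rec$accel$steps >= 0))
  expect_true(all(rec$accel$steps[format(rec$accel$timestamp, "%H") %in%
                                    c("23", "00", "01", "02", "03", "04", "05")] == 0))
  # generator labels agree with the ingest labeler by construction
  expect_identical(rec$truth$label,
                   label_fasting_state(rec$glucose$timestamp, rec$meals))
})

test_that("cohorts derive distinct, reproducible participants from one master seed", {
  cfg <- sim_config("eTRE", n_days = 1, seed = 4)
  expect_length(simulate_cohort(cfg, 1, include_accel = FALSE), 1)
  coh <- simulate_cohort(cfg, 6, include_accel = FALSE)
  coh2 <- simulate_cohort(cfg, 6, include_accel = FALSE)
  base <- vapply(coh, function(r) r$config$baseline_glucose, numeric(1))
  expect_equal(length(unique(base)), 6)
  expect_identical(lapply(coh, function(r) r$glucose$glucose),
                   lapply(coh2, function(r) r$glucose$glucose))
  other <- simulate_cohort(sim_config("eTRE", n_days = 1, seed = 5), 6,
                           include_accel = FALSE)
  expect_false(identical(coh[[1]]$meals$start, other[[1]]$meals$start))
})
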