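test_that("sliding windows count, label and drop as specified", {
  rec <- simulate_participant(sim_config("eTRE", n_days = 1, seed = 1),
                              include_accel = FALSE)
  al <- align_participant(rec$glucose, NULL, rec$meals, "P01", "eTRE")
  wins <- sliding_windows(al, window_spec(45, 15))
  expect_equal(nrow(wins), 96 - 3 + 1) # N - width/step + 1
  expect_equal(attr(wins, "n_dropped"), 0)
  # all-fasting day -> every window labeled fasting
  rec0 <- simulate_participant(sim_config("habitual", n_days = 1, seed = 2,
                                          meals_per_day = 0L), include_accel = FALSE)
  al0 <- align_participant(rec0$glucose, NULL, rec0$meals)
  expect_true(all(sliding_windows(al0)$label == "fasting"))
  # windows over a glucose gap are dropped and counted
  al$glucose[10] <- NA
  wins_gap <- sliding_windows(al)
  expect_equal(attr(wins_gap, "n_dropped"), 3)
  expect_equal(nrow(wins_gap), 91)
})

test_that("glycemic formulas match hand-computed values exactly", {
  f <- glucose_window_features(c(100, 100, 100))
  expect_equal(unname(f[c("glucose_mean", "glucose_sd", "glucose_cv")]),
               c(100, 0, 0), tolerance = 1e-12)
  expect_equal(unname(f["glucose_j_index"]), 0.1, tolerance = 1e-12)
  expect_equal(unname(f["glucose_max"]), 100)

  f2 <- glucose_window_features(c(90, 110, 100))
  sd_exact <- sqrt(200 / 3) # population SD, divisor N
  expect_equal(unname(f2["glucose_mean"]), 100, tolerance = 1e-12)
  expect_equal(unname(f2["glucose_sd"]), sd_exact, tolerance = 1e-12)
  expect_equal(unname(f2["glucose_cv"]), 100 * sd_exact / 100, tolerance = 1e-12)
  expect_equal(unname(f2["glucose_j_index"]), 0.001 * (100 + sd_exact),
               tolerance = 1e-12)
  expect_equal(unname(f2["glucose_max"]), 110)
  expect_error(glucose_window_features(100), ">= 2")
})

test_that("the J-index identity and scale consistency hold on random windows", {
  set.seed(7)
  for (i in 1:25) {
    v <- runif(3, 60, 200)
    f <- glucose_window_features(v)
    expect_equal(unname(f["glucose_j_index"]),
                 0.001 * (f[["glucose_mean"]] + f[["glucose_sd"]]),
                 tolerance = 1e-12)
    fc <- glucose_window_features(2.5 * v)
    expect_equal(fc[["glucose_cv"]], f[["glucose_cv"]], tolerance = 1e-9)
    expect_equal(fc[["glucose_sd"]], 2.5 * f[["glucose_sd"]], tolerance = 1e-9)
    expect_equal(fc[["glucose_j_index"]], 2.5 * f[["glucose_j_index"]],
                 tolerance = 1e-9)
  }
  fsq <- glucose_window_features(c(90, 110, 100), j_index_squared = TRUE)
  expect_equal(unname(fsq["glucose_j_index"]), 0.001 * (100 + sqrt(200 / 3))^2,
               tolerance = 1e-12)
})

test_that("acceleration features match their closed forms", {
  n <- 2700
  const <- data.frame(x = rep(0, n), y = rep(0, n), z = rep(0.5, n),
                      steps = rep(0L, n), vector_magnitude = rep(0.5, n))
  f <- accel_window_features(const)
  expect_equal(unname(f[c("z_mean", "z_energy", "peak_count")]), c(0.5, 0.25, 0))
  sine <- sin(2 * pi * seq_len(n) / 60)
  fs <- accel_window_features(data.frame(x = sine, y = 0, z = 0, steps = 0L,
                                         vector_magnitude = abs(sine)))
  expect_equal(unname(fs["x_energy"]), 0.5, tolerance = 0.01) # mean of sin^2
  zero <- data.frame(x = 0, y = 0, z = 0, steps = 0L, vector_magnitude = 0)[rep(1, 10), ]
  expect_true(all(accel_window_features(zero) == 0))
})

test_that("table features equal brute-force recomputation from raw slices", {
  rec <- simulate_participant(sim_config("eTRE", n_days = 2, seed = 13))
  tab <- build_feature_table(list(rec))
  set.seed(5)
  idx <- sample.int(nrow(tab), 100)
  a_t0 <- as.numeric(rec$accel$timestamp[1])
  for (i in idx) {
    w0 <- tab$window_start[i]
    gsel <- rec$glucose$timestamp >= w0 & rec$glucose$timestamp < w0 + 45 * 60
    g_oracle <- oracle_glucose_features(rec$glucose$glucose[gsel])
    expect_equal(unlist(tab[i, names(g_oracle)]), g_oracle, tolerance = 1e-9,
                 ignore_attr = TRUE)
    off <- as.numeric(w0) - a_t0
    a_oracle <- oracle_accel_features(rec$accel[(off + 1):(off + 2700), ])
    expect_equal(unlist(tab[i, names(a_oracle)]), a_oracle, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("features are invariant under a rigid time shift", {
  rec <- simulate_participant(sim_config("eTRE", n_days = 1, seed = 17))
  tab <- build_feature_table(list(rec))
  shift <- 26 * 3600 # whole number of grid steps
  rec$glucose$timestamp <- rec$glucose$timestamp + shift
  rec$accel$timestamp <- rec$accel$timestamp + shift
  rec$meals$start <- rec$meals$start + shift
  rec$meals$end <- rec$meals$end + shift
  tab2 <- build_feature_table(list(rec))
  feats <- intersect(feature_registry()$name, names(tab))
  expect_equal(as.matrix(tab2[, feats]), as.matrix(tab[, feats]), tolerance = 1e-12)
  expect_identical(as.character(tab2$label), as.character(tab$label))
})

test_that("feature tables are complete and deterministic", {
  recs <- simulate_cohort(sim_config("eTRE", n_days = 1, seed = 23), 2)
  tab <- build_feature_table(recs)
  expect_true(all(feature_registry()$name %in% names(tab)))
  expect_false(anyNA(tab[, feature_registry()$name]))
  expect_equal(nrow(tab), 2 * 94)
  expect_identical(tab, build_feature_table(recs))
})

test_that("RFE keeps everything when asked to, and finds the informative feature", {
  set.seed(1)
  n <- 200
  y <- rep(c("fasting", "non_fasting"), each = n / 2)
  mk <- function(seed) {
    set.seed(seed)
    data.frame(glucose_mean = (y == "non_fasting") + rnorm(n, 0, 0.05),
               glucose_sd = rnorm(n), label = y)
  }
  tab <- mk(1)
  expect_setequal(rfe_select(tab, n_keep = 2), c("glucose_mean", "glucose_sd"))
  hits <- sum(vapply(1:10, function(s)
    rfe_select(mk(s), n_keep = 1, seed = s) == "glucose_mean", logical(1)))
  expect_gte(hits, 9)
})

test_that("grouped RFE keeps the prescribed per-sensor counts", {
  rec <- simulate_participant(sim_config("eTRE", n_days = 2, seed = 29))
  tab <- build_feature_table(list(rec))
  kept <- rfe_select(tab, n_keep = 6, seed = 1,
                     n_keep_per_group = c(glucose = 3, accel = 3))
  reg <- feature_registry()
  src <- reg$source[match(kept, reg$name)]
  expect_equal(sum(src == "glucose"), 3)
  expect_equal(sum(src == "accel"), 3)
})
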