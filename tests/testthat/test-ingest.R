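write_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("CGM reader parses, deduplicates and sorts", {
  p <- write_lines(c("timestamp,glucose",
                     "2024-03-01 00:15:00,95",
                     "2024-03-01 00:00:00,90",
                     "2024-03-01 00:30:00,100",
                     "2024-03-01 00:15:00,999999",
                     "2024-03-01 00:15:00,97"))
  gs <- suppressWarnings(read_cgm_csv(p))
  expect_equal(nrow(gs), 3)
  expect_false(is.unsorted(gs$timestamp))
  expect_equal(gs$glucose, c(90, 95, 100)) # first valid reading per timestamp wins
  rep <- attr(gs, "parse_report")
  expect_equal(rep$n_range_dropped, 1)
  expect_equal(rep$n_duplicates, 1)
})

test_that("CGM reader tolerates decimal commas and drops unparseable rows", {
  p <- write_lines(c("timestamp;glucose",
                     "2024-03-01 00:00:00;90,5",
                     "not-a-date;85",
                     "2024-03-01 00:15:00;92,25"))
  gs <- read_cgm_csv(p, sep = ";", dec = ",")
  expect_equal(gs$glucose, c(90.5, 92.25))
  expect_equal(attr(gs, "parse_report")$n_parse_dropped, 1)
})

test_that("CGM reader rejects files without usable rows", {
  p <- write_lines(c("timestamp,glucose"))
  expect_error(read_cgm_csv(p), "empty|parseable")
  p2 <- write_lines(c("timestamp,glucose", "junk,junk"))
  expect_error(read_cgm_csv(p2), "parseable")
})

test_that("actigraphy reader computes the vector magnitude when absent", {
  p <- write_lines(c("timestamp,x,y,z",
                     "2024-03-01 00:00:00,3,4,0",
                     "2024-03-01 00:00:01,1,2,2"))
  a <- read_actigraphy_csv(p)
  expect_equal(a$vector_magnitude, c(5, 3)) # 3-4-5 and 1-2-2 triangles
  expect_equal(a$steps, c(0L, 0L))
  p2 <- write_lines(c("timestamp,steps", "2024-03-01 00:00:00,3"))
  expect_error(read_actigraphy_csv(p2), "x/y/z")
})

test_that("meal-log reader merges overlaps and rejects inverted rows", {
  p <- write_lines(c("participant_id,start,end",
                     "P01,2024-03-01 08:00:00,2024-03-01 08:20:00",
                     "P01,2024-03-01 08:10:00,2024-03-01 08:30:00",
                     "P01,2024-03-01 12:00:00,2024-03-01 12:30:00",
                     "P01,2024-03-01 19:00:00,2024-03-01 18:00:00"))
  expect_warning(read_meal_log(p), "rejected")
  ml <- suppressWarnings(read_meal_log(p))
  expect_equal(nrow(ml), 2)
  expect_equal(format(ml$start[1], "%H:%M"), "08:00")
  expect_equal(format(ml$end[1], "%H:%M"), "08:30")
  expect_false(is.unsorted(ml$start))
})

test_that("meal-log reader accepts the duration-minutes layout", {
  p <- write_lines(c("participant_id,start,duration_minutes",
                     "P01,2024-03-01 12:00:00,30",
                     "P01,2024-03-01 08:00:00,20"))
  ml <- read_meal_log(p)
  expect_equal(nrow(ml), 2)
  expect_equal(as.numeric(difftime(ml$end, ml$start, units = "mins")), c(20, 30))
})

test_that("downsampled accel bins equal brute-force bin aggregation", {
  set.seed(11)
  t0 <- as.POSIXct("2024-03-01", tz = "UTC")
  n <- 3600
  a <- accel_series("P01", t0 + 0:(n - 1),
                    x = rnorm(n), y = rnorm(n), z = rep(0.5, n),
                    steps = rep(1L, n), lux = runif(n))
  grid <- t0 + seq(0, 3600 - 900, by = 900)
  agg <- downsample_accel(a, grid)
  expect_equal(agg$z, rep(0.5, 4))
  expect_equal(agg$steps, rep(900, 4)) # sum, not mean
  for (b in seq_along(grid)) {
    sel <- a$timestamp >= grid[b] & a$timestamp < grid[b] + 900
    expect_equal(agg$x[b], mean(a$x[sel]), tolerance = 1e-12)
    expect_equal(agg$vector_magnitude[b], mean(a$vector_magnitude[sel]),
                 tolerance = 1e-12)
  }
  # a grid extending past the data flags empty bins
  grid2 <- t0 + seq(0, 7200 - 900, by = 900)
  agg2 <- downsample_accel(a, grid2)
  expect_true(all(is.na(agg2$x[5:8])) && all(agg2$n_samples[5:8] == 0))
})

test_that("eating-window labels are closed-interval and idempotent", {
  t0 <- as.POSIXct("2024-03-01", tz = "UTC")
  meals <- meal_log("P01", start = t0 + c(8, 12) * 3600,
                    end = t0 + c(8.5, 16) * 3600)
  grid <- t0 + seq(0, 86400 - 900, by = 900)
  lab <- label_fasting_state(grid, meals)
  at <- function(h) lab[which(grid == t0 + h * 3600)]
  expect_equal(as.character(at(12)), "non_fasting")
  expect_equal(as.character(at(3)), "fasting")
  expect_equal(as.character(at(8)), "non_fasting")   # first start inclusive
  expect_equal(as.character(at(16)), "non_fasting")  # last end inclusive
  expect_equal(as.character(at(16.25)), "fasting")
  expect_identical(lab, label_fasting_state(grid, meals)) # idempotent
  expect_true(all(label_fasting_state(grid, meals[0, ]) == "fasting"))
})

test_that("stream alignment joins on the glucose grid and flags gaps", {
  rec <- simulate_participant(sim_config("eTRE", n_days = 2, seed = 21))
  al <- align_participant(rec$glucose, rec$accel, rec$meals, "P01", "eTRE")
  expect_equal(nrow(al), nrow(rec$glucose))
  expect_named(al, c("timestamp", "glucose", "x", "y", "z", "vector_magnitude",
                     "lux", "steps", "accel_n", "label"))
  expect_true(all(al$accel_n > 0))
  # accelerometer starting a day late leaves the first day's bins flagged
  late <- rec$accel[rec$accel$timestamp >= rec$glucose$timestamp[1] + 86400, ]
  agg <- downsample_accel(late, snap_to_grid(rec$glucose)$timestamp)
  expect_true(all(agg$n_samples[1:96] == 0) && all(agg$n_samples[97:192] > 0))
  # disjoint time ranges are an error
  shifted <- rec$accel
  shifted$timestamp <- shifted$timestamp + 10 * 86400
  expect_error(align_participant(rec$glucose, shifted, rec$meals), "overlap")
})

test_that("simulated records round-trip exactly through the CSV readers", {
  rec <- simulate_participant(sim_config("eTRE", n_days = 1, seed = 31))
  dir <- withr::local_tempdir()
  paths <- write_participant_csv(rec, dir)
  gs <- read_cgm_csv(paths[["cgm"]])
  expect_equal(as.numeric(gs$timestamp), as.numeric(rec$glucose$timestamp))
  expect_equal(gs$glucose, rec$glucose$glucose, tolerance = 1e-9)
  ac <- read_actigraphy_csv(paths[["accel"]])
  expect_equal(as.numeric(ac$timestamp), as.numeric(rec$accel$timestamp))
  expect_equal(ac$x, rec$accel$x, tolerance = 1e-9)
  expect_equal(ac$vector_magnitude, rec$accel$vector_magnitude, tolerance = 1e-9)
  expect_identical(ac$steps, rec$accel$steps)
  ml <- read_meal_log(paths[["meals"]])
  expect_equal(as.numeric(ml$start), as.numeric(rec$meals$start))
  expect_equal(as.numeric(ml$end), as.numeric(rec$meals$end))
})
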