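# Shared fixtures and independent oracles, all built in code.

# Two-level glucose trace: fasting baseline everywhere except a fed plateau on
# the closed daily eating window 08:00-16:00 (one meal block per day).
make_two_level_record <- function(n_days = 14, fasting_level = 90, fed_level = 130,
                                  noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t0 <- as.POSIXct("2024-03-01", tz = "UTC")
  grid <- t0 + seq(0, n_days * 86400 - 900, by = 900)
  mod <- (as.numeric(grid) - as.numeric(t0)) %% 86400 / 60
  fed <- mod >= 480 & mod <= 960
  vals <- ifelse(fed, fed_level, fasting_level) + rnorm(length(grid), 0, noise_sd)
  meals <- meal_log("P01",
                    start = t0 + (seq_len(n_days) - 1) * 86400 + 480 * 60,
                    end = t0 + (seq_len(n_days) - 1) * 86400 + 960 * 60,
                    condition = "eTRE")
  glucose <- glucose_series("P01", grid, vals)
  list(participant_id = "P01", condition = "eTRE", glucose = glucose,
       meals = meals, accel = NULL,
       truth = data.frame(timestamp = grid, label = label_fasting_state(grid, meals)))
}

# Brute-force glucose window features, written independently of the package
# implementation (explicit sums).
oracle_glucose_features <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  sd_pop <- sqrt(sum((v - m)^2) / n)
  c(glucose_mean = m, glucose_sd = sd_pop, glucose_cv = 100 * sd_pop / m,
    glucose_j_index = 0.001 * (m + sd_pop),
    glucose_max = v[which.max(v)], glucose_min = v[which.min(v)])
}

# Brute-force accel window features from a raw slice data frame.
oracle_accel_features <- function(slice) {
  en <- function(a) sum(a * a) / length(a)
  vm <- slice$vector_magnitude
  thr <- sum(vm) / length(vm) + sqrt(sum((vm - mean(vm))^2) / (length(vm) - 1))
  peaks <- integer(0)
  for (i in 2:(length(vm) - 1)) {
    if (vm[i] > vm[i - 1] && vm[i] > vm[i + 1] && vm[i] > thr) {
      if (!length(peaks) || i - peaks[length(peaks)] >= 5) peaks <- c(peaks, i)
    }
  }
  c(x_mean = mean(slice$x), y_mean = mean(slice$y), z_mean = mean(slice$z),
    x_max = max(slice$x), y_max = max(slice$y), z_max = max(slice$z),
    x_energy = en(slice$x), y_energy = en(slice$y), z_energy = en(slice$z),
    steps_mean = mean(slice$steps), vm_mean = mean(vm),
    peak_count = length(peaks))
}

# Naive majority-vote smoother (per-position enumeration).
oracle_smooth <- function(labels, k) {
  n <- length(labels)
  h <- (k - 1) %/% 2
  out <- labels
  for (i in seq_len(n)) {
    win <- labels[max(1, i - h):min(n, i + h)]
    tab <- table(win)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1) out[i] <- top
  }
  out
}

# Independent confusion-matrix metrics.
oracle_metrics <- function(y_true, y_pred, positive) {
  tp <- sum(y_true == positive & y_pred == positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  tn <- sum(y_true != positive & y_pred != positive)
  prec <- if (tp + fp) tp / (tp + fp) else 0
  rec <- if (tp + fn) tp / (tp + fn) else 0
  list(accuracy = (tp + tn) / length(y_true), precision = prec, recall = rec,
       f1 = if (prec + rec) 2 * prec * rec / (prec + rec) else 0,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

# O(n^2) all-pairs Tomek-link scan.
oracle_tomek_links <- function(X, y) {
  n <- nrow(X)
  d2 <- as.matrix(dist(X))^2
  diag(d2) <- Inf
  nn <- apply(d2, 1, which.min)
  links <- 0L
  for (i in seq_len(n)) {
    j <- nn[i]
    if (nn[j] == i && y[i] != y[j] && i < j) links <- links + 1L
  }
  links
}

# Well-separated two-cluster toy set, linearly separable.
make_separable_toy <- function(n_per_class = 30, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n_per_class, 0, 0.3), ncol = 2),
             matrix(rnorm(2 * n_per_class, 4, 0.3), ncol = 2))
  colnames(X) <- c("f1", "f2")
  y <- factor(rep(c("fasting", "non_fasting"), each = n_per_class),
              levels = c("fasting", "non_fasting"))
  list(X = X, y = y)
}
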