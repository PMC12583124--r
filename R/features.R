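# 45-min sliding-window feature engineering over the aligned streams.

#' Sliding-window specification
#'
#' @param width Window width in minutes (default 45).
#' @param step Advance step in minutes (default 15, one glucose sample).
#' @return A `window_spec` list.
#' @export
window_spec <- function(width = 45, step = 15) {
  if (width < step) stop_user("width must be >= step")
  if (width %% step != 0) stop_user("width must be a multiple of step")
  structure(list(width = width, step = step), class = "window_spec")
}

#' Feature registry
#'
#' The fixed set of window features, in canonical column order, with the
#' sensor each derives from. Glucose: mean, population SD, intraday CV
#' (`100 * sd/mean`), J-index (`0.001 * (mean + sd)`), max, min.
#' Acceleration: per-axis mean/max/energy, mean steps, mean vector
#' magnitude, signal peak count.
#'
#' @return `data.frame(name, source)`.
#' @export
feature_registry <- function() {
  data.frame(
    name = c("glucose_mean", "glucose_sd", "glucose_cv", "glucose_j_index",
             "glucose_max", "glucose_min",
             "x_mean", "y_mean", "z_mean", "x_max", "y_max", "z_max",
             "x_energy", "y_energy", "z_energy",
             "steps_mean", "vm_mean", "peak_count"),
    source = rep(c("glucose", "accel"), c(6L, 12L))
  )
}

#' Enumerate sliding windows over an aligned dataset
#'
#' Windows `[t, t + width)` advance by `step` over the glucose grid; the
#' window label is the label of the window's centre grid point (the sample
#' count is odd at the defaults, so no ties arise). Windows overlapping
#' glucose gaps, unlabeled points, or (when accelerometer columns are
#' present) missing accelerometer bins are dropped and counted in the
#' `n_dropped` attribute.
#'
#' @param aligned An `aligned_dataset` (see [align_participant()]).
#' @param spec A [window_spec()].
#' @return `data.frame(start_idx, window_start, label)` with attribute
#'   `n_dropped`.
#' @export
sliding_windows <- function(aligned, spec = window_spec()) {
  ts <- as.numeric(aligned$timestamp)
  grid_step <- if (length(ts) > 1) (ts[2] - ts[1]) / 60 else 15
  w <- as.integer(spec$width / grid_step)   # grid points per window
  s <- as.integer(spec$step / grid_step)    # grid points per advance
  n <- nrow(aligned)
  if (n < w) stop_user("aligned dataset shorter than one window")
  starts <- seq.int(1L, n - w + 1L, by = s)
  centre <- starts + (w - 1L) %/% 2L
  ok <- rep(TRUE, length(starts))
  for (j in seq_len(w) - 1L) ok <- ok & !is.na(aligned$glucose[starts + j])
  if ("accel_n" %in% names(aligned)) {
    for (j in seq_len(w) - 1L) ok <- ok & aligned$accel_n[starts + j] > 0
  }
  ok <- ok & !is.na(aligned$label[centre])
  out <- data.frame(start_idx = starts[ok],
                    window_start = aligned$timestamp[starts[ok]],
                    label = aligned$label[centre[ok]])
  attr(out, "n_dropped") <- sum(!ok)
  attr(out, "points_per_window") <- w
  out
}

#' Glycemic features of one window
#'
#' @param values Glucose samples (mg/dL) of one window; at least 2, all
#'   positive.
#' @param j_index_squared Use the squared literature variant
#'   `0.001 * (mean + sd)^2` instead of the linear form.
#' @return Named numeric vector: mean, population SD, intraday CV
#'   (`100 * sd/mean`), J-index (`0.001 * (mean + sd)`), max, min.
#' @export
#' @examples
#' glucose_window_features(c(90, 110, 100))
glucose_window_features <- function(values, j_index_squared = FALSE) {
  if (length(values) < 2) stop_user("glucose window needs >= 2 values")
  if (any(values <= 0)) stop_user("glucose values must be positive")
  m <- mean(values)
  sd_pop <- sqrt(mean((values - m)^2))
  j <- if (j_index_squared) 0.001 * (m + sd_pop)^2 else 0.001 * (m + sd_pop)
  c(glucose_mean = m, glucose_sd = sd_pop, glucose_cv = 100 * sd_pop / m,
    glucose_j_index = j, glucose_max = max(values), glucose_min = min(values))
}

#' Acceleration features of one window
#'
#' Axis energies are mean squared amplitudes (`mean(a^2)`); the peak count
#' is the number of strict local maxima of the vector magnitude exceeding
#' `mean + 1 * sd` of the window, thinned to a minimum separation of
#' `min_separation_s` seconds.
#'
#' @param slice Data frame of the raw 1 Hz samples in the window (columns
#'   `x`, `y`, `z`, `steps`, `vector_magnitude`).
#' @param peak_sd_mult Peak threshold in SD units above the window mean.
#' @param min_separation_s Minimum peak separation, seconds.
#' @return Named numeric vector of the 12 acceleration features.
#' @export
accel_window_features <- function(slice, peak_sd_mult = 1, min_separation_s = 5) {
  if (!nrow(slice)) stop_user("empty accel slice")
  vm <- slice$vector_magnitude
  c(x_mean = mean(slice$x), y_mean = mean(slice$y), z_mean = mean(slice$z),
    x_max = max(slice$x), y_max = max(slice$y), z_max = max(slice$z),
    x_energy = mean(slice$x^2), y_energy = mean(slice$y^2), z_energy = mean(slice$z^2),
    steps_mean = mean(slice$steps), vm_mean = mean(vm),
    peak_count = count_signal_peaks(vm, peak_sd_mult, min_separation_s))
}

count_signal_peaks <- function(v, sd_mult = 1, min_sep = 5) {
  n <- length(v)
  if (n < 3) return(0)
  cand <- which(diff(sign(diff(v))) == -2) + 1L # strict local maxima
  thr <- mean(v) + sd_mult * stats::sd(v)
  cand <- cand[v[cand] > thr]
  if (!length(cand)) return(0)
  kept <- cand[1]; last <- cand[1]
  for (i in cand[-1]) {
    if (i - last >= min_sep) { kept <- c(kept, i); last <- i }
  }
  length(kept)
}

#' Build the windowed feature table for one participant
#'
#' @param record A `participant_record`, or a list with elements `glucose`,
#'   `accel`, `meals`, `participant_id`, `condition`.
#' @param spec A [window_spec()].
#' @param j_index_squared Passed to [glucose_window_features()].
#' @return Feature-table rows for this participant (see
#'   [build_feature_table()]).
#' @export
featurize_record <- function(record, spec = window_spec(), j_index_squared = FALSE) {
  aligned <- align_participant(record$glucose, record$accel, record$meals,
                               participant_id = record$participant_id,
                               condition = record$condition)
  wins <- sliding_windows(aligned, spec)
  if (!nrow(wins)) return(NULL)
  w <- attr(wins, "points_per_window")
  gmat <- vapply(seq_len(w) - 1L,
                 function(j) aligned$glucose[wins$start_idx + j],
                 numeric(nrow(wins)))
  if (is.null(dim(gmat))) gmat <- matrix(gmat, nrow = 1)
  gm <- rowMeans(gmat)
  gsd <- sqrt(rowMeans((gmat - gm)^2))
  gfeat <- cbind(glucose_mean = gm, glucose_sd = gsd, glucose_cv = 100 * gsd / gm,
                 glucose_j_index = if (j_index_squared) 0.001 * (gm + gsd)^2
                                   else 0.001 * (gm + gsd),
                 glucose_max = apply(gmat, 1, max), glucose_min = apply(gmat, 1, min))

  afeat <- NULL
  if (!is.null(record$accel)) {
    a <- record$accel
    a_t0 <- as.numeric(a$timestamp[1])
    wlen <- spec$width * 60
    offs <- as.numeric(wins$window_start) - a_t0
    nsec <- nrow(a)
    # plain-vector fast path over the raw 1 Hz slices
    xv <- a$x; yv <- a$y; zv <- a$z; sv <- as.numeric(a$steps); vmv <- a$vector_magnitude
    afeat <- t(vapply(seq_len(nrow(wins)), function(i) {
      i0 <- offs[i] + 1
      i1 <- offs[i] + wlen
      if (i0 < 1 || i1 > nsec) return(rep(NA_real_, 12))
      ix <- i0:i1
      xs <- xv[ix]; ys <- yv[ix]; zs <- zv[ix]; vs <- vmv[ix]
      c(mean(xs), mean(ys), mean(zs), max(xs), max(ys), max(zs),
        mean(xs^2), mean(ys^2), mean(zs^2), mean(sv[ix]), mean(vs),
        count_signal_peaks(vs))
    }, numeric(12)))
    colnames(afeat) <- c("x_mean", "y_mean", "z_mean", "x_max", "y_max", "z_max",
                         "x_energy", "y_energy", "z_energy",
                         "steps_mean", "vm_mean", "peak_count")
    keep <- stats::complete.cases(afeat)
    wins <- wins[keep, , drop = FALSE]
    gfeat <- gfeat[keep, , drop = FALSE]
    afeat <- afeat[keep, , drop = FALSE]
  }

  out <- data.frame(participant_id = attr(aligned, "participant_id"),
                    condition = attr(aligned, "condition"),
                    window_start = wins$window_start)
  out <- cbind(out, gfeat)
  if (!is.null(afeat)) out <- cbind(out, afeat)
  out$label <- wins$label
  out
}

#' Build the cohort feature table
#'
#' One row per surviving 45-min window across all participants, carrying the
#' full feature registry and the fasting label of the window centre.
#' Row order is deterministic: (participant, condition, window start).
#'
#' @param records List of `participant_record`s.
#' @param spec A [window_spec()].
#' @param j_index_squared Use the squared J-index variant.
#' @return A `feature_table` data frame.
#' @export
build_feature_table <- function(records, spec = window_spec(), j_index_squared = FALSE) {
  if (inherits(records, "participant_record")) records <- list(records)
  rows <- lapply(records, featurize_record, spec = spec,
                 j_index_squared = j_index_squared)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop_user("no complete windows; feature table is empty")
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id, out$condition, out$window_start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, spec = spec, class = c("feature_table", "data.frame"))
}

feature_columns <- function(table) {
  intersect(feature_registry()$name, names(table))
}

#' Recursive feature elimination
#'
#' Iteratively fits the ranking model on the remaining features and drops
#' the single least important one (importance is `|coefficient|` for linear
#' families, impurity importance for tree families) until `n_keep` remain.
#' Ties are broken by registry order (the later-registered feature is
#' dropped). When `n_keep_per_group` is supplied (named counts per feature
#' `source`, e.g. `c(glucose = 3, accel = 3)`), a source already at its
#' quota is protected from further elimination, so the selection keeps the
#' prescribed per-sensor shape.
#'
#' @param table A `feature_table` (or data frame with registry feature
#'   columns and a `label` column).
#' @param n_keep Number of features to retain (ignored when
#'   `n_keep_per_group` is given).
#' @param ranker A [model_spec()] for the ranking model; linear
#'   (`logistic`, `sgd_linear`) and tree (`decision_tree`, `random_forest`)
#'   families are supported.
#' @param seed Integer seed controlling any ranker stochasticity.
#' @param n_keep_per_group Optional named integer vector of per-source
#'   quotas.
#' @return Character vector of kept feature names (registry order), with
#'   attribute `elimination_order`.
#' @export
rfe_select <- function(table, n_keep, ranker = model_spec("logistic"), seed = 1L,
                       n_keep_per_group = NULL) {
  feats <- feature_columns(table)
  X <- as.matrix(table[, feats, drop = FALSE])
  if (any(!is.finite(X))) stop_user("non-finite feature values")
  y <- as_state_factor(table$label)
  reg <- feature_registry()
  grp <- reg$source[match(feats, reg$name)]
  if (!is.null(n_keep_per_group)) {
    n_keep <- sum(n_keep_per_group)
    if (!all(names(n_keep_per_group) %in% grp))
      stop_user("n_keep_per_group names must match feature sources present")
  }
  if (n_keep < 1 || n_keep > length(feats)) stop_user("n_keep out of range")
  remaining <- feats
  eliminated <- character(0)
  it <- 0L
  while (length(remaining) > n_keep) {
    it <- it + 1L
    spec <- ranker
    spec$seed <- seed + it
    fit <- train_model(spec, X[, remaining, drop = FALSE], y)
    imp <- feature_importance(fit)[remaining]
    imp[is.na(imp)] <- 0
    eligible <- remaining
    if (!is.null(n_keep_per_group)) {
      g <- reg$source[match(remaining, reg$name)]
      counts <- vapply(names(n_keep_per_group), function(s) sum(g == s), numeric(1))
      at_quota <- names(n_keep_per_group)[counts <= n_keep_per_group]
      eligible <- remaining[!g %in% at_quota]
    }
    # lowest importance; ties drop the later-registered feature
    cand <- eligible[imp[eligible] == min(imp[eligible])]
    drop <- cand[which.max(match(cand, reg$name))]
    eliminated <- c(eliminated, drop)
    remaining <- setdiff(remaining, drop)
  }
  structure(feats[feats %in% remaining], elimination_order = eliminated)
}
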