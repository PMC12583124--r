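`%||%` <- function(a, b) if (is.null(a)) b else a

# All timestamps in the package are timezone-naive local clock time, stored as
# POSIXct in UTC so arithmetic is DST-free.
as_utc <- function(x, ...) as.POSIXct(x, tz = "UTC", ...)

#' Minute of day of a timestamp
#'
#' Clock time expressed as (possibly fractional) minutes since local midnight.
#'
#' @param ts POSIXct vector.
#' @return Numeric vector in `[0, 1440)`.
#' @keywords internal
#' @noRd
minute_of_day <- function(ts) {
  lt <- as.POSIXlt(ts, tz = "UTC")
  lt$hour * 60 + lt$min + lt$sec / 60
}

day_start <- function(ts) {
  as_utc(trunc(ts, units = "days"))
}

# "HH:MM" -> minutes since midnight
hm_to_minutes <- function(x) {
  if (is.numeric(x)) return(x)
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) as.numeric(p[1]) * 60 + as.numeric(p[2]), numeric(1))
}

label_levels <- function() c("fasting", "non_fasting")

as_state_factor <- function(x) {
  factor(as.character(x), levels = label_levels())
}

stop_user <- function(...) stop(..., call. = FALSE)

is_count <- function(x) length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= 1

# Squared Euclidean cross-distances between rows of A (m x d) and B (n x d).
pairwise_sq_dist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# Index of the nearest neighbour of each row of X among all other rows,
# computed in chunks to bound memory.
nn1_index <- function(X, chunk = 1024L) {
  n <- nrow(X)
  out <- integer(n)
  starts <- seq(1L, n, by = chunk)
  for (s in starts) {
    e <- min(s + chunk - 1L, n)
    d2 <- pairwise_sq_dist(X[s:e, , drop = FALSE], X)
    d2[cbind(seq_len(e - s + 1L), s:e)] <- Inf # exclude self
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}
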