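# Exact Shapley-value attribution by full coalition enumeration.

shapley_value_table <- function(score_fn, background, instance, d) {
  # v(S) = mean score over background rows with the features in S set to the
  # instance's values (interventional expectation); index = bitmask + 1.
  B <- as.matrix(background)
  n_masks <- bitwShiftL(1L, d)
  v <- numeric(n_masks)
  for (m in seq_len(n_masks) - 1L) {
    Xm <- B
    for (i in seq_len(d)) {
      if (bitwAnd(m, bitwShiftL(1L, i - 1L)) != 0L) Xm[, i] <- instance[i]
    }
    v[m + 1L] <- mean(score_fn(Xm))
  }
  v
}

#' Exact Shapley attribution of one prediction
#'
#' Computes exact Shapley values by enumerating all `2^d` feature
#' coalitions:
#' `phi_i = sum over S not containing i of |S|! (d-|S|-1)! / d! *
#' (v(S + i) - v(S))`, where the coalition value `v(S)` is the mean model
#' score over the background rows with the features in `S` replaced by the
#' instance's values (interventional expectation, no sampling). The
#' efficiency axiom `baseline + sum(phi) = f(x)` holds by construction and
#' is verified numerically.
#'
#' @param score_fn Function mapping a feature matrix to numeric scores
#'   (e.g. `function(X) score_model(model, X)`).
#' @param background Background feature matrix (the reference distribution;
#'   subsample to a few hundred rows for speed).
#' @param instance Numeric feature vector to explain.
#' @param max_features Enumeration guard; inputs wider than this error out.
#' @return An `attribution`: list with `baseline` (`E[f(X)]` over the
#'   background), named `phi`, and `fx` (the model score at the instance).
#' @export
#' @examples
#' bg <- matrix(rnorm(40), ncol = 2, dimnames = list(NULL, c("a", "b")))
#' att <- exact_shapley(function(X) X[, 1] + 2 * X[, 2], bg, c(a = 1, b = 1))
exact_shapley <- function(score_fn, background, instance, max_features = 12L) {
  background <- as.matrix(background)
  d <- length(instance)
  stopifnot(ncol(background) == d, nrow(background) >= 1)
  if (d > max_features)
    stop_user("exact enumeration supports at most ", max_features,
              " features; approximate attribution is out of scope")
  fnames <- names(instance) %||% colnames(background) %||% paste0("f", seq_len(d))
  v <- shapley_value_table(score_fn, background, instance, d)
  fact <- factorial(0:d)
  wts <- fact[1:d] * fact[d:1] / fact[d + 1L] # weight for |S| = 0 .. d-1
  phi <- numeric(d)
  masks <- seq_len(bitwShiftL(1L, d)) - 1L
  sizes <- vapply(masks, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(d - 1L))) != 0L),
                  numeric(1))
  for (i in seq_len(d)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- masks[bitwAnd(masks, bit) == 0L]
    phi[i] <- sum(wts[sizes[without + 1L] + 1L] *
                    (v[bitwOr(without, bit) + 1L] - v[without + 1L]))
  }
  structure(list(baseline = v[1L],
                 phi = stats::setNames(phi, fnames),
                 fx = v[length(v)]),
            class = "attribution")
}

#' @export
print.attribution <- function(x, ...) {
  cat(sprintf("<attribution baseline %.4f -> f(x) %.4f>\n", x$baseline, x$fx))
  print(round(sort(x$phi, decreasing = TRUE), 4))
  invisible(x)
}

#' Shapley values by permutation enumeration
#'
#' Independent cross-check of [exact_shapley()]: averages each feature's
#' marginal contribution over all `d!` orderings. Limited to small `d`.
#'
#' @inheritParams exact_shapley
#' @param max_features Permutation-enumeration guard (default 8).
#' @return An `attribution`.
#' @export
shapley_permutation <- function(score_fn, background, instance, max_features = 8L) {
  d <- length(instance)
  if (d > max_features) stop_user("permutation enumeration supports at most ",
                                  max_features, " features")
  fnames <- names(instance) %||% colnames(background) %||% paste0("f", seq_len(d))
  v <- shapley_value_table(score_fn, as.matrix(background), instance, d)
  perms <- all_permutations(d)
  phi <- numeric(d)
  for (p in perms) {
    m <- 0L
    for (i in p) {
      m2 <- bitwOr(m, bitwShiftL(1L, i - 1L))
      phi[i] <- phi[i] + v[m2 + 1L] - v[m + 1L]
      m <- m2
    }
  }
  phi <- phi / length(perms)
  structure(list(baseline = v[1L], phi = stats::setNames(phi, fnames),
                 fx = v[length(v)]),
            class = "attribution")
}

all_permutations <- function(d) {
  if (d == 1L) return(list(1L))
  sub <- all_permutations(d - 1L)
  out <- vector("list", d * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in 0:(d - 1L)) {
      k <- k + 1L
      out[[k]] <- append(p, d, after = pos)
    }
  }
  out
}

#' Global feature importance from attributions
#'
#' Mean absolute Shapley contribution per feature across a set of explained
#' instances, sorted descending.
#'
#' @param attributions List of `attribution` objects over a shared feature
#'   registry.
#' @return Named numeric vector of mean `|phi|`, descending.
#' @export
global_importance <- function(attributions) {
  if (!length(attributions)) stop_user("no attributions supplied")
  nm <- names(attributions[[1]]$phi)
  for (a in attributions) {
    if (!identical(names(a$phi), nm))
      stop_user("attributions do not share one feature registry")
  }
  mat <- vapply(attributions, function(a) abs(a$phi), numeric(length(nm)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1, dimnames = list(nm, NULL))
  sort(rowMeans(mat), decreasing = TRUE)
}
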