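# Supervised fasting-state classification: rebalancing, scaling, model
# registry, chronological label smoothing and evaluation.

#' SMOTE oversampling followed by Tomek-link removal
#'
#' Rebalances a two-class dataset: (1) SMOTE — the minority class is
#' oversampled up to the majority count with synthetic points
#' `x' = x_i + lambda * (x_nn - x_i)`, `lambda ~ U(0, 1)`, where `x_nn` is
#' one of the `k_neighbors` nearest minority neighbours of minority point
#' `x_i`; (2) Tomek links — pairs of opposite-class points that are mutual
#' 1-nearest neighbours are removed (both members), cleaning the class
#' boundary. Deterministic given `seed`.
#'
#' @param X Numeric feature matrix (rows = samples).
#' @param y Two-level factor of labels.
#' @param k_neighbors SMOTE neighbourhood size; the minority class must
#'   exceed it.
#' @param seed Integer seed.
#' @return List with `X`, `y`, `n_synthetic` and `n_tomek_removed`.
#' @export
balance_smote_tomek <- function(X, y, k_neighbors = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop_user("balance_smote_tomek requires exactly two classes")
  cnt <- table(y)
  minority <- names(cnt)[which.min(cnt)]
  n_min <- min(cnt); n_maj <- max(cnt)
  n_syn <- n_maj - n_min
  set.seed(seed)
  Xs <- NULL
  if (n_syn > 0) {
    if (n_min <= k_neighbors)
      stop_user("minority class must exceed k_neighbors = ", k_neighbors)
    Xm <- X[y == minority, , drop = FALSE]
    d2 <- pairwise_sq_dist(Xm, Xm)
    diag(d2) <- Inf
    nn <- t(apply(d2, 1, function(r) order(r)[seq_len(k_neighbors)]))
    base_i <- sample.int(n_min, n_syn, replace = TRUE)
    nb_i <- nn[cbind(base_i, sample.int(k_neighbors, n_syn, replace = TRUE))]
    lambda <- runif(n_syn)
    Xs <- Xm[base_i, , drop = FALSE] +
      lambda * (Xm[nb_i, , drop = FALSE] - Xm[base_i, , drop = FALSE])
  }
  Xb <- rbind(X, Xs)
  yb <- factor(c(as.character(y), rep(minority, n_syn)), levels = levels(y))
  # Tomek links: mutual opposite-class 1-NNs; removing a link can expose new
  # mutual pairs, so iterate until the boundary is clean
  n_removed <- 0L
  repeat {
    nn1 <- nn1_index(Xb)
    i <- seq_len(nrow(Xb))
    link <- nn1[nn1] == i & yb != yb[nn1] & i < nn1
    remove <- unique(c(i[link], nn1[link]))
    if (!length(remove) || length(remove) >= nrow(Xb) - 2L) break
    Xb <- Xb[-remove, , drop = FALSE]
    yb <- yb[-remove]
    n_removed <- n_removed + length(remove)
  }
  list(X = Xb, y = yb, n_synthetic = n_syn, n_tomek_removed = n_removed)
}

#' Min-max scaling fitted on the training set
#'
#' Per-feature `(x - min) / (max - min)` with bounds taken from `X_train`
#' only; a constant training feature maps to 0 everywhere; values in
#' `X_apply` may fall outside `[0, 1]`.
#'
#' @param X_train Training feature matrix.
#' @param X_apply Optional matrix scaled with the training bounds.
#' @return List with `train`, `apply` (or `NULL`), `min`, `max`.
#' @export
scale_minmax <- function(X_train, X_apply = NULL) {
  X_train <- as.matrix(X_train)
  if (any(!is.finite(X_train))) stop_user("non-finite values in X_train")
  mn <- apply(X_train, 2, min)
  mx <- apply(X_train, 2, max)
  rng <- mx - mn
  rng[rng == 0] <- 1 # constant feature -> 0 everywhere
  sc <- function(X) sweep(sweep(as.matrix(X), 2, mn), 2, rng, "/")
  list(train = sc(X_train),
       apply = if (is.null(X_apply)) NULL else sc(X_apply),
       min = mn, max = mx)
}

#' Classifier specification
#'
#' @param family One of `"svm_rbf"`, `"random_forest"`, `"mlp"`, `"knn"`,
#'   `"decision_tree"`, `"logistic"`, `"sgd_linear"`.
#' @param hyperparameters Named list overriding the family defaults
#'   (e.g. `cost`/`gamma` for the SVM, `ntree` for the forest, `size` for
#'   the MLP, `k` for kNN, `epochs`/`learning_rate` for the SGD model).
#' @param seed Integer seed fixed for stochastic families.
#' @return A `model_spec` list.
#' @export
model_spec <- function(family = c("svm_rbf", "random_forest", "mlp", "knn",
                                  "decision_tree", "logistic", "sgd_linear"),
                       hyperparameters = list(), seed = 1L) {
  family <- match.arg(family)
  structure(list(family = family, hyperparameters = hyperparameters, seed = seed),
            class = "model_spec")
}

#' Train a fasting-state classifier
#'
#' Fits the family named in `spec` on a scaled, balanced feature matrix.
#' Standard fits go through established implementations (e1071 SVM,
#' randomForest, rpart, nnet, `stats::glm`); kNN and the linear SGD
#' classifier are small in-package implementations. Training is
#' deterministic given `spec$seed`.
#'
#' @param spec A [model_spec()].
#' @param X Numeric feature matrix with column names.
#' @param y Two-level factor (canonically `fasting` / `non_fasting`; the
#'   second level is the score's positive class).
#' @return A `fitted_model` exposing [predict_labels()] and
#'   [score_model()].
#' @export
train_model <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop_user("train_model requires exactly two classes")
  hp <- spec$hyperparameters
  set.seed(spec$seed)
  pos <- levels(y)[2]
  y01 <- as.numeric(y == pos)
  fit <- switch(spec$family,
    svm_rbf = e1071::svm(x = X, y = y, kernel = "radial",
                         cost = hp$cost %||% 1,
                         gamma = hp$gamma %||% (1 / ncol(X)), scale = FALSE),
    random_forest = randomForest::randomForest(x = X, y = y,
                                               ntree = hp$ntree %||% 300),
    mlp = nnet::nnet(x = X, y = y01, size = hp$size %||% 8,
                     decay = hp$decay %||% 0.01, maxit = hp$maxit %||% 300,
                     entropy = TRUE, trace = FALSE),
    knn = list(X = X, y = y, k = hp$k %||% 5L),
    decision_tree = rpart::rpart(.y ~ ., data = data.frame(X, .y = y),
                                 method = "class",
                                 control = rpart::rpart.control(
                                   cp = hp$cp %||% 0.01,
                                   minsplit = hp$minsplit %||% 20)),
    logistic = suppressWarnings(glm(y01 ~ ., data = data.frame(X, y01 = y01),
                                    family = binomial())),
    sgd_linear = sgd_logistic_fit(X, y01,
                                  epochs = hp$epochs %||% 30L,
                                  learning_rate = hp$learning_rate %||% 0.5,
                                  l2 = hp$l2 %||% 1e-4, seed = spec$seed),
    stop_user("unknown model family: ", spec$family)
  )
  structure(list(spec = spec, family = spec$family, fit = fit,
                 feature_names = colnames(X), levels = levels(y), positive = pos),
            class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("<fitted_model %s on %d features: %s>\n",
              x$family, length(x$feature_names),
              paste(x$feature_names, collapse = ", ")))
  invisible(x)
}

# Seeded stochastic-gradient-descent logistic classifier.
sgd_logistic_fit <- function(X, y01, epochs = 30L, learning_rate = 0.5,
                             l2 = 1e-4, seed = 1L) {
  set.seed(seed)
  n <- nrow(X); d <- ncol(X)
  w <- numeric(d); b <- 0; t <- 0
  for (ep in seq_len(epochs)) {
    for (i in sample.int(n)) {
      t <- t + 1
      lr <- learning_rate / (1 + 1e-3 * t)
      p <- plogis(b + sum(X[i, ] * w))
      g <- p - y01[i]
      w <- w - lr * (g * X[i, ] + l2 * w)
      b <- b - lr * g
    }
  }
  list(w = w, b = b)
}

check_registry <- function(model, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X)) || !identical(colnames(X), model$feature_names))
    stop_user("feature registry mismatch: model expects (",
              paste(model$feature_names, collapse = ", "), ")")
  X
}

#' Continuous classifier score
#'
#' Score of the positive class (the second factor level, canonically
#' `non_fasting`): class probability where the family provides one, decision
#' margin for the SVM, neighbour fraction for kNN.
#'
#' @param model A `fitted_model`.
#' @param X Feature matrix with the training column layout.
#' @return Numeric score vector (higher = more positive-class).
#' @export
score_model <- function(model, X) {
  X <- check_registry(model, X)
  pos <- model$positive
  switch(model$family,
    svm_rbf = {
      dv <- attr(predict(model$fit, X, decision.values = TRUE), "decision.values")
      first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
      if (first == pos) dv[, 1] else -dv[, 1]
    },
    random_forest = predict(model$fit, X, type = "prob")[, pos],
    mlp = as.numeric(predict(model$fit, X)),
    knn = knn_votes(model$fit, X),
    decision_tree = predict(model$fit, data.frame(X), type = "prob")[, pos],
    logistic = as.numeric(predict(model$fit, data.frame(X), type = "response")),
    sgd_linear = plogis(model$fit$b + as.numeric(X %*% model$fit$w))
  )
}

knn_votes <- function(fit, X, chunk = 512L) {
  n <- nrow(X)
  pos <- levels(fit$y)[2]
  is_pos <- fit$y == pos
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- pairwise_sq_dist(X[s:e, , drop = FALSE], fit$X)
    for (r in seq_len(e - s + 1L)) {
      nb <- order(d2[r, ])[seq_len(fit$k)]
      out[s + r - 1L] <- mean(is_pos[nb])
    }
  }
  out
}

#' Predict fasting labels for a window sequence
#'
#' @param model A `fitted_model`.
#' @param X Feature matrix, rows in chronological order; columns must match
#'   the training registry.
#' @return Factor of labels, one per row, order preserved.
#' @export
predict_labels <- function(model, X) {
  X <- check_registry(model, X)
  score <- score_model(model, X)
  lev <- model$levels
  thr <- if (model$family == "svm_rbf") 0 else 0.5 # margin vs probability
  factor(ifelse(score > thr, lev[2], lev[1]), levels = lev)
}

# Importance notion used inside RFE: |coefficient| for linear families,
# impurity importance for tree families.
feature_importance <- function(model) {
  fn <- model$feature_names
  switch(model$family,
    logistic = {
      cf <- coef(model$fit)[-1]
      stats::setNames(abs(as.numeric(cf)), fn)
    },
    sgd_linear = stats::setNames(abs(model$fit$w), fn),
    decision_tree = {
      vi <- model$fit$variable.importance
      out <- stats::setNames(numeric(length(fn)), fn)
      out[names(vi)] <- vi
      out
    },
    random_forest = {
      im <- randomForest::importance(model$fit)
      stats::setNames(im[fn, 1], fn)
    },
    stop_user("family '", model$family, "' has no RFE importance notion; ",
              "use a linear or tree ranker")
  )
}

#' Majority-vote smoothing of a chronological label sequence
#'
#' Each position takes the majority label of the centred window of `k`
#' positions; sequence edges use the available shorter window; exact ties
#' keep the original label.
#'
#' @param labels Factor or character sequence in chronological order.
#' @param k Odd window length (>= 1).
#' @return Smoothed sequence, same type and length.
#' @export
#' @examples
#' smooth_labels(factor(c("n", "n", "n", "f", "n", "n", "n")), k = 5)
smooth_labels <- function(labels, k = 5L) {
  if (k %% 2 == 0) stop_user("k must be odd")
  if (k < 1) stop_user("k must be >= 1")
  n <- length(labels)
  if (k == 1L || n == 0L) return(labels)
  f <- as.factor(labels)
  h <- (k - 1L) %/% 2L
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  counts <- vapply(levels(f), function(lv) {
    cs <- c(0L, cumsum(f == lv))
    cs[hi + 1L] - cs[lo]
  }, numeric(n))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  best <- max.col(counts, ties.method = "first")
  mx <- counts[cbind(seq_len(n), best)]
  tie <- rowSums(counts == mx) > 1L
  out_chr <- levels(f)[best]
  out_chr[tie] <- as.character(labels)[tie]
  if (is.factor(labels)) factor(out_chr, levels = levels(labels)) else out_chr
}

#' Evaluate fasting-state predictions
#'
#' Confusion-matrix metrics with `positive` as the detection target
#' (default `non_fasting`, the fed state): accuracy, precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 (harmonic mean), the accuracy of
#' the smoothed sequence, and a seeded percentile-bootstrap 95% CI of the F1
#' over window resampling. Degenerate ratios (0/0) are defined as 0; the CI
#' is widened, if necessary, to contain the point F1.
#'
#' @param y_true,y_pred Equal-length label sequences.
#' @param y_pred_smoothed Optional smoothed prediction sequence.
#' @param positive Positive-class label.
#' @param bootstrap_n Bootstrap replicates for the F1 CI.
#' @param seed Integer seed for the bootstrap.
#' @return An `eval_report` list: accuracy, smoothed_accuracy, precision,
#'   recall, f1, f1_ci_low, f1_ci_high, tp, fp, fn, tn, n.
#' @export
evaluate <- function(y_true, y_pred, y_pred_smoothed = NULL,
                     positive = "non_fasting", bootstrap_n = 1000L, seed = 1L) {
  if (!length(y_true)) stop_user("empty input")
  stopifnot(length(y_true) == length(y_pred))
  yt <- as.character(y_true) == positive
  yp <- as.character(y_pred) == positive
  f1_of <- function(t, p) {
    tp <- sum(t & p); fp <- sum(!t & p); fn <- sum(t & !p)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }
  tp <- sum(yt & yp); fp <- sum(!yt & yp); fn <- sum(yt & !yp); tn <- sum(!yt & !yp)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  set.seed(seed)
  n <- length(yt)
  boot <- vapply(seq_len(bootstrap_n), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    f1_of(yt[idx], yp[idx])
  }, numeric(1))
  ci <- unname(quantile(boot, c(0.025, 0.975)))
  structure(list(
    accuracy = (tp + tn) / n,
    smoothed_accuracy = if (is.null(y_pred_smoothed)) NA_real_ else
      mean(as.character(y_pred_smoothed) == as.character(y_true)),
    precision = precision, recall = recall, f1 = f1,
    f1_ci_low = min(ci[1], f1), f1_ci_high = max(ci[2], f1),
    tp = tp, fp = fp, fn = fn, tn = tn, n = n, positive = positive
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report n=%d | accuracy %.3f | smoothed %.3f | ",
                     "precision %.3f | recall %.3f | F1 %.3f (%.3f-%.3f)>\n"),
              x$n, x$accuracy, x$smoothed_accuracy, x$precision, x$recall,
              x$f1, x$f1_ci_low, x$f1_ci_high))
  invisible(x)
}
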