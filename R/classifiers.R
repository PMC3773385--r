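#' Classifier specification
#'
#' A single train/predict contract over three back ends:
#' * `knn` — majority vote among the `k` Euclidean-nearest training
#'   vectors. Distance ties are broken by training-set order, vote ties by
#'   the class of the single nearest neighbour among the tied classes.
#' * `pnn` — probabilistic neural network (Parzen kernel density
#'   classifier): per-class averaged Gaussian kernels, predict the argmax.
#'   Score ties (including full kernel underflow) fall back to the class of
#'   the nearest training sample. `spread` is either a fixed kernel width
#'   sigma (> 0), or `"auto"`: a multiplier grid `seq(0.05, 1, 0.05)` of
#'   the RMS pairwise training distance, selected by leave-one-out accuracy
#'   on the training data (smallest multiplier on ties).
#' * `svm` — soft-margin RBF support vector machine (one-vs-one multiclass
#'   via \pkg{e1071}/libsvm) with fixed defaults `C = 10`,
#'   `gamma = 1 / (d * var)` of the standardized training matrix.
#'
#' All back ends see z-score-standardized features; the statistics are
#' always taken from the training fold only.
#'
#' @param kind `"knn"`, `"pnn"` or `"svm"`
#' @param k number of neighbours (odd, >= 1)
#' @param spread PNN kernel width: positive number or `"auto"`
#' @param spread_mult optional fixed multiplier of the RMS pairwise
#'   training distance (overrides the `"auto"` grid; used to freeze an
#'   already-resolved spread)
#' @param C SVM soft-margin cost
#' @param gamma SVM RBF width; `NULL` = `1 / (d * var)`
#' @return list of class `classifier_spec`
#' @export
classifier_spec <- function(kind = c("knn", "pnn", "svm"), k = 3L,
                            spread = "auto", spread_mult = NULL,
                            C = 10, gamma = NULL) {
  kind <- match.arg(kind)
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) stop("`k` must be odd and >= 1")
  if (!(identical(spread, "auto") || (is.numeric(spread) && spread > 0)))
    stop("`spread` must be a positive number or \"auto\"")
  if (!is.null(spread_mult) && !(is.numeric(spread_mult) && spread_mult > 0))
    stop("`spread_mult` must be a positive number")
  structure(list(kind = kind, k = k, spread = spread, spread_mult = spread_mult,
                 C = C, gamma = gamma),
            class = "classifier_spec")
}

# -- standardization ---------------------------------------------------------

# Fit z-score statistics on the training rows only. Zero-spread features get
# unit scale so they pass through as raw (constant) differences.
standardize_fit <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  list(center = center, scale = scale)
}

standardize_apply <- function(X, stats) {
  scale(X, center = stats$center, scale = stats$scale)[, , drop = FALSE]
}

rms_pairwise_distance <- function(Xs) {
  n <- nrow(Xs)
  if (n < 2L) return(0)
  sqrt(mean(stats::dist(Xs)^2))
}

# PNN spread multiplier grid of the "auto" rule.
SPREAD_GRID <- seq(0.05, 1, by = 0.05)

# Resolve an "auto" spread into a fixed multiplier by LOO on (X, y).
resolve_spread <- function(X, y, grid = SPREAD_GRID) {
  yi <- as.integer(as_grade_factor(y)) - 1L
  sub <- seq_len(ncol(X)) - 1L
  acc <- vapply(grid, function(cc) {
    p <- cpp_loo_predict(X, yi, sub, 1L, 3L, -1, cc)
    mean(p == yi)
  }, numeric(1))
  grid[which.max(acc)]  # which.max keeps the smallest multiplier on ties
}

#' Train a classifier
#'
#' @param X numeric matrix of training feature vectors (rows = samples)
#' @param y class labels (one per row; every class needs >= 1 sample)
#' @param spec a [classifier_spec()]
#' @return object of class `texgrade_model` with a [predict][predict.texgrade_model] method
#' @export
fit_classifier <- function(X, y, spec = classifier_spec("knn")) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("training features must be finite")
  y <- as_grade_factor(y)
  if (any(table(y) < 1L)) stop("every class needs at least one training sample")
  if (spec$kind == "knn" && spec$k > nrow(X))
    stop("`k` cannot exceed the number of training samples")
  st <- standardize_fit(X)
  Xs <- standardize_apply(X, st)
  model <- list(spec = spec, stats = st, Xs = Xs, y = y, levels = levels(y))
  if (spec$kind == "pnn") {
    model$sigma <- if (is.numeric(spec$spread)) {
      spec$spread
    } else {
      mult <- if (!is.null(spec$spread_mult)) spec$spread_mult else resolve_spread(X, y)
      model$spread_mult <- mult
      mult * rms_pairwise_distance(Xs)
    }
    if (!is.finite(model$sigma) || model$sigma <= 0)
      stop("resolved PNN spread must be positive")
  }
  if (spec$kind == "svm") {
    gamma <- if (!is.null(spec$gamma)) spec$gamma else 1 / (ncol(X) * var(as.vector(Xs)))
    model$svm <- e1071::svm(x = Xs, y = y, scale = FALSE, kernel = "radial",
                            cost = spec$C, gamma = gamma)
    model$gamma <- gamma
  }
  class(model) <- "texgrade_model"
  model
}

#' Predict grades for new feature vectors
#'
#' Queries are standardized with the training-fold statistics stored in the
#' model; the prediction is always a label from the training label set.
#'
#' @param object a fitted `texgrade_model`
#' @param newdata numeric matrix (or vector) of query feature vectors
#' @param ... unused
#' @return factor of predicted labels; for PNN, per-class scores are
#'   attached as attribute `"scores"`
#' @export
predict.texgrade_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (!all(is.finite(newdata))) stop("query features must be finite")
  Qs <- standardize_apply(newdata, object$stats)
  out <- switch(object$spec$kind,
                knn = predict_knn(object, Qs),
                pnn = predict_pnn(object, Qs),
                svm = {
                  p <- predict(object$svm, Qs)
                  factor(as.character(p), levels = object$levels)
                })
  out
}

# squared Euclidean distances from one query row to all training rows
.q_dist2 <- function(Xs, q) colSums((t(Xs) - q)^2)

predict_knn <- function(model, Qs) {
  k <- model$spec$k
  yi <- as.integer(model$y)
  pred <- apply(Qs, 1, function(q) {
    d2 <- .q_dist2(model$Xs, q)
    sel <- order(d2)[seq_len(k)]        # order() is stable: ties by index
    votes <- tabulate(yi[sel], nbins = length(model$levels))
    tied <- which(votes == max(votes))
    if (length(tied) > 1L) {
      yi[sel[yi[sel] %in% tied][1]]     # nearest neighbour among tied classes
    } else tied
  })
  factor(model$levels[pred], levels = model$levels)
}

predict_pnn <- function(model, Qs) {
  yi <- as.integer(model$y)
  nc <- tabulate(yi, nbins = length(model$levels))
  sig2 <- 2 * model$sigma^2
  scores <- matrix(0, nrow(Qs), length(model$levels),
                   dimnames = list(NULL, model$levels))
  pred <- integer(nrow(Qs))
  for (r in seq_len(nrow(Qs))) {
    d2 <- .q_dist2(model$Xs, Qs[r, ])
    kern <- exp(-d2 / sig2)
    sc <- as.vector(rowsum(kern, yi)) / nc[sort(unique(yi))]
    s <- numeric(length(model$levels))
    s[sort(unique(yi))] <- sc
    scores[r, ] <- s
    best <- max(s)
    tied <- which(s == best)
    pred[r] <- if (length(tied) > 1L || best <= 0) yi[which.min(d2)] else tied
  }
  structure(factor(model$levels[pred], levels = model$levels), scores = scores)
}

#' Leave-one-out predictions for a labeled dataset
#'
#' Each sample is predicted by a model trained on all others;
#' standardization (and, for SVM, the fit) is redone per round. For kNN and
#' PNN an exact closed-form fast path is used; `naive = TRUE` forces the
#' literal fit/predict loop (the two paths are equivalent and the test
#' suite asserts it).
#'
#' @param X numeric feature matrix
#' @param y labels
#' @param spec a [classifier_spec()]; an `"auto"` PNN spread is resolved
#'   once on the full data, then applied per fold as a fixed multiplier
#' @param naive force the literal per-round loop
#' @return factor of leave-one-out predictions
#' @export
loo_predict <- function(X, y, spec, naive = FALSE) {
  X <- as.matrix(X)
  y <- as_grade_factor(y)
  n <- nrow(X)
  if (n < length(levels(y)) + 1L) stop("need at least one more sample than classes")
  spec <- resolve_spec_for_loo(X, y, spec)
  if (!naive && spec$kind %in% c("knn", "pnn")) {
    yi <- as.integer(y) - 1L
    method <- if (spec$kind == "knn") 0L else 1L
    sig_abs <- if (spec$kind == "pnn" && is.numeric(spec$spread)) spec$spread else -1
    sig_mult <- if (spec$kind == "pnn" && sig_abs < 0) spec$spread_mult else 1
    p <- cpp_loo_predict(X, yi, seq_len(ncol(X)) - 1L, method, spec$k, sig_abs, sig_mult)
    return(factor(levels(y)[p + 1L], levels = levels(y)))
  }
  preds <- character(n)
  for (i in seq_len(n)) {
    ytr <- droplevels(y[-i])
    if (nlevels(ytr) < nlevels(y))
      warning("round ", i, ": a class is absent from the training fold; ",
              "predicting among the remaining classes")
    m <- fit_classifier(X[-i, , drop = FALSE], as.character(ytr), spec)
    preds[i] <- as.character(predict(m, X[i, , drop = FALSE]))
  }
  factor(preds, levels = levels(y))
}

# Freeze an "auto" PNN spread into a multiplier so that every LOO round (and
# every subset of a search) applies the same, comparably-scaled rule.
resolve_spec_for_loo <- function(X, y, spec) {
  if (spec$kind == "pnn" && identical(spec$spread, "auto") && is.null(spec$spread_mult))
    spec$spread_mult <- resolve_spread(as.matrix(X), y)
  spec
}
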