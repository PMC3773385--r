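#' Build an evaluation result from true and predicted labels
#'
#' Wraps a confusion matrix (true x predicted) together with the per-class
#' ("partial") accuracies and the overall accuracy, all in percent.
#' Conservation (row sums = class counts; overall = 100 trace / total) is
#' asserted at construction.
#'
#' @param true true labels
#' @param pred predicted labels
#' @param subset feature subset used (metadata only)
#' @return object of class `evaluation_result`
#' @export
evaluation_result <- function(true, pred, subset = NULL) {
  true <- as_grade_factor(true)
  pred <- factor(as.character(pred), levels = levels(true))
  if (anyNA(pred)) stop("predictions outside the label set")
  cm <- table(true = true, predicted = pred)
  n <- sum(cm)
  partial <- 100 * diag(cm) / pmax(rowSums(cm), 1L)
  overall <- 100 * sum(diag(cm)) / n
  stopifnot(all(rowSums(cm) == tabulate(true, nbins = nlevels(true))),
            isTRUE(all.equal(overall, 100 * sum(diag(cm)) / n)))
  structure(list(confusion = cm, partial = partial, overall = overall,
                 subset = subset),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> overall %.1f%%  partial: %s\n",
              x$overall,
              paste(sprintf("%s %.1f%%", names(x$partial), x$partial),
                    collapse = ", ")))
  if (!is.null(x$subset))
    cat("  features:", paste(x$subset, collapse = ", "), "\n")
  print(x$confusion)
  invisible(x)
}

#' Leave-one-out evaluation with a fixed feature subset
#'
#' Runs n train/predict rounds, each holding out one sample;
#' standardization (and the SVM fit) is redone per round. The feature
#' subset is fixed throughout — subset selection, when wanted inside the
#' evaluation, belongs to [ecv_evaluate()].
#'
#' @param table feature table or numeric matrix
#' @param labels class labels; defaults to `table$grade`
#' @param spec a [classifier_spec()]
#' @param subset feature names to use (default: all feature columns)
#' @return an [evaluation_result()]
#' @export
loo_evaluate <- function(table, labels = table$grade,
                         spec = classifier_spec("knn"), subset = NULL) {
  X <- if (is.matrix(table)) table else feature_matrix(table, subset)
  if (is.matrix(table) && !is.null(subset)) X <- X[, subset, drop = FALSE]
  y <- as_grade_factor(labels)
  pred <- loo_predict(X, y, spec)
  evaluation_result(y, pred, subset = colnames(X))
}

#' Stratified train/test split
#'
#' Draws `floor(n_c * test_fraction)` test samples per class without
#' replacement, deterministically for a given seed; the remainder trains.
#'
#' @param labels class labels
#' @param test_fraction fraction of each class held out (default 1/3)
#' @param seed integer RNG seed
#' @return list with sorted integer vectors `train` and `test`
#' @export
stratified_split <- function(labels, test_fraction = 1 / 3, seed = 1L) {
  g <- as_grade_factor(labels)
  counts <- tabulate(g, nbins = nlevels(g))
  if (any(counts < 3L))
    stop("every class needs at least 3 members for a ", signif(test_fraction, 3),
         " split; class sizes: ", paste(counts, collapse = ", "))
  test <- withr::with_seed(as.integer(seed), {
    unlist(lapply(levels(g), function(lv) {
      idx <- which(g == lv)
      sample(idx, floor(length(idx) * test_fraction))
    }), use.names = FALSE)
  })
  test <- sort(test)
  list(train = setdiff(seq_along(g), test), test = test)
}

#' External cross-validation over repeated stratified splits
#'
#' Per trial: a stratified 2/3 design / 1/3 evaluation split; the
#' significance filter and the exhaustive subset search run on the design
#' fold ONLY; the final model is trained on the design fold with the
#' selected subset and evaluated once on the held-out fold. Per-trial seeds
#' are `master_seed + trial`, so trials are independent but reproducible.
#'
#' @inheritParams loo_evaluate
#' @param n_trials number of random splits
#' @param master_seed integer master seed
#' @param alpha significance-filter threshold
#' @param max_subset_size largest subset enumerated in the search
#' @param candidate_features candidate features entering the filter
#' @return object of class `ecv_result`: per-trial `results`, `subsets`,
#'   `subset_sizes`, `splits`, and a `summary` from [summarize_trials()]
#' @export
ecv_evaluate <- function(table, labels = table$grade,
                         spec = classifier_spec("pnn"), n_trials = 10L,
                         master_seed = 1L, alpha = 0.001, max_subset_size = 5L,
                         candidate_features = NULL) {
  X <- if (is.matrix(table)) table else feature_matrix(table, candidate_features)
  y <- as_grade_factor(labels)
  stopifnot(n_trials >= 1L)
  trials <- vector("list", n_trials)
  subsets <- vector("list", n_trials)
  splits <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    sp <- stratified_split(y, seed = as.integer(master_seed) + t)
    Xtr <- X[sp$train, , drop = FALSE]
    ytr <- y[sp$train]
    filt <- significance_filter(Xtr, ytr, alpha = alpha)
    cand <- filt$retained
    if (!length(cand)) {
      warning("trial ", t, ": no feature passed the filter; ",
              "falling back to the minimum-p feature")
      cand <- names(which.min(filt$pvalues))
    }
    if (spec$kind == "svm") cand <- cand[order(filt$pvalues[cand])]
    best <- exhaustive_search(Xtr, ytr, spec, candidate_features = cand,
                              max_subset_size = max_subset_size)
    model <- fit_classifier(Xtr[, best$features, drop = FALSE], ytr, best$spec)
    pred <- predict(model, X[sp$test, best$features, drop = FALSE])
    trials[[t]] <- evaluation_result(y[sp$test], pred, subset = best$features)
    subsets[[t]] <- best$features
    splits[[t]] <- sp
  }
  acc <- t(vapply(trials, function(r) c(r$partial, overall = r$overall),
                  numeric(length(levels(y)) + 1L)))
  structure(list(results = trials, subsets = subsets,
                 subset_sizes = lengths(subsets), splits = splits,
                 accuracies = acc, summary = summarize_trials(acc),
                 spec = spec, master_seed = master_seed),
            class = "ecv_result")
}

#' @export
print.ecv_result <- function(x, ...) {
  cat(sprintf("<ecv_result> %d trials (%s)\n", nrow(x$accuracies), x$spec$kind))
  for (t in seq_len(nrow(x$accuracies)))
    cat(sprintf("  trial %2d: overall %5.1f%%  (%d features)\n",
                t, x$accuracies[t, "overall"], x$subset_sizes[t]))
  s <- x$summary
  cat("  mean +/- std:",
      paste(sprintf("%s %.1f +/- %.1f", colnames(x$accuracies),
                    s$mean, s$sd), collapse = ";  "), "\n")
  invisible(x)
}

#' Mean and sample standard deviation across trials
#'
#' Arithmetic mean and sample (n - 1 denominator) standard deviation per
#' accuracy column, with one-decimal half-up rounded versions for
#' reporting.
#'
#' @param acc numeric matrix or data frame, trials in rows
#' @return list with `mean`, `sd`, `mean_1dp`, `sd_1dp` (named per column)
#' @export
summarize_trials <- function(acc) {
  acc <- as.matrix(acc)
  if (nrow(acc) < 2L) stop("need at least 2 trials to summarize")
  m <- colMeans(acc)
  s <- apply(acc, 2, sd)
  list(mean = m, sd = s,
       mean_1dp = round_half_up(m, 1), sd_1dp = round_half_up(s, 1))
}
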