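#' Significance filter over the texture features
#'
#' Retains the features whose per-feature one-way ANOVA across the grade
#' groups is significant at `alpha` (default 0.001). Features with zero
#' total variance carry no class signal, are assigned p = 1 and dropped
#' with a warning; features with zero within-class but positive
#' between-class variance are retained with p = 0 (the degenerate
#' F -> infinity limit). A dataset-level Wilks'-lambda MANOVA p-value is
#' computed for reference (`wilks_p`) but does not gate features.
#'
#' @param table feature table (data frame with feature columns) or numeric
#'   matrix
#' @param labels class labels; defaults to `table$grade`
#' @param alpha retention threshold on the per-feature p-value
#' @param features candidate feature columns (default: all feature columns
#'   present)
#' @return object of class `filter_result` with `pvalues`, `retained`,
#'   `alpha`, `wilks_p`
#' @export
significance_filter <- function(table, labels = table$grade, alpha = 0.001,
                                features = NULL) {
  X <- if (is.matrix(table)) table else feature_matrix(table, features)
  if (is.matrix(table) && !is.null(features)) X <- X[, features, drop = FALSE]
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  g <- as_grade_factor(labels)
  if (nlevels(g) < 2L) stop("need at least 2 classes")
  if (any(tabulate(g) < 2L)) stop("need at least 2 samples per class")
  pvals <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    if (var(x) == 0) return(1)
    p <- tryCatch(oneway.test(x ~ g, var.equal = TRUE)$p.value,
                  error = function(e) NaN)
    if (is.nan(p)) {
      # zero residual variance: F degenerates; sign of the between-class SS decides
      betw <- var(ave(x, g))
      p <- if (betw > 0) 0 else 1
    }
    p
  }, numeric(1))
  names(pvals) <- colnames(X)
  zerovar <- apply(X, 2, var) == 0
  if (any(zerovar))
    warning("dropping zero-variance feature(s): ",
            paste(colnames(X)[zerovar], collapse = ", "))
  # Wilks' lambda is only defined for p < n - g; skip it otherwise
  wilks_p <- tryCatch({
    Xv <- X[, !zerovar, drop = FALSE]
    if (ncol(Xv) >= nrow(Xv) - nlevels(g)) NA_real_ else {
      fit <- manova(Xv ~ g)
      s <- summary(fit, test = "Wilks")$stats
      unname(s[1, "Pr(>F)"])
    }
  }, error = function(e) NA_real_)
  structure(list(pvalues = pvals,
                 retained = colnames(X)[pvals < alpha & !zerovar],
                 alpha = alpha, wilks_p = wilks_p),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("<filter_result> %d/%d features retained at p < %g (Wilks p = %s)\n",
              length(x$retained), length(x$pvalues), x$alpha,
              format(x$wilks_p, digits = 3)))
  invisible(x)
}

#' Exhaustive feature-subset search scored by leave-one-out accuracy
#'
#' Evaluates the leave-one-out overall accuracy of every feature subset of
#' size `1..max_subset_size` drawn from `candidate_features` and returns
#' the best one. Ties are broken deterministically: higher accuracy first,
#' then smaller subset, then lexicographic feature-name order. When a
#' subset size reaches a perfect score, the remaining (larger) sizes are
#' skipped: under the strict-improvement tie-break no larger subset can
#' win, so the shortcut is exact. An `"auto"`
#' PNN spread is resolved once per search (on the full candidate set) so
#' that all subset scores share the same spread rule. With the SVM back end
#' the candidate set is truncated to `svm_max_candidates` features (in the
#' order given, which downstream callers rank by filter p-value), because
#' libsvm must be refit n times per subset.
#'
#' @param table feature table or numeric matrix
#' @param labels class labels; defaults to `table$grade`
#' @param spec a [classifier_spec()] used for scoring
#' @param candidate_features candidate feature names (default: all feature
#'   columns)
#' @param max_subset_size largest subset size enumerated
#' @param svm_max_candidates candidate cap for the SVM back end
#' @return object of class `best_subset` with `features`, `accuracy`
#'   (fraction), `n_evaluated`, `spec`
#' @export
exhaustive_search <- function(table, labels = table$grade,
                              spec = classifier_spec("knn"),
                              candidate_features = NULL, max_subset_size = 5L,
                              svm_max_candidates = 8L) {
  X <- if (is.matrix(table)) table else feature_matrix(table, candidate_features)
  if (is.matrix(table) && !is.null(candidate_features))
    X <- X[, candidate_features, drop = FALSE]
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (ncol(X) < 1L) stop("`candidate_features` must be nonempty")
  stopifnot(max_subset_size >= 1L)
  y <- as_grade_factor(labels)
  if (spec$kind == "svm" && ncol(X) > svm_max_candidates)
    X <- X[, colnames(X)[seq_len(svm_max_candidates)], drop = FALSE]
  feats <- sort(colnames(X))
  X <- X[, feats, drop = FALSE]
  k <- length(feats)
  m <- min(max_subset_size, k)
  spec <- resolve_spec_for_loo(X, y, spec)

  best_acc <- -1
  best_set <- NULL
  n_eval <- 0L
  yi <- as.integer(y) - 1L
  for (s in seq_len(m)) {
    idx <- combn(k, s)   # columns in lexicographic order of sorted names
    if (spec$kind %in% c("knn", "pnn")) {
      subsets <- lapply(seq_len(ncol(idx)), function(j) idx[, j] - 1L)
      method <- if (spec$kind == "knn") 0L else 1L
      sig_abs <- if (spec$kind == "pnn" && is.numeric(spec$spread)) spec$spread else -1
      sig_mult <- if (spec$kind == "pnn" && sig_abs < 0) spec$spread_mult else 1
      accs <- cpp_loo_score_subsets(X, yi, subsets, method, spec$k, sig_abs, sig_mult)
    } else {
      accs <- vapply(seq_len(ncol(idx)), function(j) {
        tryCatch(mean(loo_predict(X[, idx[, j], drop = FALSE], y, spec) == y),
                 error = function(e) {
                   warning("classifier failed on a subset; scored 0: ",
                           conditionMessage(e))
                   0
                 })
      }, numeric(1))
    }
    n_eval <- n_eval + ncol(idx)
    j_best <- which.max(accs)           # first max: lexicographic tie-break
    if (accs[j_best] > best_acc) {      # strict: smaller subsets win ties
      best_acc <- accs[j_best]
      best_set <- feats[idx[, j_best]]
    }
    # A perfect score cannot be beaten, and ties go to smaller subsets, so
    # the result over the remaining sizes is already determined: stop.
    if (best_acc == 1) break
  }
  stopifnot(n_eval == sum(choose(k, seq_len(s))))
  structure(list(features = best_set, accuracy = best_acc,
                 n_evaluated = n_eval, spec = spec),
            class = "best_subset")
}

#' @export
print.best_subset <- function(x, ...) {
  cat(sprintf("<best_subset> {%s}  LOO accuracy %.1f%%  (%d subsets evaluated, %s)\n",
              paste(x$features, collapse = ", "), 100 * x$accuracy,
              x$n_evaluated, x$spec$kind))
  invisible(x)
}
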