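#' Cross-validated AUCs of SVM and random-forest comparison models
#'
#' Benchmarks the two machine-learning comparison classifiers against the
#' logistic pipeline: an RBF-kernel support vector machine
#' ([e1071::svm()] with default regularisation) and a random forest
#' ([randomForest::randomForest()] with default settings).  Both are
#' evaluated by the same seeded stratified k-fold cross-validation as the
#' lasso screen; held-out class probabilities are pooled and scored with
#' [roc_analysis()] in the fixed `above_positive` orientation.  The
#' contract is reproducibility under a fixed seed, not specific AUC
#' values.
#'
#' @param table data.frame with a binary `label` column and feature
#'   columns.
#' @param features feature column names.
#' @param folds number of CV folds (default 10).
#' @param seed seed controlling fold assignment and model fitting.
#' @return named list with elements `svm` and `random_forest`, each a list
#'   of `auc` and the pooled out-of-fold `scores`.
#' @export
comparison_classifiers <- function(table, features, folds = 10L, seed = 1L) {
  y <- binary_label(table$label)
  if (length(unique(y)) != 2) stop("label must contain both classes", call. = FALSE)
  X <- as.matrix(table[, features, drop = FALSE])
  yf <- factor(ifelse(y == 1, "rec", "no_rec"), levels = c("no_rec", "rec"))
  fold <- make_stratified_folds(y, folds, seed)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  svm_scores <- rf_scores <- rep(NA_real_, length(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) next
    set.seed(seed + f)
    sv <- e1071::svm(X[tr, , drop = FALSE], yf[tr], kernel = "radial",
                     probability = TRUE, scale = TRUE)
    pr <- attr(stats::predict(sv, X[!tr, , drop = FALSE], probability = TRUE),
               "probabilities")
    svm_scores[!tr] <- pr[, "rec"]
    set.seed(seed + f)
    rf <- randomForest::randomForest(X[tr, , drop = FALSE], yf[tr])
    rf_scores[!tr] <- stats::predict(rf, X[!tr, , drop = FALSE],
                                     type = "prob")[, "rec"]
  }
  ok <- !is.na(svm_scores)
  list(svm = list(auc = roc_analysis(svm_scores[ok], y[ok],
                                     direction = "above_positive")$auc,
                  scores = svm_scores),
       random_forest = list(auc = roc_analysis(rf_scores[ok], y[ok],
                                               direction = "above_positive")$auc,
                            scores = rf_scores))
}
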