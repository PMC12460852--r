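#' Empirical ROC analysis with Youden cutpoint
#'
#' Builds the empirical ROC curve of a score against a binary label over
#' all distinct score cutpoints.  The AUC is computed as the Mann-Whitney
#' statistic `U / (n1 * n0)` with ties counted 1/2, which equals the
#' trapezoidal area under the empirical curve.  The Youden threshold
#' maximises `sensitivity + specificity - 1`; ties are broken toward the
#' cutpoint with higher specificity.
#'
#' Direction: with `"below_positive"` a case is called positive when its
#' score is strictly below the threshold (the convention of the
#' recurrence-location rule, where low max/mean ADC ratios mark the
#' recurrence-prone region); `"above_positive"` is the reverse.  With
#' `"auto"` (default) the orientation giving AUC >= 0.5 on the data is
#' chosen.
#'
#' @param scores numeric vector.
#' @param labels binary labels; `"rec"`, `TRUE` or 1 is the positive class.
#' @param direction `"auto"`, `"below_positive"` or `"above_positive"`.
#' @return An object of class `roc_curve` with fields `thresholds`,
#'   `sensitivity`, `specificity`, `auc`, `youden_threshold`, `youden_j`,
#'   `direction`.
#' @export
roc_analysis <- function(scores, labels,
                         direction = c("auto", "below_positive",
                                       "above_positive")) {
  direction <- match.arg(direction)
  y <- binary_label(labels)
  stopifnot(length(scores) == length(y))
  if (anyNA(scores)) stop("missing scores not supported", call. = FALSE)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present", call. = FALSE)

  # Mann-Whitney AUC for the above_positive orientation, ties at 1/2
  r <- rank(scores)
  auc_above <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (direction == "auto")
    direction <- if (auc_above >= 0.5) "above_positive" else "below_positive"
  auc <- if (direction == "above_positive") auc_above else 1 - auc_above

  # candidate thresholds: all distinct scores plus sentinels so that the
  # all-positive and all-negative rules are both reachable
  u <- sort(unique(scores))
  if (direction == "below_positive") {
    thr <- c(u, Inf)                        # positive iff score <  t
    sens <- vapply(thr, function(t) mean(scores[y == 1] < t), 0)
    spec <- vapply(thr, function(t) mean(scores[y == 0] >= t), 0)
  } else {
    thr <- c(-Inf, u)                       # positive iff score >  t
    sens <- vapply(thr, function(t) mean(scores[y == 1] > t), 0)
    spec <- vapply(thr, function(t) mean(scores[y == 0] <= t), 0)
  }
  j <- sens + spec - 1
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[which.max(spec[best])]

  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, youden_threshold = thr[best], youden_j = j[best],
                 youden_sensitivity = sens[best],
                 youden_specificity = spec[best], direction = direction,
                 n_positive = n1, n_negative = n0),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC %.3f (%s); Youden threshold %.4g (sens %.1f%%, spec %.1f%%)\n",
              x$auc, x$direction, x$youden_threshold,
              100 * x$youden_sensitivity, 100 * x$youden_specificity))
  invisible(x)
}
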