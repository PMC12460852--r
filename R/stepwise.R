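#' Forward stepwise logistic regression
#'
#' Greedy forward selection for a binomial GLM: at each step the candidate
#' with the smallest likelihood-ratio p-value against the current model is
#' admitted while that p-value is below `alpha_entry`.  The final model is
#' refit by IRLS to convergence ([stats::glm()] with a tight epsilon), and
#' Wald p-values and odds ratios are reported per included feature.  If no
#' candidate passes entry (or `candidates` is empty) the intercept-only
#' model is returned with `intercept_only = TRUE`.
#'
#' Candidates are normally the features surviving the lasso screen
#' ([lasso_logistic_path()]).
#'
#' @param table data.frame with a binary `label` column and feature
#'   columns.
#' @param candidates character vector of candidate feature names.
#' @param alpha_entry likelihood-ratio entry threshold (default 0.05).
#' @return An object of class `stepwise_logistic`: `included_features`
#'   (in entry order), `coefficients`, `odds_ratios`, `p_values` (Wald),
#'   `entry_p_values` (likelihood-ratio), `n_obs`, `intercept_only`, `fit`.
#' @export
forward_stepwise_logistic <- function(table, candidates, alpha_entry = 0.05) {
  y <- binary_label(table$label)
  dat <- cbind(data.frame(.y = y),
               table[, setdiff(candidates, character(0)), drop = FALSE])
  included <- character(0)
  entry_p <- numeric(0)
  remaining <- candidates

  fit_model <- function(feats) {
    fml <- if (length(feats))
      stats::as.formula(paste(".y ~", paste(feats, collapse = " + ")))
    else stats::as.formula(".y ~ 1")
    suppressWarnings(stats::glm(fml, data = dat, family = stats::binomial(),
                                control = list(epsilon = 1e-10, maxit = 100)))
  }

  current <- fit_model(included)
  while (length(remaining) > 0 && alpha_entry > 0) {
    ps <- vapply(remaining, function(f) {
      cand <- fit_model(c(included, f))
      stats::pchisq(current$deviance - cand$deviance, df = 1,
                    lower.tail = FALSE)
    }, 0)
    best <- which.min(ps)
    if (ps[best] >= alpha_entry) break
    included <- c(included, remaining[best])
    entry_p <- c(entry_p, ps[best])
    remaining <- remaining[-best]
    current <- fit_model(included)
  }

  sm <- summary(current)$coefficients
  coefs <- stats::coef(current)
  feat_idx <- setdiff(names(coefs), "(Intercept)")
  structure(list(included_features = included,
                 coefficients = coefs,
                 odds_ratios = exp(coefs[feat_idx]),
                 p_values = stats::setNames(sm[feat_idx, "Pr(>|z|)"], feat_idx),
                 entry_p_values = stats::setNames(entry_p, included),
                 n_obs = nrow(dat),
                 intercept_only = length(included) == 0,
                 alpha_entry = alpha_entry,
                 fit = current),
            class = "stepwise_logistic")
}

#' @export
print.stepwise_logistic <- function(x, ...) {
  if (x$intercept_only) {
    cat("<stepwise_logistic> intercept-only model (no candidate passed entry)\n")
  } else {
    cat(sprintf("<stepwise_logistic> n=%d; features: %s\n", x$n_obs,
                paste(x$included_features, collapse = ", ")))
    for (f in x$included_features)
      cat(sprintf("  %s: coef %.4f, OR %.3f, Wald p %.4g\n", f,
                  x$coefficients[f], x$odds_ratios[f], x$p_values[f]))
  }
  invisible(x)
}

#' Linear predictor scores of a stepwise model
#'
#' @param model a [forward_stepwise_logistic()] result.
#' @param table data.frame with the model's feature columns.
#' @return numeric vector of linear-predictor scores.
#' @export
stepwise_scores <- function(model, table) {
  as.numeric(stats::predict(model$fit, newdata = table, type = "link"))
}

#' Plain-text model report
#'
#' Writes a summary table of the screening and stepwise stage: one row per
#' candidate feature with its lasso keep/drop status and, if included in
#' the stepwise model, the Wald p-value and odds ratio.
#'
#' @param lasso a [lasso_logistic_path()] result.
#' @param model a [forward_stepwise_logistic()] result.
#' @param path output file; a data.frame is returned invisibly.
#' @export
write_model_report <- function(lasso, model, path = NULL) {
  feats <- lasso$features
  rep <- data.frame(
    feature = feats,
    lasso = ifelse(feats %in% lasso$selected_features, "keep", "drop"),
    p_value = vapply(feats, function(f)
      if (f %in% model$included_features) model$p_values[f] else NA_real_, 0),
    odds_ratio = vapply(feats, function(f)
      if (f %in% model$included_features) model$odds_ratios[f] else NA_real_, 0))
  if (!is.null(path)) utils::write.csv(rep, path, row.names = FALSE)
  invisible(rep)
}
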