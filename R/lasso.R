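#' @useDynLib edemarec, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# deterministic stratified fold assignment
make_stratified_folds <- function(y, k, seed) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

binary_label <- function(x) {
  if (is.logical(x)) return(as.numeric(x))
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) stop("numeric labels must be 0/1", call. = FALSE)
    return(x)
  }
  u <- sort(unique(as.character(x)))
  if (length(u) != 2) stop("label must be binary", call. = FALSE)
  # "rec" (or the alphabetically later level) codes as 1
  pos <- if ("rec" %in% u) "rec" else u[2]
  as.numeric(as.character(x) == pos)
}

#' L1-penalised logistic regression path with cross-validated lambda
#'
#' Fits the lasso-penalised logistic regression used to screen the eight
#' histogram features before stepwise modelling.  The solver is cyclic
#' coordinate descent inside an IRLS loop, run over a log-spaced lambda
#' grid from `lambda_max` (the smallest penalty at which all coefficients
#' are zero, computed from the score of the null model) down four decades.
#' Features are standardised internally; the intercept is unpenalised.
#' `lambda_min` is chosen by k-fold cross-validation (stratified by label,
#' fold assignment seeded) minimising mean binomial deviance.
#'
#' @param table data.frame with a binary `label` column (`"rec"` coded as
#'   the positive class) and the feature columns.
#' @param features character vector of feature column names (>= 2).
#' @param folds number of CV folds (default 10).
#' @param seed seed for the fold assignment.
#' @param nlambda number of grid points (default 100).
#' @param lambda_min_ratio ratio of the smallest to largest lambda
#'   (default 1e-4).
#' @return An object of class `lasso_path`: `lambda_grid`, `beta`
#'   (standardised scale, p x nlambda), `coef_path` (original scale,
#'   including intercept row), `cv_mean`, `cv_sd`, `lambda_min`,
#'   `selected_features`, `kkt_max_residual`, `separated`.
#' @export
lasso_logistic_path <- function(table, features, folds = 10L, seed = 1L,
                                nlambda = 100L, lambda_min_ratio = 1e-4) {
  if (length(features) < 2) stop("need at least 2 features", call. = FALSE)
  y <- binary_label(table$label)
  if (length(unique(y)) != 2) stop("label must contain both classes", call. = FALSE)
  X <- as.matrix(table[, features, drop = FALSE])
  storage.mode(X) <- "double"
  n <- nrow(X)

  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) stop("constant feature column(s): ",
                          paste(features[scl == 0], collapse = ", "),
                          call. = FALSE)
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)

  lambda_max <- max(abs(crossprod(Xs, y - mean(y)))) / n
  lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                    length.out = nlambda))

  fit <- lasso_logistic_cd(Xs, y, lambda)
  if (any(fit$separated))
    warning("separation detected at small lambda; path truncated",
            call. = FALSE)
  usable <- !fit$separated
  if (!any(usable)) stop("lasso path separated immediately", call. = FALSE)

  # KKT residuals: |score_j| <= lambda (+tol) for inactive, == lambda for active
  kkt <- 0
  for (l in which(usable)) {
    eta <- fit$b0[l] + Xs %*% fit$beta[, l]
    pr <- 1 / (1 + exp(-eta))
    g <- as.numeric(crossprod(Xs, y - pr)) / n
    act <- fit$beta[, l] != 0
    res <- max(c(abs(g[act] - lambda[l] * sign(fit$beta[act, l])),
                 pmax(abs(g[!act]) - lambda[l], 0), 0))
    kkt <- max(kkt, res)
  }

  # stratified CV over the same grid
  fold <- make_stratified_folds(y, folds, seed)
  cvdev <- matrix(NA_real_, folds, nlambda)
  for (f in seq_len(folds)) {
    tr <- fold != f
    Xtr <- Xs[tr, , drop = FALSE]
    # re-standardise the training block so each CV fit is self-contained
    ctr_f <- colMeans(Xtr); scl_f <- apply(Xtr, 2, stats::sd)
    scl_f[scl_f == 0] <- 1
    Xtr <- sweep(sweep(Xtr, 2, ctr_f), 2, scl_f, `/`)
    Xte <- sweep(sweep(Xs[!tr, , drop = FALSE], 2, ctr_f), 2, scl_f, `/`)
    ft <- lasso_logistic_cd(Xtr, y[tr], lambda)
    eta <- sweep(Xte %*% ft$beta, 2, ft$b0, `+`)
    pr <- 1 / (1 + exp(-eta))
    pr <- pmin(pmax(pr, 1e-10), 1 - 1e-10)
    yt <- y[!tr]
    dev <- -2 * (yt * log(pr) + (1 - yt) * log(1 - pr))
    cvdev[f, ] <- colMeans(dev)
    cvdev[f, ft$separated] <- NA
  }
  cv_mean <- colMeans(cvdev)
  cv_sd <- apply(cvdev, 2, stats::sd)
  cv_mean[!usable] <- NA
  imin <- which.min(cv_mean)
  lambda_min <- lambda[imin]
  selected <- features[fit$beta[, imin] != 0]

  beta_orig <- sweep(fit$beta, 1, scl, `/`)
  b0_orig <- fit$b0 - as.numeric(crossprod(ctr, beta_orig))
  coef_path <- rbind(`(Intercept)` = b0_orig, beta_orig)
  rownames(coef_path) <- c("(Intercept)", features)
  rownames(fit$beta) <- features

  structure(list(lambda_grid = lambda, beta = fit$beta, coef_path = coef_path,
                 cv_mean = cv_mean, cv_sd = cv_sd, lambda_min = lambda_min,
                 lambda_min_index = imin, selected_features = selected,
                 kkt_max_residual = kkt, separated = fit$separated,
                 deviance = fit$deviance, features = features,
                 center = ctr, scale = scl),
            class = "lasso_path")
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf("<lasso_path> %d lambdas in [%.3g, %.3g]; lambda_min = %.4g; selected: %s\n",
              length(x$lambda_grid), min(x$lambda_grid), max(x$lambda_grid),
              x$lambda_min,
              if (length(x$selected_features)) paste(x$selected_features, collapse = ", ")
              else "(none)"))
  invisible(x)
}
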