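#' Spearman rank correlation with an exact small-sample p-value
#'
#' Computes rho as the Pearson correlation of mid-ranks (average ranks for
#' ties).  For `n <= exact_n` the two-sided p-value is obtained by full
#' enumeration of all n! rank permutations; for larger n the t
#' approximation `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of
#' freedom is used.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param exact_n largest n for which the permutation null is enumerated
#'   (default 10).
#' @return list with `rho`, `p_value`, `n`, `method`.
#' @export
spearman_test <- function(x, y, exact_n = 10L) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not supported", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("rho undefined for constant input", call. = FALSE)
  rho <- stats::cor(rx, ry)
  if (n <= exact_n) {
    p <- exact_spearman_p(rx, ry)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = min(p, 1), n = n, method = method)
}

# permutations of 1..n as an n! x n integer matrix (n <= 9)
perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- perm_matrix(n - 1L)
  blocks <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    blocks[[k]] <- cbind(rep.int(k, nrow(p)),
                         matrix(rest[p], nrow(p), n - 1L))
  }
  do.call(rbind, blocks)
}

# exact two-sided permutation p for the rank cross-product statistic.
# |rho| >= |rho_obs|  <=>  |S - E S| >= |S_obs - E S| with S = sum(rx * ry).
exact_spearman_p <- function(rx, ry) {
  n <- length(rx)
  s_obs <- sum(rx * ry)
  ctr <- sum(rx) * sum(ry) / n
  dev_obs <- abs(s_obs - ctr) - 1e-9
  if (n <= 9L) {
    P <- perm_matrix(n)
    s <- as.numeric(matrix(ry[P], nrow(P)) %*% rx)
    return(mean(abs(s - ctr) >= dev_obs))
  }
  # n = 10: stream over blocks that fix the first position
  P9 <- perm_matrix(9L)
  count <- 0
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    s <- rx[1] * ry[k] +
      as.numeric(matrix(ry[rest][P9], nrow(P9)) %*% rx[-1])
    count <- count + sum(abs(s - ctr) >= dev_obs)
  }
  count / factorial(n)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' The statistic `V` is the sum of ranks of the positive differences
#' `a - b`, with zero differences dropped and average ranks for tied
#' magnitudes.  When `m <= exact_n` nonzero differences remain and no
#' magnitudes are tied, the two-sided p-value is exact (enumeration of all
#' 2^m sign assignments); otherwise the normal approximation with tie and
#' continuity corrections is used.
#'
#' @param a,b paired numeric vectors.
#' @param exact_n largest m for which the sign-flip null is enumerated
#'   (default 12).
#' @return list with `statistic` (V), `p_value`, `n_nonzero`, `method`.
#' @export
wilcoxon_paired <- function(a, b, exact_n = 12L) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) stop("all paired differences are zero", call. = FALSE)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (m <= exact_n && !ties) {
    # exact distribution by enumerating sign vectors
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    vdist <- as.numeric(signs %*% r)
    p_low <- mean(vdist <= V + 1e-9)
    p_high <- mean(vdist >= V - 1e-9)
    p <- min(1, 2 * min(p_low, p_high))
    method <- "exact enumeration"
  } else {
    mu <- m * (m + 1) / 4
    tie_tab <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- V - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation (tie/continuity corrected)"
  }
  list(statistic = V, p_value = p, n_nonzero = m, method = method)
}
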