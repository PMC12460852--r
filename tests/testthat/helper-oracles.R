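# Shared fixtures and independent brute-force oracles used across the suite.

# small, fast phantom spec for unit tests (32^2 x 16 grid)
quick_spec <- function(seed = 1L, tumor_radius_mm = 8, edema_thickness_mm = 8,
                       ...) {
  phantom_spec(grid_shape = c(32L, 32L, 18L), spacing = c(2, 2, 2),
               tumor_radius_mm = tumor_radius_mm,
               edema_thickness_mm = edema_thickness_mm, seed = seed, ...)
}

# naive loop-based histogram statistics (independent of extract_features)
naive_features <- function(x) {
  n <- length(x)
  s <- 0
  for (v in x) s <- s + v
  m <- s / n
  ss <- s3 <- s4 <- 0
  for (v in x) {
    ss <- ss + (v - m)^2
    s3 <- s3 + (v - m)^3
    s4 <- s4 + (v - m)^4
  }
  m2 <- ss / n
  xs <- sort(x)
  med <- if (n %% 2 == 1) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
  list(meanADC = m,
       stdmeanADC = sqrt(ss / (n - 1)),
       maxiADC = xs[n], miniADC = xs[1], medianADC = med,
       skewnessADC = if (n >= 3 && m2 > 0) (s3 / n) / m2^1.5 else NA_real_,
       kurtosisADC = if (n >= 3 && m2 > 0) (s4 / n) / m2^2 else NA_real_,
       ratio_maxi_mean = xs[n] / m)
}

# pairwise-counting Mann-Whitney AUC (double loop)
naive_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  u <- 0
  for (p in pos) for (q in neg)
    u <- u + if (p > q) 1 else if (p == q) 0.5 else 0
  u / (length(pos) * length(neg))
}

# exhaustive-search Youden point for the below_positive rule
naive_youden_below <- function(scores, labels) {
  thr <- c(sort(unique(scores)), Inf)
  best_j <- -Inf; best_t <- NA; best_spec <- -Inf
  for (t in thr) {
    sens <- mean(scores[labels == 1] < t)
    spec <- mean(scores[labels == 0] >= t)
    j <- sens + spec - 1
    if (j > best_j + 1e-12 ||
        (abs(j - best_j) <= 1e-12 && spec > best_spec)) {
      best_j <- j; best_t <- t; best_spec <- spec
    }
  }
  list(threshold = best_t, j = best_j)
}

# recursive permutation generator (independent of the package's)
naive_perms <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- naive_perms(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# brute-force exact two-sided Spearman p by enumeration of rank permutations
naive_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  P <- naive_perms(seq_along(ry))
  cnt <- 0
  for (i in seq_len(nrow(P)))
    if (abs(cor(rx, ry[P[i, ]])) >= obs - 1e-9) cnt <- cnt + 1
  cnt / nrow(P)
}

# brute-force exact two-sided Wilcoxon signed-rank p over all sign vectors
naive_wilcoxon_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- numeric(2^m)
  for (code in 0:(2^m - 1)) {
    bits <- as.integer(intToBits(code))[1:m]
    vs[code + 1] <- sum(r[bits == 1])
  }
  min(1, 2 * min(mean(vs <= v_obs + 1e-9), mean(vs >= v_obs - 1e-9)))
}

# loop-based tile oracle on an integer-size working grid
naive_tile_values <- function(vals, edema, k, anchor = NULL) {
  idx <- which(edema, arr.ind = TRUE)
  if (is.null(anchor)) anchor <- c(min(idx[, 1]), min(idx[, 2]))
  roi_mean <- mean(vals[edema])
  out <- NULL
  for (tx in seq(anchor[1], max(idx[, 1]), by = k)) {
    for (ty in seq(anchor[2], max(idx[, 2]), by = k)) {
      xr <- tx:min(tx + k - 1, nrow(vals))
      yr <- ty:min(ty + k - 1, ncol(vals))
      em <- edema[xr, yr, drop = FALSE]
      if (sum(em) / (k * k) < 0.5) next
      out <- rbind(out, data.frame(x = tx, y = ty,
                                   value = max(vals[xr, yr][em]) / roi_mean))
    }
  }
  out
}
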