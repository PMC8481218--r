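# Independent brute-force oracles used to cross-check the implementation.
# These deliberately recompute everything from first principles and share no
# code with the package internals.

# Constrained UPGMA by exhaustive greedy adjacent-merge search: at each step
# every adjacent cluster pair's average linkage is recomputed as the mean of
# ALL cross-pair Euclidean distances from the full distance matrix.
oracle_constrained_upgma <- function(X) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  clusters <- lapply(seq_len(n), identity)
  out <- list()
  for (step in seq_len(n - 1)) {
    k <- length(clusters)
    d_adj <- vapply(seq_len(k - 1), function(i) {
      mean(D[clusters[[i]], clusters[[i + 1]], drop = FALSE])
    }, numeric(1))
    m <- which.min(d_adj)
    out[[step]] <- data.frame(
      step = step,
      left_start = min(clusters[[m]]), left_end = max(clusters[[m]]),
      right_start = min(clusters[[m + 1]]), right_end = max(clusters[[m + 1]]),
      height = d_adj[m]
    )
    clusters[[m]] <- c(clusters[[m]], clusters[[m + 1]])
    clusters[[m + 1]] <- NULL
  }
  do.call(rbind, out)
}

# Loess with pointwise se via explicit per-point weighted-least-squares hat
# rows; residual variance through the delta1/delta2 trace corrections.
oracle_loess <- function(x, y, span = 1, degree = 2) {
  n <- length(x)
  q <- max(degree + 1, floor(span * n))   # neighbourhood size of the smoother
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    dmax <- sort(d)[q]
    w <- pmax(0, 1 - (d / dmax)^3)^3
    B <- outer(x - x[i], 0:degree, "^")
    WB <- w * B
    L[i, ] <- (solve(t(B) %*% WB, t(WB)))[1, ]
  }
  fitted <- drop(L %*% y)
  res <- y - fitted
  M <- diag(n) - L
  MMt <- M %*% t(M)
  d1 <- sum(diag(MMt))
  d2 <- sum(MMt * MMt)          # trace of (MM')^2 since MM' symmetric
  s2 <- sum(res^2) / d1
  list(fitted = fitted, se = sqrt(pmax(s2, 0) * rowSums(L^2)),
       edf = d1^2 / d2)
}

# small percent community: random compositions, rows closed to 100
random_percent_series <- function(n, m, seed) {
  set.seed(seed)
  v <- matrix(stats::rgamma(n * m, shape = 2), n, m)
  v <- v / rowSums(v) * 100
  colnames(v) <- paste0("t", seq_len(m))
  community_ts(seq_len(n), rel_abund = v, axis_direction = "time")
}

percent_matrix <- function(...) {
  m <- rbind(...)
  colnames(m) <- paste0("t", seq_len(ncol(m)))
  m
}
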