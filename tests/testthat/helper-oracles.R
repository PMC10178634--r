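# Independent oracles used across tests. Deliberately naive: plain loops
# and closed forms, sharing no code with the implementation.

# Pixel-by-pixel contrast stretch: reflect-padded window statistics and the
# stretch formula applied one pixel at a time.
oracle_contrast_stretch <- function(F, K, beta, c, a, window, L = 256) {
  M <- nrow(F); N <- ncol(F)
  r <- (window - 1) / 2
  gm <- mean(F)
  reflect <- function(i, n) {
    if (i < 1) 1 + (1 - i) else if (i > n) n - (i - n) else i
  }
  G <- matrix(0, M, N)
  for (x in 1:M) for (y in 1:N) {
    vals <- numeric(0)
    for (dx in -r:r) for (dy in -r:r) {
      vals <- c(vals, F[reflect(x + dx, M), reflect(y + dy, N)])
    }
    mu <- mean(vals)
    sigma <- sqrt(mean((vals - mu)^2))
    Q <- K * gm / (sigma + beta)
    G[x, y] <- Q * (F[x, y] - c * mu) + mu^a
  }
  pmin(pmax(G, 0), L - 1)
}

# Brute-force mid-value column filter.
oracle_threshold_filter <- function(values) {
  scores <- apply(values, 2, mean)
  thr <- (min(scores) + max(scores)) / 2
  which(scores >= thr)
}

# Bisection root finder.
oracle_bisection <- function(f, lo, hi, tol = 1e-12, max_iter = 200) {
  flo <- f(lo)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(hi - lo) < tol) break
    if (flo * fm <= 0) hi <- mid else { lo <- mid; flo <- fm }
  }
  (lo + hi) / 2
}

# Hill estimator of the tail index from the top k order statistics.
hill_estimate <- function(x, k = 1000) {
  x <- sort(abs(x), decreasing = TRUE)
  1 / mean(log(x[1:k]) - log(x[k + 1]))
}

random_image <- function(n = 5, L = 256) {
  matrix(runif(n * n, 0, L - 1), n, n)
}
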