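# Independent oracles, deliberately implemented apart from the package's
# own code paths.

# direct O(n*k) causal convolution (no FFT)
convolve_design_oracle <- function(X, h) {
  h <- as.numeric(h)
  tps <- attr(X, "tr_per_scan")
  if (is.null(tps)) tps <- nrow(X)
  out <- X * 0
  row0 <- 0
  for (s in seq_along(tps)) {
    n <- tps[s]
    for (j in which(colSums(abs(X[row0 + seq_len(n), , drop = FALSE])) > 0)) {
      x <- X[row0 + seq_len(n), j]
      y <- numeric(n)
      for (t in seq_len(n)) {
        k <- seq_len(min(t, length(h)))
        y[t] <- sum(x[t - k + 1] * h[k])
      }
      out[row0 + seq_len(n), j] <- y
    }
    row0 <- row0 + n
  }
  out
}

# modified Bessel function of the first kind, order 0, by power series
bessel_i0_series <- function(x, n_terms = 60) {
  k <- 0:(n_terms - 1)
  sum((x / 2)^(2 * k) / factorial(k)^2)
}

# inverse normal CDF by root finding (independent of qnorm)
qnorm_oracle <- function(p) {
  uniroot(function(z) pnorm(z) - p, c(-10, 10), tol = 1e-12)$root
}

# brute-force dense local grid pRF fit (0.1 deg center spacing), computing
# overlaps directly from the aperture masks
oracle_prf_fit <- function(betas, ap, near, span = 1, step = 0.1) {
  A <- t(matrix(ap$masks, nrow = ap$resolution^2))
  xs <- seq(near$x - span, near$x + span, by = step)
  ys <- seq(near$y - span, near$y + span, by = step)
  ss <- seq(max(0.11, near$sigma * 0.6), near$sigma * 1.5, by = 0.05)
  best <- list(rss = Inf)
  for (s in ss) {
    for (x0 in xs) {
      gx <- exp(-(ap$coords - x0)^2 / (2 * s^2))
      G <- sapply(ys, function(y0)
        as.vector(outer(gx, exp(-(ap$coords - y0)^2 / (2 * s^2)))))
      preds <- A %*% G
      preds <- sweep(preds, 2, colSums(G), `/`)
      num <- as.vector(crossprod(preds, betas))
      den <- colSums(preds^2)
      rss <- sum(betas^2) - num^2 / den
      j <- which.min(rss)
      if (rss[j] < best$rss)
        best <- list(x = x0, y = ys[j], sigma = s, rss = rss[j])
    }
  }
  best
}
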