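# Event-related GLM: per-vertex beta weights for each condition x stimulus
# regressor, in percent BOLD. The indicator design is convolved with a
# hemodynamic response function within each scan, augmented with per-scan
# polynomial nuisance regressors, and solved by ordinary least squares.

#' Canonical double-gamma hemodynamic response function
#'
#' The standard difference-of-gammas impulse response
#' `h(t) = g(t; 6, 1) - g(t; 16, 1) / 6`, sampled at 1 s over 50 s and
#' scaled to unit peak. Peaks near t = 5 s.
#'
#' @param duration_s Support of the sampled response in seconds.
#' @param dt Sampling interval in seconds (the TR; must be 1 for use with
#'   the TR-level design).
#' @param a1,b1,a2,b2,c Gamma shape/rate parameters and undershoot ratio.
#' @return Numeric vector `h(0), h(dt), ...`; attribute `dt`.
#' @export
hrf_double_gamma <- function(duration_s = 50, dt = 1,
                             a1 = 6, b1 = 1, a2 = 16, b2 = 1, c = 1 / 6) {
  t <- seq(0, duration_s - dt, by = dt)
  h <- stats::dgamma(t, shape = a1, rate = b1) -
    c * stats::dgamma(t, shape = a2, rate = b2)
  h <- h / max(h)
  attr(h, "dt") <- dt
  h
}

#' Convolve a predictor with the HRF
#'
#' Causal discrete convolution, truncated to the length of the input series.
#'
#' @param x Per-TR predictor values.
#' @param hrf Sampled impulse response from [hrf_double_gamma()] (or a
#'   user-supplied response sampled at the TR).
#' @return Numeric vector the same length as `x`.
#' @export
convolve_with_hrf <- function(x, hrf) {
  dt <- attr(hrf, "dt") %||% 1
  if (!isTRUE(all.equal(dt, 1)))
    stopf("invalid argument: HRF must be sampled at the 1-s TR")
  n <- length(x)
  full <- stats::convolve(x, rev(as.numeric(hrf)), type = "open")
  full[seq_len(n)]
}

# convolve every design column within each scan block
convolve_design <- function(X, hrf, tr_per_scan) {
  out <- X
  row0 <- 0L
  for (s in seq_along(tr_per_scan)) {
    rows <- row0 + seq_len(tr_per_scan[s])
    block <- X[rows, , drop = FALSE]
    active <- which(colSums(abs(block)) > 0)
    for (j in active) out[rows, j] <- convolve_with_hrf(block[, j], hrf)
    row0 <- row0 + tr_per_scan[s]
  }
  out
}

# per-scan Legendre-style polynomial nuisance block (order 0..order)
nuisance_block <- function(tr_per_scan, order) {
  blocks <- lapply(seq_along(tr_per_scan), function(s) {
    tt <- seq(-1, 1, length.out = tr_per_scan[s])
    m <- outer(tt, 0:order, `^`)
    colnames(m) <- sprintf("poly_s%d_o%d", s, 0:order)
    m
  })
  n <- sum(tr_per_scan)
  out <- matrix(0, n, (order + 1) * length(tr_per_scan))
  row0 <- 0L; col0 <- 0L
  nm <- character(0)
  for (s in seq_along(blocks)) {
    out[row0 + seq_len(tr_per_scan[s]), col0 + seq_len(order + 1)] <- blocks[[s]]
    nm <- c(nm, colnames(blocks[[s]]))
    row0 <- row0 + tr_per_scan[s]; col0 <- col0 + order + 1L
  }
  colnames(out) <- nm
  out
}

#' Fit the event-related GLM
#'
#' Ordinary least squares of each vertex's time series on the HRF-convolved
#' design plus per-scan polynomial nuisance regressors. Estimated
#' coefficients are converted to percent BOLD by dividing by the vertex's
#' mean signal intensity and multiplying by 100.
#'
#' Condition-stimulus cells never observed in the schedule produce all-zero
#' regressors; these columns are dropped and their betas reported as `NA`.
#' Rank deficiency among the remaining columns is an error naming the
#' collinear columns.
#'
#' @param series Matrix of raw signal, TR x vertices.
#' @param design Design matrix from [build_design_matrix()].
#' @param hrf Sampled HRF.
#' @param nuisance_order Per-scan polynomial order (default 2).
#' @param tr_per_scan Per-scan TR counts (default from the design).
#' @return Object of class `beta_profile`: `betas` (250 x V, percent BOLD,
#'   `NA` for unobserved cells), `se` (same shape), `r2` (GLM variance
#'   explained per vertex), `mean_signal`, `labels`, `conditions`.
#' @export
fit_glm <- function(series, design, hrf = hrf_double_gamma(),
                    nuisance_order = 2L, tr_per_scan = NULL) {
  series <- as.matrix(series)
  tr_per_scan <- tr_per_scan %||% attr(design, "tr_per_scan") %||%
    attr(series, "tr_per_scan") %||% nrow(series)
  if (nrow(series) != nrow(design))
    stopf("series and design have different numbers of TRs")
  if (nuisance_order < 0) stopf("invalid configuration: nuisance order must be >= 0")

  Xc <- convolve_design(design, hrf, tr_per_scan)
  observed <- colSums(abs(Xc)) > 0
  N <- nuisance_block(tr_per_scan, nuisance_order)
  X <- cbind(Xc[, observed, drop = FALSE], N)

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("degenerate design: collinear columns after convolution: %s",
          paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qrX, series)
  fitted <- X %*% coefs
  resid <- series - fitted

  mean_signal <- colMeans(series)
  n_task <- sum(observed)
  betas <- matrix(NA_real_, ncol(design), ncol(series),
                  dimnames = list(colnames(design), NULL))
  betas[observed, ] <- coefs[seq_len(n_task), , drop = FALSE]
  betas <- sweep(betas, 2, mean_signal, `/`) * 100

  dof <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / dof
  xtx_inv_diag <- diag(chol2inv(qr.R(qrX)))[order(qrX$pivot)][seq_len(n_task)]
  se <- matrix(NA_real_, ncol(design), ncol(series),
               dimnames = list(colnames(design), NULL))
  se[observed, ] <- sqrt(outer(xtx_inv_diag, sigma2))
  se <- sweep(se, 2, mean_signal, `/`) * 100

  tss <- colSums(sweep(series, 2, colMeans(series))^2)
  r2 <- 1 - colSums(resid^2) / tss

  structure(list(betas = betas, se = se, r2 = as.numeric(r2),
                 mean_signal = as.numeric(mean_signal),
                 labels = colnames(design),
                 conditions = attention_conditions(),
                 nuisance_order = nuisance_order),
            class = "beta_profile")
}

#' Extract condition-wise mapping betas
#'
#' Reshapes a fitted `beta_profile` into a 49 x 5 x V array of mapping-
#' stimulus betas (percent BOLD).
#'
#' @param fit A `beta_profile` from [fit_glm()].
#' @return Array with dimensions stimulus (49) x condition (5) x vertex.
#' @export
mapping_beta_array <- function(fit) {
  conds <- fit$conditions
  V <- ncol(fit$betas)
  out <- array(NA_real_, dim = c(49, length(conds), V),
               dimnames = list(NULL, conds, NULL))
  for (ci in seq_along(conds))
    out[, ci, ] <- fit$betas[(ci - 1) * 49 + seq_len(49), , drop = FALSE]
  out
}

#' Smooth a beta profile for visualization
#'
#' Convolves a bar-ordered beta profile with a normalized triangular kernel,
#' padding each sweep with its first and last values. Smoothing is applied
#' independently within the two orientation sweeps (bars 1-24 and 25-48);
#' the blank (49th) value, when present, is passed through unchanged. For
#' display only; the pRF fit always uses unsmoothed betas.
#'
#' @param betas Numeric vector of length 48 or 49 ordered by bar position
#'   (first sweep then second sweep, blank last).
#' @param width Odd kernel width in taps (default 3).
#' @return Smoothed vector, same length as the input.
#' @export
smooth_beta_profile <- function(betas, width = 3L) {
  if (width %% 2L != 1L || width < 1L)
    stopf("invalid configuration: kernel width must be odd and positive")
  half <- (width - 1L) %/% 2L
  kern <- c(seq_len(half + 1L), rev(seq_len(half)))
  kern <- kern / sum(kern)
  smooth_one <- function(x) {
    if (half == 0L) return(x)
    padded <- c(rep(x[1], half), x, rep(x[length(x)], half))
    as.numeric(stats::filter(padded, kern, sides = 2))[half + seq_along(x)]
  }
  out <- betas
  out[1:24] <- smooth_one(betas[1:24])
  out[25:48] <- smooth_one(betas[25:48])
  out
}
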