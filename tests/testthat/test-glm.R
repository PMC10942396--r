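# HRF, convolution, GLM estimation, percent-BOLD conversion, smoothing.

test_that("canonical double-gamma HRF peaks near 5 s", {
  h <- hrf_double_gamma()
  expect_length(h, 50L)
  # fine-grid evaluation of the double-gamma formula as the oracle
  tt <- seq(0, 30, by = 0.001)
  fine <- dgamma(tt, 6, 1) - dgamma(tt, 16, 1) / 6
  peak_t <- tt[which.max(fine)]
  expect_gt(peak_t, 3); expect_lt(peak_t, 7)
  expect_equal(which.max(h) - 1, round(peak_t), tolerance = 1)
  expect_equal(max(h), 1) # unit-peak scaling
})

test_that("HRF convolution is causal, linear, and shift-preserving", {
  h <- fx_hrf()
  x <- rep(0, 40); x[6] <- 1
  y <- convolve_with_hrf(x, h)
  expect_equal(y[6:40], as.numeric(h)[1:35], tolerance = 1e-10)
  expect_true(all(abs(y[1:5]) < 1e-10)) # causal
  a <- rnorm(40); b <- rnorm(40)
  expect_equal(convolve_with_hrf(a + b, h),
               convolve_with_hrf(a, h) + convolve_with_hrf(b, h),
               tolerance = 1e-10)
  bad <- h; attr(bad, "dt") <- 2
  expect_error(convolve_with_hrf(x, bad), "1-s TR")
})

test_that("GLM betas convert to percent BOLD of the mean intensity", {
  # one trial, one vertex, hand-built series: a 1-unit response on a
  # mean-100 baseline must come back as 1 percent BOLD
  sched <- build_trial_schedule(8, seed = 5)
  X <- build_design_matrix(sched)
  h <- fx_hrf()
  conv <- convolve_design_oracle(X, h)
  beta_units <- rep(0, 250)
  active <- which(colSums(abs(X)) > 0)
  beta_units[active[1]] <- 1
  signal <- conv %*% beta_units
  series <- matrix(100 + (signal - mean(signal)), ncol = 1)
  fit <- fit_glm(series, X, h)
  expect_equal(unname(fit$betas[active[1], 1]), 1, tolerance = 1e-8)
  expect_gt(fit$r2[1], 0.999)
})

test_that("nuisance-space components leave mapping betas unchanged", {
  ap <- fx_ap64()
  sched <- build_trial_schedule(52, seed = 12)
  verts <- data.frame(vertex = 1L, map = "V1", x0 = 3, y0 = 2,
                      sigma0 = 1, gain = 2)
  truth <- simulate_beta_truth(verts, ap,
                               attention_field_spec(mode = "additive_only"),
                               modulation_spec(peak = 0,
                                               account = "stimulus_locked"))
  series <- simulate_bold(truth, sched, hrf = fx_hrf(),
                          noise = noise_spec(sd = 0, drift_amp = 0))
  X <- build_design_matrix(sched)
  fit1 <- fit_glm(series, X, fx_hrf())
  # add a quadratic drift (inside the nuisance span) to the series
  n <- nrow(series)
  tt <- seq(-1, 1, length.out = n)
  fit2 <- fit_glm(series + 5 * tt^2, X, fx_hrf())
  # compare in raw signal units: the percent-BOLD conversion rescales by the
  # (slightly changed) mean intensity, the projection itself is exact
  raw1 <- fit1$betas[1:245, ] / 100 * fit1$mean_signal
  raw2 <- fit2$betas[1:245, ] / 100 * fit2$mean_signal
  expect_equal(raw1, raw2, tolerance = 1e-8)
})

test_that("GLM variance explained is invariant to affine rescaling", {
  ap <- fx_ap64()
  sched <- build_trial_schedule(52, seed = 14)
  verts <- data.frame(vertex = 1L, map = "V1", x0 = -2, y0 = 4,
                      sigma0 = 1.2, gain = 2)
  truth <- simulate_beta_truth(verts, ap,
                               attention_field_spec(mode = "additive_only"),
                               modulation_spec(peak = 0,
                                               account = "stimulus_locked"))
  series <- simulate_bold(truth, sched, hrf = fx_hrf(),
                          noise = noise_spec(sd = 0.5, drift_amp = 0), seed = 1)
  X <- build_design_matrix(sched)
  fit1 <- fit_glm(series, X, fx_hrf())
  fit2 <- fit_glm(series * 3 + 50, X, fx_hrf())
  expect_equal(fit1$r2, fit2$r2, tolerance = 1e-8)
})

test_that("OLS standard errors match the analytic covariance", {
  sched <- build_trial_schedule(104, seed = 16, trials_per_scan = 52)
  X <- build_design_matrix(sched)
  verts <- data.frame(vertex = 1L, map = "V1", x0 = 0, y0 = 0,
                      sigma0 = 1, gain = 0)
  truth <- simulate_beta_truth(verts, fx_ap64(),
                               attention_field_spec(mode = "additive_only"),
                               modulation_spec(peak = 0))
  set.seed(3)
  series <- simulate_bold(truth, sched, hrf = fx_hrf(),
                          noise = noise_spec(sd = 1, drift_amp = 0), seed = 3)
  fit <- fit_glm(series, X, fx_hrf())
  # independent oracle: sigma^2 (X'X)^-1 on the convolved+nuisance design
  conv <- convolve_design_oracle(X, fx_hrf())
  obs <- colSums(abs(conv)) > 0
  tps <- attr(X, "tr_per_scan")
  N <- cbind(rep(c(1, 0), c(tps[1], tps[2])), rep(c(0, 1), c(tps[1], tps[2])))
  tt1 <- seq(-1, 1, length.out = tps[1]); tt2 <- seq(-1, 1, length.out = tps[2])
  N <- cbind(N, c(tt1, 0 * tt2), c(0 * tt1, tt2), c(tt1^2, 0 * tt2),
             c(0 * tt1, tt2^2))
  Xf <- cbind(conv[, obs], N)
  y <- series[, 1]
  coefs <- solve(crossprod(Xf), crossprod(Xf, y))
  res <- y - Xf %*% coefs
  s2 <- sum(res^2) / (nrow(Xf) - ncol(Xf))
  se_oracle <- sqrt(s2 * diag(solve(crossprod(Xf))))[seq_len(sum(obs))] /
    mean(y) * 100
  expect_equal(unname(fit$se[obs, 1]), unname(se_oracle), tolerance = 1e-6)
})

test_that("rank-deficient designs raise a degenerate-design error", {
  sched <- build_trial_schedule(10, seed = 2)
  X <- build_design_matrix(sched)
  active <- which(colSums(X) > 0)
  X[, active[2]] <- X[, active[1]] # duplicate an observed regressor
  series <- matrix(rnorm(nrow(X), 100), ncol = 1)
  expect_error(fit_glm(series, X, fx_hrf()), "degenerate design")
})

test_that("triangular smoothing behaves as a normalized edge-padded kernel", {
  expect_equal(smooth_beta_profile(rep(2, 49)), rep(2, 49))
  x <- rep(0, 49); x[3] <- 4
  sm <- smooth_beta_profile(x)
  expect_equal(sm[1:6], c(0, 1, 2, 1, 0, 0)) # [1,2,1]/4 hand convolution
  expect_equal(sum(sm[1:24]), sum(x[1:24])) # kernel sums to 1 (interior mass)
  # sweeps are smoothed independently: an impulse at bar 24 never leaks
  # into bar 25
  y <- rep(0, 49); y[24] <- 4
  expect_equal(smooth_beta_profile(y)[25], 0)
  expect_error(smooth_beta_profile(x, width = 4), "odd")
})
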