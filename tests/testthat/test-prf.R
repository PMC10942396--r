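# Isotropic Gaussian pRF model: predictions, coarse-to-fine fitting,
# condition-wise fits, size-eccentricity relation.

test_that("beta-profile predictions follow the overlap model", {
  ap <- fx_ap64()
  p <- list(x = -7, y = 0, sigma = 1, gain = 2)
  pred <- predict_beta_profile(p, ap)
  expect_length(pred, 49L)
  expect_equal(pred[49], 0) # blank predicts 0 for any parameters
  expect_equal(predict_beta_profile(modifyList(p, list(gain = 4)), ap),
               2 * pred)
  # strongest vertical-bar response at the bar nearest x = -7
  best_bar <- which.max(pred[1:24])
  expect_lte(abs(ap$bar_offset[best_bar] - (-7)), 0.5)
  expect_error(predict_beta_profile(modifyList(p, list(sigma = 0)), ap),
               "sigma")
})

test_that("noiseless profiles are recovered with r2 = 1", {
  ap <- fx_ap64(); grid <- fx_grid64()
  truth <- list(x = 3.2, y = -4.1, sigma = 1.7, gain = 2.5)
  f <- fit_prf(predict_beta_profile(truth, ap), ap, grid = grid)
  expect_lt(abs(f$x - truth$x), 0.02)
  expect_lt(abs(f$y - truth$y), 0.02)
  expect_lt(abs(f$sigma - truth$sigma), 0.02)
  expect_equal(f$gain, truth$gain, tolerance = 1e-3)
  expect_gt(f$r2, 0.99999)
})

test_that("degenerate profiles are flagged, not fitted", {
  ap <- fx_ap64(); grid <- fx_grid64()
  z <- fit_prf(rep(0, 49), ap, grid = grid)
  expect_true(z$degenerate)
  expect_true(is.na(z$r2)) # all-zero: r2 undefined
  cst <- fit_prf(rep(1.5, 49), ap, grid = grid)
  expect_true(cst$degenerate)
  expect_equal(cst$r2, 0) # betas equal to their own mean
})

test_that("refinement never loses to the best grid point", {
  ap <- fx_ap64(); grid <- fx_grid64()
  set.seed(31)
  for (i in 1:5) {
    b <- predict_beta_profile(list(x = runif(1, -6, 6), y = runif(1, -6, 6),
                                   sigma = runif(1, 0.5, 3), gain = 2), ap) +
      rnorm(49, 0, 0.2)
    coarse <- fit_prf(b, ap, prf_fit_config(refine = FALSE), grid)
    fine <- fit_prf(b, ap, prf_fit_config(), grid)
    expect_lte(fine$rss, coarse$rss + 1e-12)
  }
})

test_that("fitted centers match a dense brute-force grid oracle", {
  ap <- fx_ap64(); grid <- fx_grid64()
  set.seed(41)
  n_cases <- 20
  for (i in seq_len(n_cases)) {
    truth <- list(x = runif(1, -7, 7), y = runif(1, -7, 7),
                  sigma = runif(1, 0.6, 3), gain = runif(1, 1, 3))
    b <- predict_beta_profile(truth, ap)
    f <- fit_prf(b, ap, grid = grid)
    o <- oracle_prf_fit(b, ap, truth)
    expect_lt(abs(f$x - o$x), 0.1)
    expect_lt(abs(f$y - o$y), 0.1)
    expect_lt(abs(f$sigma - o$sigma), 0.1)
  }
})

test_that("with the blank excluded, centers ignore additive offsets", {
  ap <- fx_ap64()
  cfg <- prf_fit_config(include_blank = FALSE)
  grid <- prf_fit_grid(ap, cfg)
  b <- predict_beta_profile(list(x = -5, y = 1, sigma = 1.5, gain = 2), ap)
  f0 <- fit_prf(b, ap, cfg, grid)
  f1 <- fit_prf(b + 0.3, ap, cfg, grid)
  expect_lt(abs(f0$x - f1$x), 0.05)
  expect_lt(abs(f0$y - f1$y), 0.05)
})

test_that("condition-wise fitting returns six solutions per vertex", {
  ap <- fx_ap64(); grid <- fx_grid64()
  b <- predict_beta_profile(list(x = 2, y = 3, sigma = 1.2, gain = 2), ap)
  barr <- array(rep(b, 5), dim = c(49, 5, 1),
                dimnames = list(NULL, attention_conditions(), NULL))
  out <- fit_prfs_by_condition(barr, ap, grid = grid)
  expect_equal(nrow(out), 6L)
  expect_setequal(out$condition, c(attention_conditions(), "average"))
  # identical condition profiles give six identical solutions
  expect_lt(diff(range(out$x)), 1e-6)
  expect_lt(diff(range(out$sigma)), 1e-6)
  expect_error(fit_prfs_by_condition(barr[, 1:4, , drop = FALSE], ap,
                                     grid = grid), "five condition")
})

test_that("averaging conditions raises r2 under matched noise", {
  ap <- fx_ap64(); grid <- fx_grid64()
  set.seed(51)
  b <- predict_beta_profile(list(x = -4, y = 2, sigma = 1.5, gain = 2), ap)
  r2_single <- c(); r2_avg <- c()
  for (rep_i in 1:8) {
    barr <- array(rep(b, 5) + rnorm(49 * 5, 0, 0.4), dim = c(49, 5, 1),
                  dimnames = list(NULL, attention_conditions(), NULL))
    out <- fit_prfs_by_condition(barr, ap, grid = grid)
    r2_single <- c(r2_single,
                   mean(out$r2[out$condition != "average"]))
    r2_avg <- c(r2_avg, out$r2[out$condition == "average"])
  }
  expect_gt(mean(r2_avg), mean(r2_single))
})

test_that("condition-specific additive offsets leave centers unchanged", {
  ap <- fx_ap64()
  cfg <- prf_fit_config(include_blank = FALSE)
  grid <- prf_fit_grid(ap, cfg)
  b <- predict_beta_profile(list(x = 1, y = -5, sigma = 1.4, gain = 2), ap)
  offs <- c(0.15, -0.05, 0.1, -0.1, 0)
  barr <- array(sapply(offs, function(o) b + o), dim = c(49, 5, 1),
                dimnames = list(NULL, attention_conditions(), NULL))
  out <- fit_prfs_by_condition(barr, ap, cfg, grid)
  expect_lt(diff(range(out$x)), 0.05)
  expect_lt(diff(range(out$y)), 0.05)
})

test_that("size-eccentricity fits recover linear structure", {
  d <- data.frame(map = rep(c("V1", "LO1"), each = 10),
                  ecc = rep(1:10, 2))
  d$sigma <- ifelse(d$map == "V1", 0.2 + 0.1 * d$ecc, 0.2 + 0.3 * d$ecc)
  fits <- fit_size_eccentricity(d)
  expect_equal(fits$slope[fits$map == "V1"], 0.1, tolerance = 1e-10)
  expect_equal(fits$intercept[fits$map == "LO1"], 0.2, tolerance = 1e-10)
  # constant sigma gives slope 0
  d2 <- data.frame(map = "V2", ecc = 1:5, sigma = 1)
  expect_equal(fit_size_eccentricity(d2)$slope, 0, tolerance = 1e-12)
  # degenerate design flagged
  d3 <- data.frame(map = "V3", ecc = rep(2, 4), sigma = 1:4)
  expect_true(is.na(fit_size_eccentricity(d3)$slope))
})
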