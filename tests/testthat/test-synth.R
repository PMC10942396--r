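# Ground-truth generators: pRF populations, attention-field geometry,
# beta-profile truth, BOLD simulation, behavior and gaze.

test_that("sampled pRF population matches its configuration", {
  verts <- sample_prf_population(200, maps = c("V1", "V3A/B"),
                                 sigma_jitter = 0, seed = 4)
  expect_equal(nrow(verts), 400L)
  expect_true(all(eccentricity(verts$x0, verts$y0) <= 12.4))
  expect_true(all(verts$sigma0 > 0))
  expect_true(all(verts$gain > 0))
  # noiseless sample: per-map OLS recovers the configured slopes exactly
  verts$sigma <- verts$sigma0
  verts$x <- verts$x0; verts$y <- verts$y0
  fits <- fit_size_eccentricity(verts)
  expect_equal(fits$slope[fits$map == "V1"], 0.10, tolerance = 1e-8)
  expect_equal(fits$slope[fits$map == "V3A/B"], 0.27, tolerance = 1e-8)
  expect_lt(fits$slope[fits$map == "V1"], fits$slope[fits$map == "V3A/B"])
  expect_error(sample_prf_population(0), "positive")
})

test_that("attention-field transform follows the Gaussian-product closed form", {
  eff <- attention_field_transform(c(4, 0, 2), c(6, 0, 4))
  expect_equal(unname(eff["x"]), (16 * 4 + 4 * 6) / 20) # = 4.4
  expect_equal(unname(eff["sigma"]), sqrt(4 * 16 / 20))
  expect_lt(eff["sigma"], 2)
  # new center strictly between pRF and field centers
  expect_true(eff["x"] > 4 && eff["x"] < 6)
  # very broad field leaves the center essentially unchanged
  far <- attention_field_transform(c(4, 0, 2), c(6, 0, 1e4))
  expect_equal(unname(far["x"]), 4, tolerance = 1e-6)
  # field centered on the pRF: center fixed, size shrinks
  cen <- attention_field_transform(c(4, 0, 2), c(4, 0, 3))
  expect_equal(unname(cen["x"]), 4)
  expect_lt(cen["sigma"], 2)
  # shift magnitude decreases monotonically with sigma_attn
  shifts <- sapply(c(2, 4, 8, 16), function(sa)
    abs(attention_field_transform(c(4, 0, 2), c(6, 0, sa))["x"] - 4))
  expect_true(all(diff(shifts) < 0))
  expect_error(attention_field_transform(c(4, 0, -1), c(6, 0, 4)),
               "invalid argument")
})

test_that("additive-only truth is a constant focal-minus-distributed offset", {
  ap <- fx_ap64()
  verts <- data.frame(vertex = 1L, map = "V1", x0 = -7, y0 = 0,
                      sigma0 = 1, gain = 2)
  mod <- modulation_spec(peak = 0.07, account = "stimulus_locked")
  truth <- simulate_beta_truth(verts, ap,
                               attention_field_spec(mode = "additive_only"),
                               mod)
  diff <- truth$total[, "left", 1] - truth$total[, "distributed", 1]
  # constant across all 49 stimuli, equal to the configured peak offset
  # (the vertex sits on the attended meridian, zero polar distance)
  expect_equal(diff, rep(0.07, 49), tolerance = 1e-12)
  # blank stimulus under distributed attention with no offset is exactly 0
  expect_equal(unname(truth$total[49, "distributed", 1]), 0)
  # blank under the focal condition carries the additive offset only
  expect_equal(unname(truth$total[49, "left", 1]), 0.07, tolerance = 1e-12)
})

test_that("additive and multiplicative modes separate in the Fig-6B statistic", {
  ap <- fx_ap64()
  set.seed(21)
  verts <- left_roi_vertices(12, seed = 21)
  add <- simulate_beta_truth(verts, ap,
                             attention_field_spec(mode = "additive_only"),
                             modulation_spec(peak = 0.1,
                                             account = "stimulus_locked"))
  mult <- simulate_beta_truth(verts, ap,
                              attention_field_spec(mode = "multiplicative_gain"),
                              modulation_spec(peak = 0.3,
                                              account = "stimulus_locked"))
  modulation_profile <- function(tr) {
    out <- (tr$total[, "up", ] + tr$total[, "down", ] +
              tr$total[, "right", ]) / 3
    rowMeans(tr$total[, "left", ] - out)
  }
  # noiseless additive: the modulation is exactly flat across stimuli
  expect_lt(diff(range(modulation_profile(add))), 1e-10)
  # with measurement noise the additive correlation scatters near zero
  # while multiplicative modulation tracks the distributed response
  set.seed(22)
  r_of <- function(tr) {
    d <- modulation_profile(tr) + rnorm(49, 0, 0.02)
    cor(d, rowMeans(tr$total[, "distributed", ]))
  }
  expect_lt(abs(r_of(add)), 0.35)
  expect_gt(r_of(mult), 0.5)
})

test_that("noiseless BOLD embeds the predictor at the baseline intensity", {
  sched <- build_trial_schedule(20, seed = 6)
  verts <- data.frame(vertex = 1L, map = "V1", x0 = 0, y0 = 0,
                      sigma0 = 1, gain = 0)
  truth <- simulate_beta_truth(verts, fx_ap64(),
                               attention_field_spec(mode = "additive_only"),
                               modulation_spec(peak = 0))
  series <- simulate_bold(truth, sched, noise = noise_spec(sd = 0, drift_amp = 0))
  expect_true(all(abs(series - 1000) < 1e-9)) # zero betas, zero noise
})

test_that("the GLM recovers noiseless stimulus-locked betas exactly", {
  ap <- fx_ap64()
  sched <- build_trial_schedule(520, seed = 7, trials_per_scan = 52)
  verts <- sample_prf_population(6, maps = c("V1", "hV4"), seed = 2)
  truth <- simulate_beta_truth(verts, ap, attention_field_spec(mode = "both"),
                               modulation_spec(peak = 0.1,
                                               account = "stimulus_locked"))
  series <- simulate_bold(truth, sched, hrf = fx_hrf(),
                          noise = noise_spec(sd = 0, drift_amp = 0))
  fit <- fit_glm(series, build_design_matrix(sched), fx_hrf())
  B <- mapping_beta_array(fit)
  expect_lt(max(abs(B - truth$total), na.rm = TRUE), 1e-8)
})

test_that("temporal accounts move only the additive component in time", {
  sched <- build_trial_schedule(30, seed = 8)
  verts <- data.frame(vertex = 1L, map = "V1", x0 = -6, y0 = 0,
                      sigma0 = 1, gain = 0) # no stimulus-driven response
  mk <- function(account) {
    truth <- simulate_beta_truth(verts, fx_ap64(),
                                 attention_field_spec(mode = "additive_only"),
                                 modulation_spec(peak = 0.2, account = account))
    simulate_bold(truth, sched, hrf = fx_hrf(),
                  noise = noise_spec(sd = 0, drift_amp = 0))
  }
  sus <- mk("sustained"); tra <- mk("transient"); tev <- mk("target_evoked")
  # all three differ pairwise (different onsets/durations of the boxcar)
  expect_gt(max(abs(sus - tra)), 1e-6)
  expect_gt(max(abs(sus - tev)), 1e-6)
  expect_gt(max(abs(tra - tev)), 1e-6)
  # transient predictor is the shortest, sustained the longest
  expect_gt(sum(abs(sus - 1000)), sum(abs(tra - 1000)))
})

test_that("SDT behavior has the configured sensitivity structure", {
  sched <- build_trial_schedule(8000, seed = 13)
  # chance performance at d' = 0
  beh0 <- simulate_behavior(sched, dprime = c(valid = 0, neutral = 0,
                                              invalid = 0), seed = 1)
  expect_lt(abs(mean(beh0$correct) - 0.5), 0.02)
  # d' = 4 with criterion 0: accuracy -> pnorm(2)
  beh4 <- simulate_behavior(sched, dprime = c(valid = 4, neutral = 4,
                                              invalid = 4), seed = 2)
  expect_lt(abs(mean(beh4$correct) - pnorm(2)), 0.01)
  expect_true(all(beh4$rt_s > 0))
  expect_error(simulate_behavior(sched, dprime = c(valid = -1, neutral = 1,
                                                   invalid = 1)),
               "non-negative")
})

test_that("simulated gaze respects fixation, blinks, and display geometry", {
  sched <- build_trial_schedule(30, seed = 3)
  disp <- display_geometry()
  still <- simulate_gaze(sched, fixation_sd_deg = 0, blink_rate = 0, seed = 1)
  expect_true(all(abs(still$x_px - disp$center_px[1]) < 1e-9))
  expect_true(all(abs(still$y_px - disp$center_px[2]) < 1e-9))
  expect_false(any(still$blink))
  g <- simulate_gaze(sched, fixation_sd_deg = 0.05, blink_rate = 0.03,
                     seed = 2)
  expect_lt(abs(mean(g$blink) - 0.03), 0.01)
})
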