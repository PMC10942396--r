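# Attention-induced pRF center shifts and controls.

# a hand-built pRF table: one row per vertex x condition
make_prf_table <- function(centers_by_cond, map = "V1", r2 = 1) {
  conds <- names(centers_by_cond)
  do.call(rbind, lapply(conds, function(cond) {
    xy <- centers_by_cond[[cond]]
    data.frame(vertex = seq_len(nrow(xy)), condition = cond,
               x = xy[, 1], y = xy[, 2], sigma = 1, gain = 1, r2 = r2,
               degenerate = FALSE, map = map, stringsAsFactors = FALSE)
  }))
}

test_that("distance change follows the subtraction definition", {
  # distributed at (4, 0); attend-right at (4.5, 0); target (6, 0):
  # change = 1.5 - 2.0 = -0.5
  base <- matrix(c(4, 0), 1)
  centers <- list(up = base, down = base, left = base,
                  right = matrix(c(4.5, 0), 1), distributed = base)
  prfs <- make_prf_table(centers)
  right_target <- default_targets()[default_targets()$condition == "right", ]
  out <- distance_change_to_target(prfs, right_target)
  expect_equal(out$per_vertex$change, -0.5, tolerance = 1e-12)
  # identical focal and distributed centers: zero change
  same <- make_prf_table(list(up = base, down = base, left = base,
                              right = base, distributed = base))
  out0 <- distance_change_to_target(same)
  expect_equal(out0$by_map$mean_change, 0)
})

test_that("shift summaries respect the joint five-model filters", {
  base <- matrix(c(4, 0), 1)
  centers <- list(up = base, down = base, left = base,
                  right = matrix(c(4.5, 0), 1), distributed = base)
  low_r2 <- make_prf_table(centers, r2 = 0.2) # below the 0.25 threshold
  expect_warning(out <- distance_change_to_target(low_r2), "no vertex")
  expect_equal(nrow(out$by_map), 0L)
  far <- make_prf_table(lapply(centers, function(m) m + 4)) # ecc > 5.5
  expect_warning(distance_change_to_target(far), "no vertex")
})

test_that("shift summaries are invariant under global rotation", {
  set.seed(111)
  n <- 20
  r <- sqrt(runif(n)) * 4 + 0.6; th <- runif(n, 0, 2 * pi)
  base <- cbind(r * cos(th), r * sin(th))
  targets <- default_targets()
  shift_toward <- function(xy, tx, ty, d = 0.3) {
    v <- cbind(tx - xy[, 1], ty - xy[, 2])
    nv <- sqrt(rowSums(v^2))
    xy + v / nv * pmin(d, nv)
  }
  centers <- list(
    up = shift_toward(base, 0, 6), down = shift_toward(base, 0, -6),
    left = shift_toward(base, -6, 0), right = shift_toward(base, 6, 0),
    distributed = base)
  prfs <- make_prf_table(centers)
  out1 <- distance_change_to_target(prfs, targets)
  rot <- 25 * pi / 180
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
  prfs_r <- prfs
  xy_r <- as.matrix(prfs[, c("x", "y")]) %*% t(R)
  prfs_r$x <- xy_r[, 1]; prfs_r$y <- xy_r[, 2]
  targets_r <- targets
  txy <- as.matrix(targets[, c("x", "y")]) %*% t(R)
  targets_r$x <- txy[, 1]; targets_r$y <- txy[, 2]
  out2 <- distance_change_to_target(prfs_r, targets_r)
  expect_equal(out1$by_map$mean_change, out2$by_map$mean_change,
               tolerance = 1e-10)
  # every shift toward the attended target: negative summary
  expect_lt(out1$by_map$mean_change, 0)
})

test_that("recovered shift magnitude tracks the configured ground truth", {
  ap <- fx_ap64(); grid <- fx_grid64()
  set.seed(112)
  n <- 8
  r <- sqrt(runif(n)) * 3.5 + 1; th <- runif(n, 0, 2 * pi)
  verts <- data.frame(vertex = 1:n, map = "hV4",
                      x0 = r * cos(th), y0 = r * sin(th),
                      sigma0 = 1.5, gain = 2)
  rec <- sapply(c(0.1, 0.4), function(sh) {
    attn <- attention_field_spec(mode = "position_only", shift_deg = sh)
    truth <- simulate_beta_truth(verts, ap, attn,
                                 modulation_spec(peak = 0,
                                                 account = "stimulus_locked"))
    prfs <- fit_prfs_by_condition(truth$total, ap, grid = grid)
    prfs$map <- "hV4"
    out <- distance_change_to_target(prfs)
    out$by_map$mean_change
  })
  expect_lt(rec[1], 0)
  expect_lt(rec[2], rec[1]) # larger configured shift, larger recovered effect
  expect_equal(rec[1], -0.1, tolerance = 0.05)
  expect_equal(rec[2], -0.4, tolerance = 0.1)
})

test_that("vector binning flags congruent opposed shifts", {
  set.seed(113)
  n <- 40
  r <- sqrt(runif(n)) * 4.5 + 0.6; th <- runif(n, 0, 2 * pi)
  base <- cbind(r * cos(th), r * sin(th))
  delta <- 0.25
  centers <- list(
    up = base, down = base,
    left = cbind(base[, 1] - delta, base[, 2]),
    right = cbind(base[, 1] + delta, base[, 2]),
    distributed = base)
  prfs <- make_prf_table(centers)
  bins <- binned_shift_vectors(prfs, c("left", "right"))
  expect_gt(nrow(bins), 3)
  expect_true(all(bins$congruent))
  # no shift anywhere: congruence undefined
  none <- make_prf_table(list(up = base, down = base, left = base,
                              right = base, distributed = base))
  bins0 <- binned_shift_vectors(none, c("left", "right"))
  expect_true(all(is.na(bins0$congruent)))
  expect_error(binned_shift_vectors(prfs, c("left", "up")), "pair")
})

test_that("the identity permutation reproduces the unshuffled analysis", {
  ap <- fx_ap64(); grid <- fx_grid64()
  set.seed(114)
  n <- 6
  r <- sqrt(runif(n)) * 3 + 1.2; th <- runif(n, 0, 2 * pi)
  verts <- data.frame(vertex = 1:n, map = "hV4",
                      x0 = r * cos(th), y0 = r * sin(th),
                      sigma0 = 1.2, gain = 2)
  sched <- build_trial_schedule(208, seed = 115, trials_per_scan = 52)
  attn <- attention_field_spec(mode = "position_only", shift_deg = 0.4)
  truth <- simulate_beta_truth(verts, ap, attn,
                               modulation_spec(peak = 0,
                                               account = "stimulus_locked"))
  series <- simulate_bold(truth, sched, hrf = fx_hrf(),
                          noise = noise_spec(sd = 0.3), seed = 116)
  true_out <- prf_shift_pipeline(series, sched, ap, verts$map, grid = grid)
  id_out <- shuffled_control(series, sched, ap, verts$map, grid = grid,
                             permutation = seq_len(nrow(sched)))
  expect_equal(true_out$by_map, id_out$by_map, tolerance = 1e-12)
  expect_lt(true_out$by_map$mean_change, 0)
})
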