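# Shared fixtures, built once per test run. The 64-px aperture grid is the
# workhorse resolution for fitting tests; geometric property tests build
# their own finer grids.

.fx <- new.env()

fx_ap64 <- function() {
  if (is.null(.fx$ap64)) .fx$ap64 <- build_bar_apertures(resolution = 64)
  .fx$ap64
}

fx_grid64 <- function() {
  if (is.null(.fx$grid64))
    .fx$grid64 <- prf_fit_grid(fx_ap64(), prf_fit_config())
  .fx$grid64
}

fx_hrf <- function() {
  if (is.null(.fx$hrf)) .fx$hrf <- hrf_double_gamma()
  .fx$hrf
}

# a wedge population around one target, same layout per participant
wedge_vertices <- function(n, target_angle, seed, sigma_slope = 0.17) {
  set.seed(seed)
  ecc <- runif(n, 4.5, 7.5)
  ang <- (target_angle + runif(n, -25, 25)) * pi / 180
  data.frame(vertex = seq_len(n), map = "V3",
             x0 = ecc * cos(ang), y0 = ecc * sin(ang),
             sigma0 = 0.3 + sigma_slope * ecc, gain = 2,
             stringsAsFactors = FALSE)
}

left_roi_vertices <- function(n, seed, sigma_slope = 0.17) {
  wedge_vertices(n, 180, seed, sigma_slope)
}

# forward-simulate one participant's attentional modulation traces: four
# target-wedge ROIs share one scan series, and the in-minus-out differences
# are averaged across the four targets (the pooled-ROI analysis)
simulate_participant_traces <- function(account, participant, n_trials = 520,
                                        n_vertices = 30, noise_sd = 1,
                                        peak = 0.2, alignment = "cue",
                                        window_s = 14, seed = 1) {
  ap <- fx_ap64()
  targets <- default_targets()
  verts <- do.call(rbind, lapply(seq_len(nrow(targets)), function(i) {
    v <- wedge_vertices(n_vertices, targets$angle_deg[i],
                        seed * 1000 + participant * 7 + i)
    v$roi <- targets$condition[i]
    v
  }))
  verts$vertex <- seq_len(nrow(verts))
  sched <- build_trial_schedule(n_trials, seed = seed * 100 + participant,
                                trials_per_scan = 52)
  truth <- simulate_beta_truth(
    verts, ap, attention_field_spec(mode = "additive_only"),
    modulation_spec(peak = peak, account = account))
  series <- simulate_bold(truth, sched, hrf = fx_hrf(),
                          noise = noise_spec(sd = noise_sd),
                          seed = seed * 10 + participant)
  diffs <- lapply(seq_len(nrow(targets)), function(i) {
    tc <- attentional_modulation_timecourse(
      series, sched, which(verts$roi == targets$condition[i]),
      targets$condition[i], ap, c(targets$x[i], targets$y[i]),
      alignment = alignment, window_s = window_s)
    tc$diff
  })
  pooled <- Reduce(`+`, diffs) / length(diffs)
  list("1s" = pooled[, "1s"], "2s" = pooled[, "2s"])
}

simulate_group_traces <- function(account, n_participants = 8, ...) {
  lapply(seq_len(n_participants), function(p)
    simulate_participant_traces(account, p, ...))
}
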