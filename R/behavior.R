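# Behavioral sensitivity (signal detection), bootstrap confidence intervals,
# and gaze-position statistics.

#' Signal-detection sensitivity (d') for a cell of trials
#'
#' The 2AFC tilt judgment is mapped onto a yes/no framework by arbitrarily
#' treating clockwise as "target present": a hit is a CW response on a
#' CW-tilted trial and a false alarm a CW response on a CCW-tilted trial.
#' `d' = z(hit rate) - z(false-alarm rate)`. To avoid infinite values, 0.5
#' is added to the hit and false-alarm counts; under the default
#' `"loglinear"` rule 1 is also added to the corresponding trial counts
#' (`"hits_only"` leaves the denominators untouched).
#'
#' @param truth_cw Logical vector: true tilt clockwise.
#' @param resp_cw Logical vector: reported tilt clockwise.
#' @param correction `"loglinear"` or `"hits_only"`.
#' @return d' (scalar); `NA` for an empty cell or one lacking both tilt
#'   directions.
#' @export
compute_dprime <- function(truth_cw, resp_cw,
                           correction = c("loglinear", "hits_only")) {
  correction <- match.arg(correction)
  n_sig <- sum(truth_cw)
  n_noise <- sum(!truth_cw)
  if (n_sig < 1 || n_noise < 1) return(NA_real_)
  hits <- sum(resp_cw & truth_cw)
  fas <- sum(resp_cw & !truth_cw)
  denom_add <- if (correction == "loglinear") 1 else 0
  hr <- (hits + 0.5) / (n_sig + denom_add)
  far <- (fas + 0.5) / (n_noise + denom_add)
  stats::qnorm(hr) - stats::qnorm(far)
}

#' Summarize behavioral performance
#'
#' d' and mean reaction time per cue validity (optionally crossed with
#' response-cue location), with bootstrap confidence intervals across trials
#' within each cell when requested.
#'
#' @param trials Trial table with `validity`, `truth_cw`, `resp_cw`, `rt_s`,
#'   and (optionally) `response_cue`.
#' @param by_location Split cells by response-cue location as well.
#' @param correction d' correction rule, see [compute_dprime()].
#' @return `data.frame` with one row per cell: `validity` (, `location`),
#'   `n`, `dprime`, `mean_rt`.
#' @export
summarize_behavior <- function(trials, by_location = FALSE,
                               correction = "loglinear") {
  keys <- if (by_location) list(trials$validity, trials$response_cue)
          else list(trials$validity)
  cells <- split(trials, keys, drop = TRUE)
  out <- lapply(cells, function(d) {
    row <- data.frame(validity = d$validity[1], stringsAsFactors = FALSE)
    if (by_location) row$location <- d$response_cue[1]
    row$n <- nrow(d)
    row$dprime <- compute_dprime(d$truth_cw, d$resp_cw, correction)
    row$mean_rt <- mean(d$rt_s)
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Bootstrap a group statistic across participants
#'
#' Resamples participants with replacement, recomputes the group mean each
#' time, and returns the percentile confidence interval of the resampled
#' means (the protocol's group-level uncertainty throughout: 1000 resamples,
#' 68% CI by default).
#'
#' @param stat Numeric vector, one value per participant (>= 2).
#' @param n_boot Number of bootstrap resamples.
#' @param ci Central coverage of the percentile interval (e.g. 0.68, 0.95).
#' @param seed Optional integer seed.
#' @return List: `mean`, `ci` (length 2), `boot` (resampled means).
#' @export
bootstrap_group <- function(stat, n_boot = 1000L, ci = 0.68, seed = NULL) {
  stat <- stat[!is.na(stat)]
  if (length(stat) < 2) stopf("bootstrap requires at least 2 participants")
  with_seed(seed, {
    n <- length(stat)
    boot <- vapply(seq_len(n_boot),
                   function(i) mean(stat[sample.int(n, n, replace = TRUE)]),
                   numeric(1))
    alpha <- (1 - ci) / 2
    list(mean = mean(stat),
         ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
         boot = boot)
  })
}

#' Gaze-position summary per cue type
#'
#' Converts gaze samples from screen pixels to degrees of visual angle using
#' the display geometry (exact arctangent conversion per axis), removes
#' blink samples, averages each trial's gaze over the mapping-stimulus-onset
#' to target-onset window, subtracts the per-trial median gaze during the
#' 300-ms fixation period (calibration correction), and averages across
#' trials by cue type. Also reports the fraction of non-blink samples
#' farther than the fixation-break criterion from fixation.
#'
#' @param samples Gaze table from [simulate_gaze()] (or the same TSV layout):
#'   `t_ms`, `x_px`, `y_px`, `blink`.
#' @param schedule Trial schedule.
#' @param display A [display_geometry()].
#' @param break_criterion_deg Fixation-break radius, degrees (default 2).
#' @return List: `by_cue` data.frame (`cue`, `n_trials`, `x_deg`, `y_deg`),
#'   `fixation_break_fraction`, `n_excluded_trials` (all-blink windows).
#' @export
analyze_gaze <- function(samples, schedule, display = display_geometry(),
                         break_criterion_deg = 2) {
  tr_per_scan <- schedule_tr_per_scan(schedule)
  scans <- sort(unique(schedule$scan))
  offsets <- c(0L, cumsum(tr_per_scan))[seq_along(scans)] * 1000L
  names(offsets) <- scans

  gx <- px_to_deg(samples$x_px, display$center_px[1], display$cm_per_px_x,
                  display$distance_cm)
  gy <- px_to_deg(samples$y_px, display$center_px[2], display$cm_per_px_y,
                  display$distance_cm)
  ok <- !samples$blink
  frac_break <- mean(sqrt(gx[ok]^2 + gy[ok]^2) > break_criterion_deg)

  n_excluded <- 0L
  per_trial <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    t0 <- offsets[[as.character(schedule$scan[i])]] +
      schedule$onset_tr[i] * 1000L
    # trial timeline in ms: 0-300 fixation, 300-600 cue, 600 bar onset,
    # target at 600 + bar + isi
    fix_idx <- which(samples$t_ms >= t0 & samples$t_ms < t0 + 300 & ok)
    bar_on <- t0 + 600
    target_on <- t0 + 600 + schedule$bar_duration_s[i] * 1000 +
      schedule$isi_ms[i]
    win_idx <- which(samples$t_ms >= bar_on & samples$t_ms < target_on & ok)
    if (length(win_idx) == 0 || length(fix_idx) == 0) {
      n_excluded <- n_excluded + 1L
      next
    }
    per_trial[[i]] <- data.frame(
      cue = schedule$cue[i],
      x = mean(gx[win_idx]) - stats::median(gx[fix_idx]),
      y = mean(gy[win_idx]) - stats::median(gy[fix_idx]),
      stringsAsFactors = FALSE)
  }
  per_trial <- do.call(rbind, per_trial)
  by_cue <- do.call(rbind, lapply(split(per_trial, per_trial$cue), function(d)
    data.frame(cue = d$cue[1], n_trials = nrow(d), x_deg = mean(d$x),
               y_deg = mean(d$y), stringsAsFactors = FALSE)))
  rownames(by_cue) <- NULL
  list(by_cue = by_cue, fixation_break_fraction = frac_break,
       n_excluded_trials = n_excluded)
}
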