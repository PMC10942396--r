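# Trial schedules and GLM design matrices for the event-related protocol.
#
# Each trial: 300 ms fixation + 300 ms pre-cue, a bar mapping stimulus for
# 1 or 2 s, a jittered ISI, a brief Gabor target array, and a response window
# whose duration flexes so that every trial spans an integer number of 1-s
# TRs. At the TR grid this discretizes to: cue at the trial-onset TR, bar at
# the following 1 or 2 TRs, target at the TR after the bar, one response TR.

#' Trial proportion settings
#'
#' Marginal probabilities of the randomized trial factors. Defaults are the
#' experimental proportions: 80% focal cues (equiprobable over the four
#' cardinal locations) / 20% distributed; 75% cue validity on focal trials;
#' 10% blank mapping stimuli; bar duration 1 or 2 s equiprobable; ISI 50 ms
#' on 10% of trials and 300/400/500 ms equiprobable on the rest.
#'
#' @param p_focal Probability that the cue is focal.
#' @param p_valid Probability that a focal cue matches the response cue.
#' @param p_blank Probability of a blank mapping stimulus.
#' @param p_bar2 Probability of the 2-s bar duration.
#' @param p_isi Named probabilities over ISI values in ms.
#' @return List of proportions, validated to sum to 1 within each family.
#' @export
trial_proportions <- function(p_focal = 0.8, p_valid = 0.75, p_blank = 0.1,
                              p_bar2 = 0.5,
                              p_isi = c("50" = 0.1, "300" = 0.3,
                                        "400" = 0.3, "500" = 0.3)) {
  for (p in c(p_focal, p_valid, p_blank, p_bar2))
    if (p < 0 || p > 1) stopf("invalid configuration: probabilities must lie in [0, 1]")
  if (abs(sum(p_isi) - 1) > 1e-8)
    stopf("invalid configuration: ISI probabilities must sum to 1 (got %g)", sum(p_isi))
  list(p_focal = p_focal, p_valid = p_valid, p_blank = p_blank,
       p_bar2 = p_bar2, p_isi = p_isi)
}

#' Build a pseudo-random trial schedule
#'
#' Samples trial factors independently per trial according to
#' [trial_proportions()] (the protocol randomizes rather than counterbalances
#' trial composition). Reproducible for a fixed `seed`.
#'
#' @param n_trials Number of trials (> 0).
#' @param seed Optional integer seed.
#' @param proportions A [trial_proportions()] list.
#' @param trials_per_scan If given, trials are grouped into consecutive scans
#'   of this size and TR indices restart within each scan.
#' @param pad_pre_tr TRs of rest prepended to each scan before the first trial.
#' @return A `data.frame` with one row per trial: `trial`, `scan`, `cue`,
#'   `bar_index` (1..49, 49 = blank), `bar_duration_s`, `isi_ms`,
#'   `response_cue`, `validity`, `onset_tr` (0-based, within scan),
#'   `duration_tr`, `cue_tr`, `bar_onset_tr`, `target_tr`. Attribute
#'   `tr_per_scan` holds the per-scan TR counts.
#' @export
build_trial_schedule <- function(n_trials, seed = NULL,
                                 proportions = trial_proportions(),
                                 trials_per_scan = NULL, pad_pre_tr = 0L) {
  if (n_trials <= 0) stopf("invalid configuration: n_trials must be positive")
  p <- proportions
  with_seed(seed, {
    focal <- stats::runif(n_trials) < p$p_focal
    cue <- ifelse(focal, sample(focal_conditions(), n_trials, replace = TRUE),
                  "distributed")
    blank <- stats::runif(n_trials) < p$p_blank
    bar_index <- ifelse(blank, 49L, sample.int(48L, n_trials, replace = TRUE))
    bar_duration <- ifelse(stats::runif(n_trials) < p$p_bar2, 2L, 1L)
    isi <- as.integer(sample(names(p$p_isi), n_trials, replace = TRUE,
                             prob = p$p_isi))
    valid <- stats::runif(n_trials) < p$p_valid
    response_cue <- character(n_trials)
    for (i in seq_len(n_trials)) {
      if (!focal[i]) {
        response_cue[i] <- sample(focal_conditions(), 1L)
      } else if (valid[i]) {
        response_cue[i] <- cue[i]
      } else {
        response_cue[i] <- sample(setdiff(focal_conditions(), cue[i]), 1L)
      }
    }
    validity <- ifelse(!focal, "neutral", ifelse(cue == response_cue, "valid", "invalid"))
    duration_tr <- 3L + bar_duration

    if (is.null(trials_per_scan)) trials_per_scan <- n_trials
    scan <- (seq_len(n_trials) - 1L) %/% trials_per_scan + 1L
    onset_tr <- integer(n_trials)
    for (s in unique(scan)) {
      idx <- which(scan == s)
      onset_tr[idx] <- pad_pre_tr + cumsum(c(0L, duration_tr[idx]))[seq_along(idx)]
    }
    sched <- data.frame(
      trial = seq_len(n_trials), scan = scan, cue = cue,
      bar_index = as.integer(bar_index), bar_duration_s = bar_duration,
      isi_ms = isi, response_cue = response_cue, validity = validity,
      onset_tr = as.integer(onset_tr), duration_tr = duration_tr,
      stringsAsFactors = FALSE)
    sched$cue_tr <- sched$onset_tr
    sched$bar_onset_tr <- sched$onset_tr + 1L
    sched$target_tr <- sched$onset_tr + 1L + sched$bar_duration_s
    tr_per_scan <- vapply(split(sched, sched$scan),
                          function(d) max(d$onset_tr + d$duration_tr), integer(1))
    attr(sched, "tr_per_scan") <- unname(tr_per_scan)
    sched
  })
}

# per-scan TR counts for a schedule, falling back to the stored attribute
schedule_tr_per_scan <- function(schedule, tr_per_scan = NULL) {
  out <- tr_per_scan %||% attr(schedule, "tr_per_scan")
  if (is.null(out)) {
    out <- vapply(split(schedule, schedule$scan),
                  function(d) max(d$onset_tr + d$duration_tr), integer(1))
    out <- unname(out)
  }
  out
}

#' Design-matrix column labels
#'
#' 245 mapping labels (5 conditions x 49 stimuli) followed by 5 target labels.
#' @param n_stim Number of mapping stimuli (default 49).
#' @return Character vector of length `5 * n_stim + 5`.
#' @export
design_column_labels <- function(n_stim = 49L) {
  conds <- attention_conditions()
  c(as.vector(t(outer(conds, seq_len(n_stim),
                      function(co, st) sprintf("map_%s_%02d", co, st)))),
    sprintf("target_%s", conds))
}

#' Build the GLM design matrix
#'
#' TR-by-250 indicator matrix: one column per attention condition x mapping
#' stimulus (1s spanning the 1 or 2 bar TRs) plus one target column per
#' condition (a single 1 at the target TR). Sub-TR events (cue, ISI, response
#' window) are not represented. Multiple scans are concatenated row-wise.
#'
#' @param schedule A schedule from [build_trial_schedule()].
#' @param tr_per_scan Integer vector of TR counts per scan (default: the
#'   schedule's own `tr_per_scan` attribute).
#' @return Matrix with `sum(tr_per_scan)` rows and 250 labeled columns;
#'   attributes `tr_per_scan` and `conditions`.
#' @export
build_design_matrix <- function(schedule, tr_per_scan = NULL) {
  if (nrow(schedule) == 0L) {
    n_tr <- sum(tr_per_scan %||% 0L)
    return(matrix(0, nrow = n_tr, ncol = 250L,
                  dimnames = list(NULL, design_column_labels())))
  }
  tr_per_scan <- schedule_tr_per_scan(schedule, tr_per_scan)
  scans <- sort(unique(schedule$scan))
  if (length(tr_per_scan) == 1L && length(scans) > 1L)
    tr_per_scan <- rep(tr_per_scan, length(scans))
  if (length(tr_per_scan) != length(scans))
    stopf("tr_per_scan must have one entry per scan")
  offsets <- c(0L, cumsum(tr_per_scan))[seq_along(scans)]
  names(offsets) <- scans
  n_tr <- sum(tr_per_scan)

  labels <- design_column_labels()
  X <- matrix(0, nrow = n_tr, ncol = length(labels),
              dimnames = list(NULL, labels))
  conds <- attention_conditions()
  for (i in seq_len(nrow(schedule))) {
    tr0 <- offsets[[as.character(schedule$scan[i])]]
    bar_rows <- tr0 + schedule$bar_onset_tr[i] +
      seq_len(schedule$bar_duration_s[i]) # 1-based rows for 0-based TRs
    target_row <- tr0 + schedule$target_tr[i] + 1L
    scan_end <- tr0 + tr_per_scan[[match(schedule$scan[i], scans)]]
    if (max(bar_rows, target_row) > scan_end)
      stopf("out of range: trial %d exceeds scan length (%d TRs)",
            schedule$trial[i], tr_per_scan[[match(schedule$scan[i], scans)]])
    ci <- match(schedule$cue[i], conds)
    X[bar_rows, (ci - 1L) * 49L + schedule$bar_index[i]] <- 1
    X[target_row, 245L + ci] <- 1
  }
  attr(X, "tr_per_scan") <- tr_per_scan
  attr(X, "conditions") <- conds
  X
}
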