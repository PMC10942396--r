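# Synthetic ground-truth data: vertex populations with known pRFs, known
# attentional modulation (additive wedge and/or attention-field position
# shifts), noisy BOLD time series, signal-detection behavior, and fixational
# gaze. Every downstream stage of the pipeline is validated by recovering
# these known parameters.

#' Sample a ground-truth pRF population
#'
#' Vertices are drawn quasi-uniformly over the circular stimulus window
#' (uniform in area). pRF size follows the canonical linear size-eccentricity
#' relation, `sigma0 = intercept + slope(map) * eccentricity + jitter`,
#' truncated to stay positive, with map-specific slopes increasing up the
#' cortical hierarchy. Gains are positive (percent BOLD at full overlap).
#'
#' @param n_per_map Vertices per visual field map.
#' @param maps Map labels (default the six modeled maps).
#' @param slopes Named size-eccentricity slopes per map (deg sigma / deg ecc).
#' @param intercept Size at fixation, degrees.
#' @param sigma_jitter SD of Gaussian jitter added to sigma, degrees.
#' @param gain_mean,gain_sd Lognormal gain parameters (percent BOLD).
#' @param window_radius_deg Maximum eccentricity, degrees.
#' @param seed Optional integer seed.
#' @return `data.frame`: `vertex`, `map`, `x0`, `y0`, `sigma0`, `gain`.
#' @export
sample_prf_population <- function(n_per_map = 200L, maps = map_labels(),
                                  slopes = c(V1 = 0.10, V2 = 0.13, V3 = 0.17,
                                             "hV4" = 0.25, "V3A/B" = 0.27,
                                             LO1 = 0.30),
                                  intercept = 0.3, sigma_jitter = 0.05,
                                  gain_mean = 2, gain_sd = 0.3,
                                  window_radius_deg = 12.4, seed = NULL) {
  if (n_per_map <= 0) stopf("invalid configuration: n_per_map must be positive")
  if (any(slopes[maps] <= 0) || any(is.na(slopes[maps])))
    stopf("invalid configuration: a positive slope is required for every map")
  with_seed(seed, {
    n <- n_per_map * length(maps)
    r <- window_radius_deg * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    map <- rep(maps, each = n_per_map)
    ecc <- r
    sigma <- intercept + slopes[map] * ecc +
      stats::rnorm(n, 0, sigma_jitter)
    sigma <- pmax(sigma, 0.05)
    data.frame(
      vertex = seq_len(n), map = map,
      x0 = r * cos(th), y0 = r * sin(th), sigma0 = as.numeric(sigma),
      gain = exp(stats::rnorm(n, log(gain_mean), gain_sd)),
      stringsAsFactors = FALSE)
  })
}

#' Default attentional target locations
#'
#' The four Gabor targets at 6 deg eccentricity on the cardinal meridians.
#' @param ecc_deg Target eccentricity in degrees.
#' @return `data.frame` with `condition`, `x`, `y`, `angle_deg`.
#' @export
default_targets <- function(ecc_deg = 6) {
  data.frame(
    condition = focal_conditions(),
    x = c(0, 0, -ecc_deg, ecc_deg),
    y = c(ecc_deg, -ecc_deg, 0, 0),
    angle_deg = c(90, 270, 180, 0),
    stringsAsFactors = FALSE)
}

#' Attention-field specification
#'
#' A Gaussian attention field centered at each focal target. Under focal
#' attention the effective pRF is the (normalized) product of the attention
#' field and the baseline pRF Gaussian, which pulls the pRF center toward the
#' attended target (see [attention_field_transform()]). `shift_deg`, when
#' given, instead displaces the center directly toward the target by a fixed
#' amount (size unchanged), providing exact position-shift ground truth.
#'
#' @param targets Target table from [default_targets()].
#' @param sigma_attn Attention-field SD, degrees (> 0).
#' @param mode One of `"additive_only"` (no position change),
#'   `"position_only"`, `"both"`, `"multiplicative_gain"`.
#' @param shift_deg Optional fixed center displacement toward the target,
#'   degrees (overrides the Gaussian-product geometry).
#' @return Object of class `attention_field_spec`.
#' @export
attention_field_spec <- function(targets = default_targets(), sigma_attn = 8,
                                 mode = c("additive_only", "position_only",
                                          "both", "multiplicative_gain"),
                                 shift_deg = NULL) {
  if (sigma_attn <= 0) stopf("invalid argument: sigma_attn must be positive")
  structure(list(targets = targets, sigma_attn = sigma_attn,
                 mode = match.arg(mode), shift_deg = shift_deg),
            class = "attention_field_spec")
}

#' Gaussian-product receptive-field transform
#'
#' Closed form for the multiplication of an attentional gain field with a
#' Gaussian receptive field. The product of two isotropic Gaussians is a
#' Gaussian with center
#' `(sigma_attn^2 * c_prf + sigma0^2 * c_field) / (sigma0^2 + sigma_attn^2)`
#' (componentwise) and size
#' `sqrt(sigma0^2 * sigma_attn^2 / (sigma0^2 + sigma_attn^2))`;
#' the new center lies strictly between pRF and field centers and the new
#' size is smaller than either.
#'
#' @param prf Numeric `(x0, y0, sigma0)` of the baseline pRF.
#' @param field Numeric `(x, y, sigma_attn)` of the attention field.
#' @return Named numeric `(x, y, sigma)` of the effective pRF.
#' @export
attention_field_transform <- function(prf, field) {
  s0 <- prf[[3]]; sa <- field[[3]]
  if (s0 <= 0 || sa <= 0)
    stopf("invalid argument: both Gaussian sizes must be positive")
  w <- sa^2 / (s0^2 + sa^2)
  c(x = w * prf[[1]] + (1 - w) * field[[1]],
    y = w * prf[[2]] + (1 - w) * field[[2]],
    sigma = sqrt(s0^2 * sa^2 / (s0^2 + sa^2)))
}

# per-condition effective pRFs for a vertex table; list of data.frames keyed
# by condition, each with x, y, sigma
effective_prfs <- function(vertices, attn) {
  base <- data.frame(x = vertices$x0, y = vertices$y0, sigma = vertices$sigma0)
  out <- list(distributed = base)
  for (i in seq_len(nrow(attn$targets))) {
    cond <- attn$targets$condition[i]
    if (attn$mode %in% c("additive_only", "multiplicative_gain")) {
      out[[cond]] <- base
    } else if (!is.null(attn$shift_deg)) {
      dx <- attn$targets$x[i] - base$x
      dy <- attn$targets$y[i] - base$y
      d <- sqrt(dx^2 + dy^2)
      step <- pmin(attn$shift_deg, d)
      f <- ifelse(d > 0, step / d, 0)
      out[[cond]] <- data.frame(x = base$x + f * dx, y = base$y + f * dy,
                                sigma = base$sigma)
    } else {
      w <- attn$sigma_attn^2 / (base$sigma^2 + attn$sigma_attn^2)
      out[[cond]] <- data.frame(
        x = w * base$x + (1 - w) * attn$targets$x[i],
        y = w * base$y + (1 - w) * attn$targets$y[i],
        sigma = sqrt(base$sigma^2 * attn$sigma_attn^2 /
                       (base$sigma^2 + attn$sigma_attn^2)))
    }
  }
  out[attention_conditions()]
}

#' Attentional modulation specification
#'
#' The wedge-shaped additive baseline modulation and its within-trial
#' temporal account. The additive offset for a vertex under a focal condition
#' is a difference-of-von-Mises profile of the polar-angle distance between
#' the vertex's baseline pRF center and the attended target: positive
#' (enhancement) near the target, negative (suppression) far from it. The
#' distributed condition carries no additive offset. In multiplicative-gain
#' mode the same profile acts as a dimensionless gain factor `1 + g`.
#'
#' Temporal accounts of when the modulation enters the neural predictor:
#' `"stimulus_locked"` folds it into the mapping-stimulus response exactly as
#' the GLM models it; `"sustained"` runs from the cue TR through the target
#' TR; `"transient"` occupies only the cue TR; `"target_evoked"` runs from
#' the target TR to the end of the trial.
#'
#' @param peak Profile value at zero polar distance (percent BOLD for
#'   additive modes; gain fraction for multiplicative mode).
#' @param B Offset of the profile.
#' @param mu Profile center, degrees of polar-angle distance.
#' @param kappa1,kappa2 Concentrations of the positive and negative von Mises
#'   terms (`kappa1 > kappa2` gives center-surround structure).
#' @param account Temporal account (see above).
#' @param target_amp Amplitude of the Gabor-target response, percent BOLD.
#' @return Object of class `modulation_spec`; field `S` holds the scalar that
#'   makes the profile peak equal `peak` exactly.
#' @export
modulation_spec <- function(peak = 0.1, B = 0, mu = 0, kappa1 = 6, kappa2 = 1,
                            account = c("sustained", "stimulus_locked",
                                        "transient", "target_evoked"),
                            target_amp = 0) {
  if (kappa1 <= 0 || kappa2 <= 0)
    stopf("invalid configuration: kappa1 and kappa2 must be positive")
  structure(list(
    S = dvm_scale_for_peak(peak, B, kappa1, kappa2), B = B, mu = mu,
    kappa1 = kappa1, kappa2 = kappa2, peak = peak,
    account = match.arg(account), target_amp = target_amp),
    class = "modulation_spec")
}

# additive offset (or gain fraction) per condition x vertex
modulation_matrix <- function(vertices, attn, mod) {
  conds <- attention_conditions()
  m <- matrix(0, nrow = length(conds), ncol = nrow(vertices),
              dimnames = list(conds, NULL))
  v_angle <- polar_angle(vertices$x0, vertices$y0)
  for (i in seq_len(nrow(attn$targets))) {
    cond <- attn$targets$condition[i]
    dth <- polar_angle_distance(v_angle, attn$targets$angle_deg[i])
    m[cond, ] <- dvm_value(dth, mod[c("S", "B", "mu", "kappa1", "kappa2")])
  }
  m
}

#' Simulate ground-truth beta profiles
#'
#' For each vertex, condition and mapping stimulus, the true response is
#' `gain * overlap(effective Gaussian, aperture)` plus, in the additive
#' modes, the condition's additive baseline offset (the blank stimulus
#' receives the offset only). In multiplicative-gain mode the response is
#' `(1 + g) * gain * overlap` with no additive term.
#'
#' @param vertices Population from [sample_prf_population()].
#' @param ap Aperture set.
#' @param attn An [attention_field_spec()].
#' @param mod A [modulation_spec()].
#' @return Object of class `beta_truth`: arrays `stimulus` and `total`
#'   (49 x 5 x V), matrix `additive` (5 x V), matrix `target` (5 x V), plus
#'   the inputs.
#' @export
simulate_beta_truth <- function(vertices, ap, attn = attention_field_spec(),
                                mod = modulation_spec()) {
  V <- nrow(vertices)
  conds <- attention_conditions()
  eff <- effective_prfs(vertices, attn)
  A <- aperture_matrix(ap)
  stim <- array(0, dim = c(ap$n_apertures, length(conds), V),
                dimnames = list(NULL, conds, NULL))
  base_ov <- NULL # conditions with unshifted pRFs share the base overlaps
  for (cond in conds) {
    unshifted <- identical(eff[[cond]], eff[["distributed"]])
    if (unshifted && !is.null(base_ov)) {
      ov <- base_ov
    } else {
      ov <- overlap_matrix(A, ap$coords, eff[[cond]])
      if (unshifted) base_ov <- ov
    }
    stim[, cond, ] <- sweep(ov, 2, vertices$gain, `*`)
  }
  madd <- modulation_matrix(vertices, attn, mod)
  n_ap <- ap$n_apertures
  total <- stim
  if (attn$mode == "multiplicative_gain") {
    for (ci in seq_along(conds))
      total[, ci, ] <- stim[, ci, ] * rep(1 + madd[ci, ], each = n_ap)
    additive <- matrix(0, length(conds), V, dimnames = list(conds, NULL))
  } else {
    for (ci in seq_along(conds))
      total[, ci, ] <- stim[, ci, ] + rep(madd[ci, ], each = n_ap)
    additive <- madd
  }
  target <- matrix(mod$target_amp, length(conds), V,
                   dimnames = list(conds, NULL))
  structure(list(stimulus = stim, total = total, additive = additive,
                 target = target, vertices = vertices, attn = attn, mod = mod,
                 conditions = conds),
            class = "beta_truth")
}

# overlap of many Gaussians (rows of prf data.frame) with all apertures:
# returns n_apertures x V matrix
overlap_matrix <- function(A, coords, prf) {
  V <- nrow(prf)
  P <- length(coords)^2
  G <- matrix(0, P, V)
  for (v in seq_len(V)) {
    gx <- exp(-(coords - prf$x[v])^2 / (2 * prf$sigma[v]^2))
    gy <- exp(-(coords - prf$y[v])^2 / (2 * prf$sigma[v]^2))
    G[, v] <- as.vector(outer(gx, gy))
  }
  sweep(A %*% G, 2, colSums(G), `/`)
}

#' Noise specification for synthetic BOLD
#'
#' White Gaussian noise plus per-scan polynomial drift, both in percent BOLD
#' units. The defaults are calibration choices for surface-vertex time
#' series, not measured values.
#'
#' @param sd White-noise SD per TR, percent BOLD.
#' @param drift_amp Peak amplitude of the per-scan drift, percent BOLD.
#' @param drift_order Polynomial order of the drift (1 = linear).
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(sd = 1, drift_amp = 0.5, drift_order = 1L) {
  if (sd < 0 || drift_amp < 0)
    stopf("invalid configuration: noise SDs must be non-negative")
  structure(list(sd = sd, drift_amp = drift_amp,
                 drift_order = as.integer(drift_order)),
            class = "noise_spec")
}

#' Simulate per-vertex BOLD time series
#'
#' Builds the neural predictor from the ground-truth betas (mapping-stimulus
#' boxcars at the bar TRs, a transient at the target TR, and the additive
#' attentional component placed according to the modulation spec's temporal
#' account), convolves it with the HRF within each scan, and embeds it in a
#' raw-intensity series: `baseline * (1 + (signal + drift + noise) / 100)`.
#'
#' @param truth A `beta_truth` from [simulate_beta_truth()].
#' @param schedule Trial schedule.
#' @param hrf Sampled hemodynamic impulse response (1-s sampling).
#' @param noise A [noise_spec()].
#' @param tr_per_scan Per-scan TR counts (default from the schedule).
#' @param baseline Mean raw signal intensity.
#' @param seed Optional integer seed.
#' @return Matrix `sum(tr_per_scan) x V` of raw signal; attribute
#'   `tr_per_scan`.
#' @export
simulate_bold <- function(truth, schedule, hrf = hrf_double_gamma(),
                          noise = noise_spec(), tr_per_scan = NULL,
                          baseline = 1000, seed = NULL) {
  tr_per_scan <- schedule_tr_per_scan(schedule, tr_per_scan)
  scans <- sort(unique(schedule$scan))
  offsets <- c(0L, cumsum(tr_per_scan))[seq_along(scans)]
  names(offsets) <- scans
  n_tr <- sum(tr_per_scan)
  V <- dim(truth$total)[3]
  conds <- truth$conditions
  account <- truth$mod$account

  stim_beta <- if (account == "stimulus_locked") truth$total else truth$stimulus
  neural <- matrix(0, n_tr, V)
  for (i in seq_len(nrow(schedule))) {
    tr0 <- offsets[[as.character(schedule$scan[i])]]
    cond <- schedule$cue[i]
    bar_rows <- tr0 + schedule$bar_onset_tr[i] + seq_len(schedule$bar_duration_s[i])
    neural[bar_rows, ] <- neural[bar_rows, , drop = FALSE] +
      rep(stim_beta[schedule$bar_index[i], cond, ], each = length(bar_rows))
    target_row <- tr0 + schedule$target_tr[i] + 1L
    neural[target_row, ] <- neural[target_row, ] + truth$target[cond, ]
    if (account != "stimulus_locked") {
      add_rows <- switch(account,
        sustained = tr0 + (schedule$cue_tr[i]:schedule$target_tr[i]) + 1L,
        transient = tr0 + schedule$cue_tr[i] + 1L,
        target_evoked = tr0 +
          (schedule$target_tr[i]:(schedule$onset_tr[i] + schedule$duration_tr[i] - 1L)) + 1L)
      neural[add_rows, ] <- neural[add_rows, , drop = FALSE] +
        rep(truth$additive[cond, ], each = length(add_rows))
    }
  }

  with_seed(seed, {
    signal <- matrix(0, n_tr, V)
    row0 <- 0L
    for (s in seq_along(scans)) {
      rows <- row0 + seq_len(tr_per_scan[s])
      for (v in seq_len(V))
        signal[rows, v] <- convolve_with_hrf(neural[rows, v], hrf)
      if (noise$drift_amp > 0 && noise$drift_order > 0) {
        tt <- seq(-1, 1, length.out = tr_per_scan[s])
        drift_basis <- outer(tt, seq_len(noise$drift_order), `^`)
        coef <- matrix(stats::rnorm(noise$drift_order * V, 0, noise$drift_amp),
                       noise$drift_order, V)
        signal[rows, ] <- signal[rows, ] + drift_basis %*% coef
      }
      # center per scan so the series mean equals the baseline intensity;
      # the offset is absorbed by the constant nuisance regressor
      signal[rows, ] <- sweep(signal[rows, , drop = FALSE], 2,
                              colMeans(signal[rows, , drop = FALSE]))
      row0 <- row0 + tr_per_scan[s]
    }
    if (noise$sd > 0)
      signal <- signal + matrix(stats::rnorm(n_tr * V, 0, noise$sd), n_tr, V)
    out <- baseline * (1 + signal / 100)
    attr(out, "tr_per_scan") <- tr_per_scan
    out
  })
}

#' Reaction-time model parameters
#'
#' Shifted-lognormal reaction times with a validity-dependent location chosen
#' so that the mean RT per validity equals `mean_rt`.
#'
#' @param mean_rt Named mean RTs in seconds per validity.
#' @param shift Non-decision shift in seconds.
#' @param sdlog Lognormal shape parameter.
#' @return List of RT parameters.
#' @export
rt_params <- function(mean_rt = c(valid = 0.30, neutral = 0.56, invalid = 0.56),
                      shift = 0.15, sdlog = 0.3) {
  if (any(mean_rt <= shift))
    stopf("invalid configuration: mean RTs must exceed the shift")
  list(mean_rt = mean_rt, shift = shift, sdlog = sdlog,
       meanlog = log(mean_rt - shift) - sdlog^2 / 2)
}

#' Simulate behavioral responses under equal-variance SDT
#'
#' Each trial's internal evidence is Normal(+d'/2, 1) when the true tilt is
#' clockwise and Normal(-d'/2, 1) when counterclockwise, with d' set by the
#' trial's cue validity; a zero criterion maps evidence to a CW/CCW report.
#' Default d' values are the group means reported for this protocol
#' (valid 4.00, neutral 1.57, invalid 0.52).
#'
#' @param schedule Trial schedule.
#' @param dprime Named non-negative d' per validity.
#' @param rt A [rt_params()] list.
#' @param seed Optional integer seed.
#' @return The schedule with added columns `truth_cw`, `resp_cw`, `correct`,
#'   `rt_s`.
#' @export
simulate_behavior <- function(schedule,
                              dprime = c(valid = 4.00, neutral = 1.57,
                                         invalid = 0.52),
                              rt = rt_params(), seed = NULL) {
  if (any(dprime < 0)) stopf("invalid configuration: d-prime must be non-negative")
  with_seed(seed, {
    n <- nrow(schedule)
    d <- dprime[schedule$validity]
    truth_cw <- stats::runif(n) < 0.5
    evidence <- stats::rnorm(n, ifelse(truth_cw, d / 2, -d / 2), 1)
    schedule$truth_cw <- truth_cw
    schedule$resp_cw <- evidence > 0
    schedule$correct <- schedule$truth_cw == schedule$resp_cw
    schedule$rt_s <- rt$shift +
      stats::rlnorm(n, rt$meanlog[schedule$validity], rt$sdlog)
    schedule
  })
}

#' Scanner display geometry
#'
#' The projected display used in the scanner: 1920 x 1080 px over
#' 60 x 36.2 cm viewed at 86.5 cm.
#' @param width_px,height_px Display resolution.
#' @param width_cm,height_cm Physical size.
#' @param distance_cm Total viewing distance.
#' @return List of display parameters with pixel pitch per axis.
#' @export
display_geometry <- function(width_px = 1920, height_px = 1080,
                             width_cm = 60, height_cm = 36.2,
                             distance_cm = 86.5) {
  list(width_px = width_px, height_px = height_px,
       width_cm = width_cm, height_cm = height_cm, distance_cm = distance_cm,
       cm_per_px_x = width_cm / width_px, cm_per_px_y = height_cm / height_px,
       center_px = c(width_px / 2, height_px / 2))
}

# exact atan conversions between screen pixels and degrees of visual angle
px_to_deg <- function(px, center, cm_per_px, distance_cm) {
  atan((px - center) * cm_per_px / distance_cm) * 180 / pi
}
deg_to_px <- function(deg, center, cm_per_px, distance_cm) {
  center + tan(deg * pi / 180) * distance_cm / cm_per_px
}

#' Simulate fixational gaze traces
#'
#' 1-kHz gaze samples around screen-center fixation with isotropic Gaussian
#' jitter, and blink episodes of ~150 ms flagged at a rate chosen so the
#' flagged fraction approximates `blink_rate`. `bias_deg` models a cue-driven
#' gaze bias: it is applied from each trial's cue onset (300 ms in) onward
#' but not during the initial fixation period, so the downstream per-trial
#' median-of-fixation correction does not cancel it.
#'
#' @param schedule Trial schedule (sets the recording duration).
#' @param fixation_sd_deg SD of fixational jitter, degrees.
#' @param blink_rate Target fraction of samples flagged as blinks.
#' @param bias_deg Cue-locked gaze bias `(x, y)` in degrees.
#' @param display A [display_geometry()].
#' @param seed Optional integer seed.
#' @return `data.frame` with `t_ms` (0-based), `x_px`, `y_px`, `blink`.
#' @export
simulate_gaze <- function(schedule, fixation_sd_deg = 0.05, blink_rate = 0.02,
                          bias_deg = c(0, 0), display = display_geometry(),
                          seed = NULL) {
  if (fixation_sd_deg < 0 || blink_rate < 0)
    stopf("invalid configuration: rates must be non-negative")
  tr_per_scan <- schedule_tr_per_scan(schedule)
  total_ms <- sum(tr_per_scan) * 1000L
  scans <- sort(unique(schedule$scan))
  scan_offset_ms <- c(0L, cumsum(tr_per_scan))[seq_along(scans)] * 1000L
  names(scan_offset_ms) <- scans
  biased <- rep(FALSE, total_ms)
  for (i in seq_len(nrow(schedule))) {
    t0 <- scan_offset_ms[[as.character(schedule$scan[i])]] +
      schedule$onset_tr[i] * 1000L
    t1 <- t0 + schedule$duration_tr[i] * 1000L
    biased[(t0 + 300L + 1L):min(t1, total_ms)] <- TRUE
  }
  with_seed(seed, {
    gx <- bias_deg[1] * biased + stats::rnorm(total_ms, 0, fixation_sd_deg)
    gy <- bias_deg[2] * biased + stats::rnorm(total_ms, 0, fixation_sd_deg)
    blink <- rep(FALSE, total_ms)
    if (blink_rate > 0) {
      dur <- 150
      n_ep <- stats::rpois(1, total_ms / 1000 * blink_rate * 1000 / dur)
      if (n_ep > 0) {
        starts <- sample.int(total_ms, n_ep, replace = TRUE)
        for (s in starts) blink[s:min(s + dur - 1L, total_ms)] <- TRUE
      }
    }
    data.frame(
      t_ms = seq_len(total_ms) - 1L,
      x_px = deg_to_px(gx, display$center_px[1], display$cm_per_px_x,
                       display$distance_cm),
      y_px = deg_to_px(gy, display$center_px[2], display$cm_per_px_y,
                       display$distance_cm),
      blink = blink)
  })
}
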