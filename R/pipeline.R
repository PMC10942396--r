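# End-to-end orchestration over the synthetic-data path: design -> synth ->
# GLM -> pRF -> ROI -> attention analyses, with a seed-stamped manifest so
# identical configurations reproduce identical outputs.

#' Pipeline configuration
#'
#' Bundles the geometry, population, schedule, noise and fit settings for a
#' full synthetic run. The defaults describe a small but complete session;
#' the experimental proportions themselves live in [trial_proportions()].
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param maps Visual field maps to simulate.
#' @param n_per_map Vertices per map.
#' @param n_trials Total trials.
#' @param trials_per_scan Trials per scan (default 52).
#' @param resolution Aperture grid resolution.
#' @param attn An [attention_field_spec()].
#' @param mod A [modulation_spec()].
#' @param noise A [noise_spec()].
#' @param fit_config A [prf_fit_config()].
#' @param nuisance_order GLM per-scan polynomial order.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, maps = c("V1", "hV4"),
                            n_per_map = 50L, n_trials = 520L,
                            trials_per_scan = 52L, resolution = 64L,
                            attn = attention_field_spec(mode = "both"),
                            mod = modulation_spec(),
                            noise = noise_spec(),
                            fit_config = prf_fit_config(),
                            nuisance_order = 2L) {
  structure(list(seed = as.integer(seed), maps = maps,
                 n_per_map = as.integer(n_per_map),
                 n_trials = as.integer(n_trials),
                 trials_per_scan = as.integer(trials_per_scan),
                 resolution = as.integer(resolution), attn = attn, mod = mod,
                 noise = noise, fit_config = fit_config,
                 nuisance_order = as.integer(nuisance_order)),
            class = "pipeline_config")
}

#' Run the full synthetic pipeline
#'
#' Generates apertures, a trial schedule, a ground-truth vertex population
#' and its BOLD time series; fits the GLM and the per-condition pRF models;
#' selects the wedge target ROIs; and computes the attentional analyses
#' (per-map tuning curves with von Mises fits and spread, distance-change
#' shift summary, behavioral summary). Deterministic for a fixed config.
#'
#' @param config A [pipeline_config()].
#' @return List with the stage outputs (`apertures`, `schedule`, `vertices`,
#'   `truth`, `series`, `glm`, `prfs`, `rois`, `tuning`, `shifts`,
#'   `behavior`) and a `manifest` recording the seed and configuration.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  seed <- config$seed
  ap <- build_bar_apertures(resolution = config$resolution)
  schedule <- build_trial_schedule(config$n_trials, seed = seed,
                                   trials_per_scan = config$trials_per_scan)
  slopes <- c(V1 = 0.10, V2 = 0.13, V3 = 0.17, "hV4" = 0.25,
              "V3A/B" = 0.27, LO1 = 0.30)
  vertices <- sample_prf_population(config$n_per_map, maps = config$maps,
                                    slopes = slopes, seed = seed + 1L)
  truth <- simulate_beta_truth(vertices, ap, config$attn, config$mod)
  series <- simulate_bold(truth, schedule, noise = config$noise,
                          seed = seed + 2L)
  design <- build_design_matrix(schedule)
  glm_fit <- fit_glm(series, design, nuisance_order = config$nuisance_order)
  betas <- mapping_beta_array(glm_fit)
  grid <- prf_fit_grid(ap, config$fit_config)
  prfs <- fit_prfs_by_condition(betas, ap, config$fit_config, grid)
  prfs$map <- vertices$map[prfs$vertex]

  avg <- prfs[prfs$condition == "average", ]
  avg$glm_r2 <- glm_fit$r2[avg$vertex]
  targets <- config$attn$targets
  rois <- lapply(seq_len(nrow(targets)), function(i)
    select_wedge_roi(avg, targets$angle_deg[i]))
  names(rois) <- targets$condition

  tuning <- lapply(split(seq_len(nrow(vertices)), vertices$map), function(vi) {
    sub <- avg[avg$vertex %in% vi, ]
    curves <- lapply(seq_len(nrow(targets)), function(i) {
      modv <- vertex_modulation(
        betas[, , sub$vertex, drop = FALSE], targets$condition[i])
      polar_tuning_curve(modv, sub, targets$angle_deg[i])
    })
    curve <- average_tuning_curves(curves)
    fit <- tryCatch(fit_diff_von_mises(curve), error = function(e) NULL)
    list(curve = curve, fit = fit,
         spread = if (!is.null(fit)) attentional_spread(fit) else NULL)
  })

  shifts <- distance_change_to_target(prfs, targets)
  behavior <- summarize_behavior(
    simulate_behavior(schedule, seed = seed + 3L))

  list(apertures = ap, schedule = schedule, vertices = vertices,
       truth = truth, series = series, glm = glm_fit, prfs = prfs,
       rois = rois, tuning = tuning, shifts = shifts, behavior = behavior,
       manifest = list(seed = seed, config = config,
                       n_tr = sum(schedule_tr_per_scan(schedule)),
                       n_vertices = nrow(vertices)))
}
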