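# Attention-induced pRF center shifts: change in distance to the attended
# target (focal minus distributed), a shuffled-cue control pipeline, and
# directional vector binning.

# apply the analysis filters jointly across all five condition models
shift_filter_vertices <- function(prfs, ecc_range, min_r2) {
  conds <- attention_conditions()
  d <- prfs[prfs$condition %in% conds, ]
  d$ecc <- eccentricity(d$x, d$y)
  ok <- tapply(
    d$ecc >= ecc_range[1] & d$ecc <= ecc_range[2] & d$r2 > min_r2 &
      !d$degenerate,
    d$vertex, all)
  as.integer(names(ok))[which(ok)]
}

#' Change in pRF distance to the attended target
#'
#' For each retained vertex and each focal target:
#' `||focal center - target|| - ||distributed center - target||` (Euclidean,
#' degrees); negative values mean the pRF moved toward the attended target.
#' Changes are averaged over vertices within a map and then across the four
#' attention conditions. Vertices are retained only when all five condition
#' models satisfy the eccentricity and variance-explained filters.
#'
#' @param prfs Long pRF table from [fit_prfs_by_condition()] with an added
#'   `map` column (per vertex).
#' @param targets Target table from [default_targets()].
#' @param ecc_range Eccentricity filter applied to every condition model
#'   (default `c(0.5, 5.5)`).
#' @param min_r2 pRF variance-explained filter (default 0.25, strict).
#' @return List of class `shift_summary`: `by_map` data.frame (`map`,
#'   `mean_change`, `n_vertex`), `per_vertex` data.frame of per-vertex
#'   changes (averaged over the four targets) for resampling.
#' @export
distance_change_to_target <- function(prfs, targets = default_targets(),
                                      ecc_range = c(0.5, 5.5),
                                      min_r2 = 0.25) {
  if (!"map" %in% names(prfs)) prfs$map <- "all"
  keep <- shift_filter_vertices(prfs, ecc_range, min_r2)
  if (length(keep) == 0) {
    warning("no vertex passes the shift-analysis filters")
    return(structure(list(
      by_map = data.frame(map = character(0), mean_change = numeric(0),
                          n_vertex = integer(0)),
      per_vertex = data.frame()), class = "shift_summary"))
  }
  d <- prfs[prfs$vertex %in% keep, ]
  dist_cond <- function(cond) {
    dd <- d[d$condition == cond, ]
    dd[order(dd$vertex), c("vertex", "x", "y", "map")]
  }
  distr <- dist_cond("distributed")
  per_target <- lapply(seq_len(nrow(targets)), function(i) {
    foc <- dist_cond(targets$condition[i])
    tx <- targets$x[i]; ty <- targets$y[i]
    sqrt((foc$x - tx)^2 + (foc$y - ty)^2) -
      sqrt((distr$x - tx)^2 + (distr$y - ty)^2)
  })
  change <- rowMeans(do.call(cbind, per_target)) # mean over the 4 targets
  per_vertex <- data.frame(vertex = distr$vertex, map = distr$map,
                           change = change, stringsAsFactors = FALSE)
  by_map <- do.call(rbind, lapply(split(per_vertex, per_vertex$map),
    function(dd) data.frame(map = dd$map[1], mean_change = mean(dd$change),
                            n_vertex = nrow(dd), stringsAsFactors = FALSE)))
  rownames(by_map) <- NULL
  structure(list(by_map = by_map, per_vertex = per_vertex),
            class = "shift_summary")
}

#' GLM-to-shift analysis pipeline
#'
#' The refit stage shared by the true analysis and the shuffled-cue control:
#' fit the GLM to the series with the given schedule, fit per-condition pRF
#' models, attach map labels, and summarize distance changes to the targets.
#'
#' @param series Raw signal matrix (TR x V).
#' @param schedule Trial schedule (possibly with permuted cues).
#' @param ap Aperture set.
#' @param map Per-vertex map labels.
#' @param targets Target table.
#' @param hrf Sampled HRF.
#' @param config pRF fit configuration.
#' @param grid Optional precomputed pRF grid.
#' @param ecc_range,min_r2 Shift-analysis filters.
#' @param nuisance_order GLM nuisance polynomial order.
#' @return A `shift_summary` (with the fitted `prfs` table attached as
#'   attribute `prfs`).
#' @export
prf_shift_pipeline <- function(series, schedule, ap, map,
                               targets = default_targets(),
                               hrf = hrf_double_gamma(),
                               config = prf_fit_config(), grid = NULL,
                               ecc_range = c(0.5, 5.5), min_r2 = 0.25,
                               nuisance_order = 2L) {
  design <- build_design_matrix(schedule)
  glm_fit <- fit_glm(series, design, hrf, nuisance_order = nuisance_order)
  betas <- mapping_beta_array(glm_fit)
  prfs <- fit_prfs_by_condition(betas, ap, config, grid)
  prfs$map <- map[prfs$vertex]
  out <- distance_change_to_target(prfs, targets, ecc_range, min_r2)
  attr(out, "prfs") <- prfs
  out
}

#' Shuffled-cue control analysis
#'
#' Randomly permutes the attention-cue labels across trials, rebuilds the
#' design matrix, refits the GLM and the per-condition pRF models, and
#' recomputes the distance-change summary. Label permutation destroys the
#' cue-locked condition structure, so the control's distance changes should
#' scatter around zero.
#'
#' @inheritParams prf_shift_pipeline
#' @param seed Optional seed for the permutation (the identity permutation
#'   is obtained with `permutation = seq_len(nrow(schedule))`).
#' @param permutation Optional explicit permutation of trial indices.
#' @return A `shift_summary` from the shuffled analysis.
#' @export
shuffled_control <- function(series, schedule, ap, map,
                             targets = default_targets(),
                             hrf = hrf_double_gamma(),
                             config = prf_fit_config(), grid = NULL,
                             ecc_range = c(0.5, 5.5), min_r2 = 0.25,
                             nuisance_order = 2L, seed = NULL,
                             permutation = NULL) {
  perm <- permutation %||%
    with_seed(seed, sample.int(nrow(schedule)))
  shuffled <- schedule
  shuffled$cue <- schedule$cue[perm]
  prf_shift_pipeline(series, shuffled, ap, map, targets, hrf, config, grid,
                     ecc_range, min_r2, nuisance_order)
}

#' Directional vector binning of pRF shifts
#'
#' For a pair of opposed focal conditions (left/right or up/down), bins
#' vertices by the eccentricity and polar angle of their pair-averaged pRF
#' center (eccentricity rings from 0.5 deg in 1-deg steps, 45-deg polar
#' sectors), restricted to eccentricities below the target eccentricity.
#' Reports the mean center under each condition per bin and whether the
#' shift component along the pair's axis is congruent with the attended
#' directions (e.g. attend-left mean x smaller than attend-right mean x).
#'
#' @param prfs Long pRF table from [fit_prfs_by_condition()].
#' @param pair Character pair of opposed conditions, `c("left", "right")`
#'   (x axis) or `c("down", "up")` (y axis).
#' @param ecc_breaks Ring edges, degrees (default `seq(0.5, 6.25, 1)`).
#' @param angle_step_deg Sector width, degrees.
#' @param max_ecc Eccentricity ceiling (default the 6-deg target
#'   eccentricity).
#' @return `data.frame`: ring and sector bounds, per-condition mean centers,
#'   `n`, `congruent` (NA when the paired centers coincide).
#' @export
binned_shift_vectors <- function(prfs, pair = c("left", "right"),
                                 ecc_breaks = seq(0.5, 6.25, by = 1),
                                 angle_step_deg = 45, max_ecc = 6) {
  axis <- if (all(sort(pair) == c("left", "right"))) "x"
          else if (all(sort(pair) == c("down", "up"))) "y"
          else stopf("pair must be left/right or up/down")
  # condition order: pair[1] should be the negative direction on the axis
  neg <- if (axis == "x") "left" else "down"
  pair <- c(neg, setdiff(pair, neg))

  a <- prfs[prfs$condition == pair[1], ]
  b <- prfs[prfs$condition == pair[2], ]
  a <- a[order(a$vertex), ]; b <- b[order(b$vertex), ]
  mx <- (a$x + b$x) / 2; my <- (a$y + b$y) / 2
  ecc <- eccentricity(mx, my); ang <- polar_angle(mx, my)
  keep <- ecc < max_ecc & ecc >= min(ecc_breaks) & ecc <= max(ecc_breaks)
  ring <- findInterval(ecc, ecc_breaks, rightmost.closed = TRUE)
  sector <- floor(ang / angle_step_deg)
  rows <- list()
  for (r in sort(unique(ring[keep]))) for (s in sort(unique(sector[keep]))) {
    sel <- keep & ring == r & sector == s
    if (!any(sel)) next
    m1 <- c(mean(a$x[sel]), mean(a$y[sel]))
    m2 <- c(mean(b$x[sel]), mean(b$y[sel]))
    comp <- if (axis == "x") m2[1] - m1[1] else m2[2] - m1[2]
    rows[[length(rows) + 1]] <- data.frame(
      ring_lo = ecc_breaks[r], ring_hi = ecc_breaks[r + 1],
      sector_lo = s * angle_step_deg, sector_hi = (s + 1) * angle_step_deg,
      n = sum(sel),
      x1 = m1[1], y1 = m1[2], x2 = m2[1], y2 = m2[2],
      shift_component = comp,
      congruent = if (comp == 0) NA else comp > 0)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
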