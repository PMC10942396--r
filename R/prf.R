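# Isotropic 2D-Gaussian pRF model fit to 49-stimulus beta profiles.
#
# Coarse-to-fine search: an exhaustive grid over (x, y, sigma) with the gain
# solved in closed form at each grid point (the model is linear in gain),
# followed by bounded refinement of (x, y, log sigma) from the best grid
# point with the gain profiled out.

#' pRF fit configuration
#'
#' @param xy_step Coarse-grid spacing for the center, degrees.
#' @param sigma_levels Coarse-grid sigma values, degrees (default log-spaced
#'   over 0.25 to 8).
#' @param center_bound Refinement bound: `|x|, |y| <= center_bound` degrees.
#' @param sigma_bounds Refinement bounds on sigma, degrees.
#' @param include_blank Include the blank stimulus (predicted response 0) in
#'   the residual sum of squares. With the blank included, an additive offset
#'   common to all stimuli lands in the residual rather than the gain; with
#'   it excluded, fitted centers are invariant to such offsets.
#' @param refine Run the refinement stage (otherwise return the best grid
#'   point).
#' @return Object of class `prf_fit_config`.
#' @export
prf_fit_config <- function(xy_step = 1,
                           sigma_levels = exp(seq(log(0.25), log(8),
                                                  length.out = 9)),
                           center_bound = 14, sigma_bounds = c(0.1, 12),
                           include_blank = TRUE, refine = TRUE) {
  if (length(sigma_levels) == 0 || any(sigma_levels <= 0))
    stopf("invalid configuration: sigma grid must be non-empty and positive")
  if (sigma_bounds[1] > min(sigma_levels) * (1 + 1e-12) ||
      sigma_bounds[2] < max(sigma_levels))
    stopf("invalid configuration: sigma bounds must contain the sigma grid")
  structure(list(xy_step = xy_step, sigma_levels = sigma_levels,
                 center_bound = center_bound, sigma_bounds = sigma_bounds,
                 include_blank = include_blank, refine = refine),
            class = "prf_fit_config")
}

#' Predict the beta profile of a pRF
#'
#' Per-stimulus prediction: gain times the normalized Gaussian-aperture
#' overlap ([gaussian_aperture_overlap()]). The blank stimulus predicts 0.
#'
#' @param params List or named vector with `x`, `y`, `sigma` (> 0) and `gain`.
#' @param ap Aperture set.
#' @return Numeric vector of 49 predicted responses.
#' @export
predict_beta_profile <- function(params, ap) {
  p <- as.list(params)
  if (p$sigma <= 0) stopf("invalid argument: sigma must be positive")
  p$gain * gaussian_aperture_overlap(ap, p$x, p$y, p$sigma)
}

#' Precompute the coarse-grid predictions
#'
#' Builds the matrix of normalized overlap predictions for every coarse grid
#' point (centers on an `xy_step` grid inside the stimulus window, crossed
#' with the sigma levels). Reusable across vertices and conditions; pass the
#' result to [fit_prf()] via `grid` to avoid rebuilding it.
#'
#' @param ap Aperture set.
#' @param config A [prf_fit_config()].
#' @return Object of class `prf_grid`: data.frame `points` (x, y, sigma) and
#'   matrix `pred` (points x 49).
#' @export
prf_fit_grid <- function(ap, config = prf_fit_config()) {
  R <- ap$window_radius_deg
  cx <- seq(-floor(R), floor(R), by = config$xy_step)
  centers <- expand.grid(x = cx, y = cx)
  centers <- centers[centers$x^2 + centers$y^2 <= R^2, ]
  A <- aperture_matrix(ap)
  n_c <- nrow(centers)
  pts <- list(); preds <- list()
  for (s in config$sigma_levels) {
    gx <- exp(-outer(ap$coords, unique(cx), function(a, b) (a - b)^2) /
                (2 * s^2))
    colnames(gx) <- as.character(unique(cx))
    G <- matrix(0, ap$resolution^2, n_c)
    sums <- numeric(n_c)
    for (i in seq_len(n_c)) {
      gxi <- gx[, as.character(centers$x[i])]
      gyi <- gx[, as.character(centers$y[i])]
      G[, i] <- as.vector(outer(gxi, gyi))
      sums[i] <- sum(gxi) * sum(gyi)
    }
    P <- t(sweep(A %*% G, 2, sums, `/`))
    pts[[length(pts) + 1]] <- data.frame(x = centers$x, y = centers$y,
                                         sigma = s)
    preds[[length(preds) + 1]] <- P
  }
  structure(list(points = do.call(rbind, pts), pred = do.call(rbind, preds),
                 resolution = ap$resolution),
            class = "prf_grid")
}

# profiled-gain residual sum of squares for an observed beta subvector
profiled_rss <- function(pred, b) {
  den <- sum(pred^2)
  if (den == 0) return(list(gain = 0, rss = sum(b^2)))
  gain <- sum(pred * b) / den
  list(gain = gain, rss = sum(b^2) - gain^2 * den)
}

#' Fit the pRF model to a beta profile
#'
#' Coarse-to-fine least squares: exhaustive grid search with closed-form
#' gain, then Nelder-Mead refinement of (x, y, log sigma) with gain profiled
#' out, clamped to the configured bounds. The refined solution is never
#' worse in RSS than the best grid point. `NA` betas (unobserved cells) are
#' ignored. An all-zero profile returns a degenerate fit (r2 `NA`) rather
#' than an error; a constant nonzero profile returns r2 = 0 with the
#' degenerate flag set.
#'
#' @param betas Numeric vector of 49 mapping betas (percent BOLD).
#' @param ap Aperture set.
#' @param config A [prf_fit_config()].
#' @param grid Optional precomputed [prf_fit_grid()].
#' @return List of class `prf_fit`: `x`, `y`, `sigma`, `gain`, `r2`, `rss`,
#'   `degenerate`, `n_obs`.
#' @export
fit_prf <- function(betas, ap, config = prf_fit_config(), grid = NULL) {
  stopifnot(length(betas) == ap$n_apertures)
  if (!all(is.finite(betas) | is.na(betas)))
    stopf("invalid argument: betas must be finite or NA")
  grid <- grid %||% prf_fit_grid(ap, config)
  fit_prf_one(betas, ap, config, grid)
}

fit_prf_one <- function(betas, ap, config, grid) {
  obs <- which(!is.na(betas))
  if (!config$include_blank) obs <- setdiff(obs, ap$blank_index)
  b <- betas[obs]
  tss <- sum((b - mean(b))^2)
  # a profile needs several observed bar stimuli to constrain (x, y, sigma)
  if (length(setdiff(obs, ap$blank_index)) < 3) {
    return(structure(list(x = NA_real_, y = NA_real_, sigma = NA_real_,
                          gain = NA_real_, r2 = NA_real_, rss = NA_real_,
                          degenerate = TRUE, n_obs = length(obs)),
                     class = "prf_fit"))
  }
  if (all(b == 0)) {
    return(structure(list(x = NA_real_, y = NA_real_, sigma = NA_real_,
                          gain = 0, r2 = NA_real_, rss = 0,
                          degenerate = TRUE, n_obs = length(obs)),
                     class = "prf_fit"))
  }

  P <- grid$pred[, obs, drop = FALSE]
  num <- as.vector(P %*% b)
  den <- rowSums(P^2)
  score <- ifelse(den > 0, num^2 / den, 0)
  best <- which.max(score)
  par0 <- c(grid$points$x[best], grid$points$y[best],
            log(grid$points$sigma[best]))
  gain0 <- num[best] / den[best]
  rss0 <- sum(b^2) - score[best]

  x <- par0[1]; y <- par0[2]; sigma <- exp(par0[3]); gain <- gain0; rss <- rss0
  if (config$refine) {
    A <- aperture_matrix(ap)[obs, , drop = FALSE]
    lo <- c(-config$center_bound, -config$center_bound,
            log(config$sigma_bounds[1]))
    hi <- c(config$center_bound, config$center_bound,
            log(config$sigma_bounds[2]))
    objective <- function(par) {
      par <- pmin(pmax(par, lo), hi)
      s <- exp(par[3])
      gx <- exp(-(ap$coords - par[1])^2 / (2 * s^2))
      gy <- exp(-(ap$coords - par[2])^2 / (2 * s^2))
      pred <- as.vector(A %*% as.vector(outer(gx, gy))) / (sum(gx) * sum(gy))
      out <- profiled_rss(pred, b)$rss
      if (!is.finite(out)) out <- sum(b^2) + 1
      out
    }
    opt <- tryCatch(
      stats::optim(par0, objective, method = "Nelder-Mead",
                   control = list(maxit = 400, reltol = 1e-10)),
      error = function(e) list(value = Inf, par = par0))
    if (opt$value <= rss0) {
      par <- pmin(pmax(opt$par, lo), hi)
      x <- par[1]; y <- par[2]; sigma <- exp(par[3])
      gx <- exp(-(ap$coords - x)^2 / (2 * sigma^2))
      gy <- exp(-(ap$coords - y)^2 / (2 * sigma^2))
      pred <- as.vector(A %*% as.vector(outer(gx, gy))) / (sum(gx) * sum(gy))
      pr <- profiled_rss(pred, b)
      gain <- pr$gain; rss <- pr$rss
    }
  }
  degenerate <- tss == 0
  r2 <- if (degenerate) 0 else 1 - rss / tss
  structure(list(x = x, y = y, sigma = sigma, gain = gain, r2 = r2,
                 rss = rss, degenerate = degenerate, n_obs = length(obs)),
            class = "prf_fit")
}

#' @export
print.prf_fit <- function(x, ...) {
  cat(sprintf("prf_fit: center (%.3f, %.3f) deg, sigma %.3f deg, gain %.3f, r2 %.3f\n",
              x$x, x$y, x$sigma, x$gain, x$r2))
  invisible(x)
}

#' Fit pRF models per attention condition
#'
#' Six independent fits per vertex: one per attention condition plus one to
#' the stimulus-wise mean of the five condition profiles ("average").
#'
#' @param beta_array Array 49 x 5 x V (or a 49 x 5 matrix for one vertex)
#'   with condition dimnames matching [attention_conditions()].
#' @param ap Aperture set.
#' @param config A [prf_fit_config()].
#' @param grid Optional precomputed grid.
#' @return `data.frame`: `vertex`, `condition` (5 conditions + "average"),
#'   `x`, `y`, `sigma`, `gain`, `r2`, `degenerate`.
#' @export
fit_prfs_by_condition <- function(beta_array, ap, config = prf_fit_config(),
                                  grid = NULL) {
  if (length(dim(beta_array)) == 2) dim(beta_array) <- c(dim(beta_array), 1)
  if (dim(beta_array)[2] != 5)
    stopf("invalid input: all five condition profiles are required")
  grid <- grid %||% prf_fit_grid(ap, config)
  V <- dim(beta_array)[3]
  rows <- vector("list", V * 6)
  k <- 0
  for (v in seq_len(V)) {
    profiles <- cbind(beta_array[, , v],
                      average = rowMeans(beta_array[, , v], na.rm = TRUE))
    profiles[is.nan(profiles)] <- NA_real_
    colnames(profiles) <- c(attention_conditions(), "average")
    for (cond in colnames(profiles)) {
      f <- fit_prf_one(profiles[, cond], ap, config, grid)
      k <- k + 1
      rows[[k]] <- data.frame(vertex = v, condition = cond, x = f$x, y = f$y,
                              sigma = f$sigma, gain = f$gain, r2 = f$r2,
                              degenerate = f$degenerate,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Linear size-eccentricity fits per map
#'
#' Ordinary least squares of pRF size on eccentricity within each visual
#' field map; the expected positive slope is a standard check of pRF fit
#' quality.
#'
#' @param prfs `data.frame` with columns `map`, `x`, `y`, `sigma` (or a
#'   precomputed `ecc` column).
#' @return `data.frame`: `map`, `intercept`, `slope`, `n`; maps with fewer
#'   than 2 distinct eccentricities are flagged with `NA` coefficients.
#' @export
fit_size_eccentricity <- function(prfs) {
  if (!"ecc" %in% names(prfs)) prfs$ecc <- eccentricity(prfs$x, prfs$y)
  out <- lapply(split(prfs, prfs$map), function(d) {
    if (length(unique(round(d$ecc, 10))) < 2)
      return(data.frame(map = d$map[1], intercept = NA_real_,
                        slope = NA_real_, n = nrow(d)))
    co <- stats::coef(stats::lm(sigma ~ ecc, data = d))
    data.frame(map = d$map[1], intercept = unname(co[1]),
               slope = unname(co[2]), n = nrow(d))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
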