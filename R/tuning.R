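# Spatial profile of anticipatory amplitude modulation: 2D visual-field
# projections, polar-angle tuning curves, difference-of-von-Mises fits, and
# the attentional spread (distance between the enhancement-to-suppression
# transition points).

#' Per-vertex attentional modulation
#'
#' Change in BOLD amplitude from distributed to focal attention: mean over
#' the 49 mapping stimuli of (focal beta - distributed beta) per vertex.
#'
#' @param beta_array 49 x 5 x V mapping betas (percent BOLD).
#' @param focal_condition One of the four focal conditions.
#' @return Numeric vector, one modulation value (percent BOLD) per vertex.
#' @export
vertex_modulation <- function(beta_array, focal_condition) {
  if (!focal_condition %in% focal_conditions())
    stopf("invalid argument: unknown focal condition '%s'", focal_condition)
  diff <- beta_array[, focal_condition, , drop = FALSE] -
    beta_array[, "distributed", , drop = FALSE]
  apply(diff, 3, mean, na.rm = TRUE)
}

#' 2D visual-field map of attentional modulation
#'
#' Places each vertex's modulation at its average-condition pRF center,
#' optionally rotates the field by `90 - target angle` degrees so the
#' attended meridian aligns with the upper vertical meridian, and resamples
#' the scattered points onto a square grid: cell-mean binning at `bin_deg`
#' followed by bilinear interpolation to `grid_deg` (empty interior cells
#' are filled from their nearest populated cell first).
#'
#' @param modulation Per-vertex modulation values.
#' @param prfs Average-condition pRF table with `x`, `y` per vertex (same
#'   order as `modulation`).
#' @param rotate_to_up_from Target polar angle (degrees) to rotate to the
#'   upper vertical meridian, or `NULL` for no rotation.
#' @param extent_deg Half-width of the output grid, degrees.
#' @param bin_deg Binning cell size, degrees.
#' @param grid_deg Output grid spacing, degrees.
#' @return List: `points` (x, y, value after rotation), `grid_x`, `grid_y`,
#'   `grid` (matrix, rows = x, cols = y).
#' @export
modulation_2d_map <- function(modulation, prfs, rotate_to_up_from = NULL,
                              extent_deg = 12.4, bin_deg = 1,
                              grid_deg = 0.25) {
  x <- prfs$x; y <- prfs$y
  if (!is.null(rotate_to_up_from)) {
    th <- deg2rad(90 - rotate_to_up_from)
    xr <- x * cos(th) - y * sin(th)
    yr <- x * sin(th) + y * cos(th)
    x <- xr; y <- yr
  }
  keep <- is.finite(x) & is.finite(y) & is.finite(modulation)
  x <- x[keep]; y <- y[keep]; v <- modulation[keep]
  if (length(unique(paste(round(x, 6), round(y, 6)))) < 3)
    stopf("interpolation error: need at least 3 distinct vertex positions")

  edges <- seq(-extent_deg, extent_deg, by = bin_deg)
  centers <- edges[-1] - bin_deg / 2
  ix <- findInterval(x, edges, all.inside = TRUE)
  iy <- findInterval(y, edges, all.inside = TRUE)
  nb <- length(centers)
  sums <- matrix(0, nb, nb); counts <- matrix(0, nb, nb)
  for (i in seq_along(v)) {
    sums[ix[i], iy[i]] <- sums[ix[i], iy[i]] + v[i]
    counts[ix[i], iy[i]] <- counts[ix[i], iy[i]] + 1
  }
  coarse <- ifelse(counts > 0, sums / pmax(counts, 1), NA_real_)
  # nearest-populated-cell fill so bilinear interpolation has full support
  if (anyNA(coarse) && any(!is.na(coarse))) {
    filled <- which(!is.na(coarse), arr.ind = TRUE)
    empty <- which(is.na(coarse), arr.ind = TRUE)
    for (k in seq_len(nrow(empty))) {
      d2 <- (filled[, 1] - empty[k, 1])^2 + (filled[, 2] - empty[k, 2])^2
      j <- which.min(d2)
      coarse[empty[k, 1], empty[k, 2]] <- coarse[filled[j, 1], filled[j, 2]]
    }
  }
  out_ax <- seq(-extent_deg + bin_deg / 2, extent_deg - bin_deg / 2,
                by = grid_deg)
  # interp2 expects z indexed [y, x] with ascending axes
  fine <- pracma::interp2(centers, centers, t(coarse),
                          rep(out_ax, times = length(out_ax)),
                          rep(out_ax, each = length(out_ax)),
                          method = "linear")
  grid <- matrix(fine, nrow = length(out_ax)) # rows = x, cols = y
  list(points = data.frame(x = x, y = y, value = v),
       grid_x = out_ax, grid_y = out_ax, grid = grid)
}

#' Polar-angle tuning curve of attentional modulation
#'
#' Bins vertices by their polar-angle distance from the attended target in
#' 20-degree steps over (-180, 180], restricted to vertices with preferred
#' eccentricity in the configured band and GLM variance explained above
#' threshold. The bin value is the mean modulation (focal minus distributed,
#' averaged over the 49 stimuli); the bin center is the mean polar distance
#' of the member vertices. Empty bins are omitted.
#'
#' @param modulation Per-vertex modulation values.
#' @param prfs Average-condition pRF table with `x`, `y`, `glm_r2`.
#' @param target_angle_deg Polar angle of the attended target.
#' @param bin_width_deg Bin width, degrees (default 20).
#' @param ecc_band Eccentricity filter (default `c(4, 8)`).
#' @param min_glm_r2 GLM variance-explained filter (default 0.05, strict).
#' @return `data.frame` of class `tuning_curve`: `center_deg`, `value`, `n`.
#' @export
polar_tuning_curve <- function(modulation, prfs, target_angle_deg,
                               bin_width_deg = 20, ecc_band = c(4, 8),
                               min_glm_r2 = 0.05) {
  ecc <- eccentricity(prfs$x, prfs$y)
  keep <- ecc >= ecc_band[1] & ecc <= ecc_band[2] &
    prfs$glm_r2 > min_glm_r2 & is.finite(modulation)
  dth <- polar_angle_distance(polar_angle(prfs$x, prfs$y), target_angle_deg)
  dth <- dth[keep]; v <- modulation[keep]
  if (length(dth) == 0) {
    out <- data.frame(center_deg = numeric(0), value = numeric(0),
                      n = integer(0))
    class(out) <- c("tuning_curve", class(out))
    return(out)
  }
  edges <- seq(-180, 180, by = bin_width_deg)
  bin <- findInterval(dth, edges, rightmost.closed = TRUE, left.open = TRUE)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(bi) {
    sel <- bin == bi
    data.frame(center_deg = mean(dth[sel]), value = mean(v[sel]),
               n = sum(sel))
  }))
  class(out) <- c("tuning_curve", class(out))
  out
}

#' Average tuning curves across targets
#'
#' Bin-wise combination of several tuning curves (one per target location):
#' vertex-count-weighted means of both the bin centers and values, keyed by
#' bin ordinal position along the polar-distance axis.
#'
#' @param curves List of `tuning_curve` data.frames.
#' @param bin_width_deg Bin width used to construct the curves.
#' @return A single `tuning_curve` data.frame.
#' @export
average_tuning_curves <- function(curves, bin_width_deg = 20) {
  all <- do.call(rbind, lapply(curves, function(cu) {
    cu <- as.data.frame(cu)
    if (nrow(cu) == 0) return(NULL)
    cu$bin <- floor((cu$center_deg + 180) / bin_width_deg)
    cu
  }))
  if (is.null(all) || nrow(all) == 0) {
    out <- data.frame(center_deg = numeric(0), value = numeric(0),
                      n = integer(0))
    class(out) <- c("tuning_curve", class(out))
    return(out)
  }
  out <- do.call(rbind, lapply(split(all, all$bin), function(d)
    data.frame(center_deg = stats::weighted.mean(d$center_deg, d$n),
               value = stats::weighted.mean(d$value, d$n), n = sum(d$n))))
  out <- out[order(out$center_deg), ]
  rownames(out) <- NULL
  class(out) <- c("tuning_curve", class(out))
  out
}

#' Fit a difference of two von Mises functions to a tuning curve
#'
#' Nonlinear least squares of
#' `y(x) = V(x; mu, kappa1) - V(x; mu, kappa2) + B` with
#' `V(x; mu, kappa) = S exp(kappa cos(x - mu)) / (2 pi I0(kappa))`
#' (single shared scalar S; degrees mapped linearly to radians). Fitting
#' uses Levenberg-Marquardt with a multi-start grid over (mu, kappa1,
#' kappa2); concentrations are optimized on the log scale to stay positive.
#' The best start by RSS wins.
#'
#' @param curve A `tuning_curve` data.frame (>= 6 populated bins).
#' @param mu_starts,kappa1_starts,kappa2_starts Multi-start grids.
#' @return List of class `von_mises_fit`: `S`, `B`, `mu` (degrees),
#'   `kappa1`, `kappa2`, `rss`, `converged`.
#' @export
fit_diff_von_mises <- function(curve,
                               mu_starts = c(-20, 0, 20),
                               kappa1_starts = c(2, 6, 12),
                               kappa2_starts = c(0.3, 1, 3)) {
  if (nrow(curve) < 6)
    stopf("need at least 6 populated bins to fit the tuning curve")
  x <- curve$center_deg; yv <- curve$value
  resid_fn <- function(p) {
    dvm_value(x, list(S = p[1], B = p[2], mu = p[3],
                      kappa1 = exp(p[4]), kappa2 = exp(p[5]))) - yv
  }
  S0 <- diff(range(yv))
  if (S0 == 0) S0 <- 1e-6
  B0 <- min(yv)
  best <- NULL
  for (mu0 in mu_starts) for (k10 in kappa1_starts) for (k20 in kappa2_starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(S0, B0, mu0, log(k10), log(k20)),
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = fit$par, rss = rss, info = fit$info)
  }
  if (is.null(best))
    stopf("difference-of-von-Mises fit failed to converge from all starts")
  p <- best$par
  structure(list(S = p[1], B = p[2], mu = p[3],
                 kappa1 = exp(p[4]), kappa2 = exp(p[5]),
                 rss = best$rss, converged = best$info %in% 1:4),
            class = "von_mises_fit")
}

#' Attentional spread from a fitted tuning curve
#'
#' Solves `f(x) = 0` by bracketing root search on `[-60, 0]` and `[0, 60]`
#' degrees — the transition points from enhancement (f > 0) to suppression
#' (f < 0) — and reports their distance (the spread), the peak enhancement,
#' the trough suppression, and the absolute modulation (peak minus trough,
#' exactly). Brackets without a sign change leave the corresponding
#' intercept `NA` and the width undefined.
#'
#' @param params A `von_mises_fit` (or compatible parameter list).
#' @param bracket Half-width of the root brackets, degrees.
#' @return List of class `spread_estimate`: `left`, `right`, `width`,
#'   `peak`, `trough`, `absolute`.
#' @export
attentional_spread <- function(params, bracket = 60) {
  f <- function(x) dvm_value(x, params[c("S", "B", "mu", "kappa1", "kappa2")])
  root_in <- function(lo, hi) {
    if (sign(f(lo)) * sign(f(hi)) > 0) return(NA_real_)
    stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
  }
  left <- root_in(-bracket, 0)
  right <- root_in(0, bracket)
  width <- if (is.na(left) || is.na(right)) NA_real_ else right - left
  xs <- seq(-180, 180, by = 0.1)
  fx <- f(xs)
  peak_x <- xs[which.max(fx)]
  trough_x <- xs[which.min(fx)]
  peak <- stats::optimize(f, c(max(-180, peak_x - 1), min(180, peak_x + 1)),
                          maximum = TRUE)$objective
  trough <- stats::optimize(f, c(max(-180, trough_x - 1),
                                 min(180, trough_x + 1)))$objective
  structure(list(left = left, right = right, width = width,
                 peak = peak, trough = trough, absolute = peak - trough),
            class = "spread_estimate")
}
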