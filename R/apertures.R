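# Bar apertures for event-related pRF mapping.
#
# The mapping stimulus is a contrast texture windowed by a bar aperture 3 deg
# wide, shown at one of 24 positions per orientation (vertical or horizontal)
# inside a circular window of radius 12.4 deg. Adjacent same-orientation bars
# step by 1 deg, so neighbours overlap in a 2-deg band. Only the binarized
# aperture matters to the pRF model; the texture itself is never rendered.

#' Build the bar-aperture set
#'
#' Constructs the 49 binary apertures (24 vertical bars, 24 horizontal bars,
#' 1 blank) on a square pixel grid spanning
#' `[-window_radius_deg, +window_radius_deg]^2`. A pixel is lit when its
#' center lies inside both the bar strip and the circular window (no
#' anti-aliasing, so masks are bit-reproducible).
#'
#' Bar centers are equally spaced by `step_deg` and symmetric about zero; with
#' the default geometry the offsets are -11.5, -10.5, ..., +11.5 deg. Aperture
#' order: indices 1..24 are vertical bars sweeping left to right, 25..48 are
#' horizontal bars sweeping bottom to top, 49 is the blank (all-zero) mask.
#'
#' @param width_deg Bar width in degrees (default 3).
#' @param step_deg Step between adjacent bar centers in degrees (default 1).
#' @param window_radius_deg Radius of the circular stimulus window (default 12.4).
#' @param resolution Pixels per side of the square grid (default 128; use a
#'   finer grid, e.g. 512, when measuring sub-degree geometric properties).
#' @return An object of class `aperture_set`: list with `masks`
#'   (`resolution x resolution x 49` array, first index = x, second = y with y
#'   increasing upward), `coords` (pixel-center coordinates along one axis),
#'   `orientation`, `bar_offset`, and the geometry parameters.
#' @export
build_bar_apertures <- function(width_deg = 3, step_deg = 1,
                                window_radius_deg = 12.4, resolution = 128L) {
  if (width_deg <= 0 || step_deg <= 0 || window_radius_deg <= 0)
    stopf("invalid configuration: geometry parameters must be positive")
  resolution <- as.integer(resolution)
  if (resolution < 32L)
    stopf("invalid configuration: resolution must be at least 32 pixels")

  # number of positions per orientation: outermost bar must reach the window
  # edge; symmetric about 0 with spacing step_deg
  half_n <- ceiling((window_radius_deg - width_deg / 2) / step_deg + 0.5)
  n_pos <- 2L * as.integer(half_n)
  offsets <- (seq_len(n_pos) - (n_pos + 1) / 2) * step_deg

  R <- window_radius_deg
  px <- 2 * R / resolution
  coords <- -R + (seq_len(resolution) - 0.5) * px
  in_circle <- outer(coords^2, coords^2, `+`) <= R^2

  n_ap <- 2L * n_pos + 1L
  masks <- array(0, dim = c(resolution, resolution, n_ap))
  for (i in seq_len(n_pos)) {
    strip <- abs(coords - offsets[i]) <= width_deg / 2
    masks[, , i] <- in_circle * strip            # vertical: condition on x (rows)
    masks[, , n_pos + i] <- in_circle * rep(strip, each = resolution) # horizontal: on y
  }
  structure(list(
    masks = masks,
    coords = coords,
    orientation = c(rep("vertical", n_pos), rep("horizontal", n_pos), "blank"),
    bar_offset = c(offsets, offsets, NA_real_),
    width_deg = width_deg, step_deg = step_deg,
    window_radius_deg = window_radius_deg, resolution = resolution,
    n_apertures = n_ap, blank_index = n_ap
  ), class = "aperture_set")
}

#' @export
print.aperture_set <- function(x, ...) {
  cat(sprintf(
    "aperture_set: %d apertures (%d vertical + %d horizontal bars + blank)\n",
    x$n_apertures, sum(x$orientation == "vertical"),
    sum(x$orientation == "horizontal")))
  cat(sprintf("  bar width %.3g deg, step %.3g deg, window radius %.3g deg, %d px\n",
              x$width_deg, x$step_deg, x$window_radius_deg, x$resolution))
  invisible(x)
}

# apertures as a (n_apertures x n_pixels) matrix for fast overlap computation
aperture_matrix <- function(ap) {
  t(matrix(ap$masks, nrow = ap$resolution^2))
}

#' Gaussian-aperture overlap
#'
#' Overlap between an isotropic 2D Gaussian and each binary aperture:
#' the sum over lit pixels of the unit-peak Gaussian, normalized by the
#' Gaussian's total pixel sum. This makes the quantity a fraction of Gaussian
#' mass inside the aperture, independent of grid resolution, so a vertex gain
#' expressed in percent BOLD is comparable across maps and grids.
#'
#' @param ap An `aperture_set`.
#' @param x0,y0 Gaussian center in degrees.
#' @param sigma Gaussian standard deviation in degrees (> 0).
#' @return Numeric vector, one overlap value in `[0, 1]` per aperture
#'   (0 for the blank).
#' @export
gaussian_aperture_overlap <- function(ap, x0, y0, sigma) {
  if (sigma <= 0) stopf("invalid argument: sigma must be positive")
  gx <- exp(-(ap$coords - x0)^2 / (2 * sigma^2))
  gy <- exp(-(ap$coords - y0)^2 / (2 * sigma^2))
  g <- as.vector(outer(gx, gy))
  as.vector(aperture_matrix(ap) %*% g) / sum(g)
}

# which bar apertures contain a given visual-field point (pixel membership)
bars_overlapping_point <- function(ap, x, y) {
  ix <- which.min(abs(ap$coords - x))
  iy <- which.min(abs(ap$coords - y))
  which(ap$masks[ix, iy, ] > 0)
}
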