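# Cortical target ROIs: wedge-shaped selections of vertices representing the
# four target locations, plus polar-coordinate utilities. Convention
# throughout: polar angle 0 = right horizontal meridian, counterclockwise
# positive, 90 = upper vertical meridian.

#' Wrap-aware signed polar-angle difference
#'
#' Signed difference `a - b` wrapped into `(-180, 180]` degrees.
#'
#' @param a,b Angles in degrees (any range).
#' @return Signed distance in degrees, vectorized.
#' @export
polar_angle_distance <- function(a, b) {
  d <- (a - b + 180) %% 360 - 180
  ifelse(d == -180, 180, d)
}

#' Wedge ROI specification
#'
#' Vertices represent a target when their average-condition pRF has an
#' eccentricity inside the band, a polar angle within the half-width of the
#' target's meridian, and sufficient GLM variance explained. Defaults match
#' the protocol's wedge definition: eccentricity 4-8 deg (targets at 6 deg),
#' +/-30 deg around each cardinal meridian, GLM variance explained > 0.05.
#' Interval bounds are closed; the variance-explained threshold is strict.
#'
#' @param ecc_band Eccentricity band `[low, high]` in degrees.
#' @param half_width_deg Angular half-width, degrees (in `(0, 90]`).
#' @param min_glm_r2 Minimum GLM variance explained (exclusive).
#' @return Object of class `wedge_roi_spec`.
#' @export
wedge_roi_spec <- function(ecc_band = c(4, 8), half_width_deg = 30,
                           min_glm_r2 = 0.05) {
  if (half_width_deg <= 0 || half_width_deg > 90)
    stopf("invalid configuration: half-width must be in (0, 90]")
  if (ecc_band[1] >= ecc_band[2])
    stopf("invalid configuration: eccentricity band must have low < high")
  structure(list(ecc_band = ecc_band, half_width_deg = half_width_deg,
                 min_glm_r2 = min_glm_r2), class = "wedge_roi_spec")
}

#' Select a wedge ROI of vertices
#'
#' @param prfs `data.frame` of average-condition pRF solutions with columns
#'   `vertex`, `x`, `y`, and `glm_r2` (GLM variance explained).
#' @param target_angle_deg Polar angle of the target meridian (90 = up,
#'   270 = down, 180 = left, 0 = right).
#' @param spec A [wedge_roi_spec()].
#' @return Integer vector of vertex ids inside the wedge (empty, with a
#'   warning, when nothing qualifies).
#' @export
select_wedge_roi <- function(prfs, target_angle_deg,
                             spec = wedge_roi_spec()) {
  ecc <- eccentricity(prfs$x, prfs$y)
  ang <- polar_angle(prfs$x, prfs$y)
  keep <- ecc >= spec$ecc_band[1] & ecc <= spec$ecc_band[2] &
    abs(polar_angle_distance(ang, target_angle_deg)) <= spec$half_width_deg &
    prfs$glm_r2 > spec$min_glm_r2
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) warning("empty wedge ROI for target at ",
                          target_angle_deg, " deg")
  prfs$vertex[keep]
}
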