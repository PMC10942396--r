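# Shared geometry helpers. Polar convention, fixed package-wide:
# 0 deg = right horizontal meridian, counterclockwise positive, 90 deg = up.

#' Eccentricity of a visual-field position
#'
#' @param x,y Position in degrees of visual angle.
#' @return Distance from fixation in degrees.
#' @export
eccentricity <- function(x, y) sqrt(x^2 + y^2)

#' Polar angle of a visual-field position
#'
#' @param x,y Position in degrees of visual angle.
#' @return Angle in degrees in `[0, 360)`, 0 = right, counterclockwise.
#' @export
polar_angle <- function(x, y) {
  a <- atan2(y, x) * 180 / pi
  (a + 360) %% 360
}

deg2rad <- function(x) x * pi / 180

#' Standard attention conditions
#'
#' The five cue conditions in canonical order: four focal cues followed by the
#' distributed (neutral) cue.
#' @return Character vector of length 5.
#' @export
attention_conditions <- function() c("up", "down", "left", "right", "distributed")

focal_conditions <- function() c("up", "down", "left", "right")

#' Visual field map labels
#' @return Character vector of the six retinotopic maps modeled.
#' @export
map_labels <- function() c("V1", "V2", "V3", "hV4", "V3A/B", "LO1")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# local RNG seeding that restores the caller's RNG state on exit
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
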