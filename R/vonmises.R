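# Difference-of-von-Mises profile, shared by the synthetic-data generator
# (wedge-shaped additive baseline modulation) and the tuning-curve fits.
#
# f(x) = S * exp(k1*cos(x - mu)) / (2*pi*I0(k1))
#      - S * exp(k2*cos(x - mu)) / (2*pi*I0(k2)) + B
#
# x and mu are polar-angle distances in degrees on [-180, 180], mapped
# linearly to radians on [-pi, pi] so the von Mises period matches the polar
# circle. A single scalar S is shared between the two terms; with k1 > k2 and
# S > 0 the profile is positive near 0 (enhancement at the attended location)
# and negative far from it (suppression), when B = 0.

von_mises_term <- function(x_deg, mu_deg, kappa) {
  exp(kappa * cos(deg2rad(x_deg - mu_deg))) / (2 * pi * besselI(kappa, 0))
}

#' Evaluate a difference-of-von-Mises tuning profile
#'
#' @param x_deg Polar-angle distance(s) from the attended target, degrees.
#' @param params List or named vector with `S`, `B`, `mu` (degrees), `kappa1`,
#'   `kappa2` (both > 0).
#' @return Profile value(s), in the units of `S` and `B` (percent BOLD for
#'   amplitude-modulation curves).
#' @export
dvm_value <- function(x_deg, params) {
  p <- as.list(params)
  if (p$kappa1 <= 0 || p$kappa2 <= 0)
    stopf("invalid argument: von Mises concentrations must be positive")
  p$S * (von_mises_term(x_deg, p$mu, p$kappa1) -
           von_mises_term(x_deg, p$mu, p$kappa2)) + p$B
}

# scalar S that makes the profile peak (value at x = mu) equal `peak`
dvm_scale_for_peak <- function(peak, B = 0, kappa1 = 6, kappa2 = 1) {
  h0 <- exp(kappa1) / (2 * pi * besselI(kappa1, 0)) -
    exp(kappa2) / (2 * pi * besselI(kappa2, 0))
  (peak - B) / h0
}
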