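#' Difference-of-Gaussians stimulus luminance profile
#'
#' Luminance profile of the low-spatial-frequency patch used to open-loop
#' (diminish) the blur cue:
#' \deqn{S(x) = 3 e^{-x^2/\sigma^2} - 2 e^{-x^2/2.25\sigma^2} + K}
#' where `sigma` is the space constant and `K` the mean luminance. A target
#' built from this profile carries too little high-spatial-frequency energy
#' to drive blur-mediated accommodation, while still providing a fusible
#' luminance blob for disparity and proximity cues.
#'
#' @param x Stimulus position(s), in the same spatial units as `sigma`.
#' @param sigma Space constant; must be > 0.
#' @param k Mean luminance offset (normalized luminance units). Default 0.
#' @return Luminance value(s), same length as `x`.
#' @examples
#' dog_stimulus_profile(0, sigma = 1)       # 3 - 2 + 0 = 1
#' dog_stimulus_profile(c(-2, 0, 2), sigma = 1.5, k = 0.5)
#' @export
dog_stimulus_profile <- function(x, sigma, k = 0) {
  assert_scalar_num(sigma, "sigma", positive = TRUE)
  assert_scalar_num(k, "k")
  if (!is.numeric(x)) stopf("`x` must be numeric")
  3 * exp(-x^2 / sigma^2) - 2 * exp(-x^2 / (2.25 * sigma^2)) + k
}

#' Accommodative demand of a target at a given distance
#'
#' Demand in diopters is the reciprocal of the viewing distance in meters:
#' a target at 40 cm demands 2.5 D, one at 1 m demands 1 D, so stepping
#' between them stimulates a 1.5 D accommodative change.
#'
#' @param d Viewing distance(s) in meters; all must be > 0.
#' @return Demand(s) in diopters.
#' @examples
#' demand_from_distance(0.40)  # 2.5 D
#' demand_from_distance(1.00)  # 1.0 D
#' @export
demand_from_distance <- function(d) {
  if (!is.numeric(d) || length(d) == 0L || anyNA(d))
    stopf("`d` must be numeric and non-missing")
  if (any(d <= 0)) stopf("viewing distance must be > 0 m (got %g)", min(d))
  1 / d
}
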