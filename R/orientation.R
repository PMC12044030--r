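#' Orientation-space geometry
#'
#' Bar tilts live in a 180-degree-periodic ("orientation") space: a bar
#' tilted at +95 degrees is the same bar as one at -85 degrees. All angular
#' arithmetic in the package therefore wraps differences into (-90, 90] and
#' absolute errors into [0, 90]; the chance level for the mean absolute
#' error of random reports is 45 degrees.
#'
#' `wrap_orientation()` maps any angle to the canonical interval (-90, 90].
#' `orientation_diff()` gives the signed acute difference `a - b` (positive
#' when `a` is anticlockwise of `b`). `orientation_error()` is its absolute
#' value, the reproduction error between a reported and a target tilt.
#'
#' @param theta,a,b,reported,target Angles in degrees; any finite value is
#'   accepted and wrapped.
#' @return Degrees: `wrap_orientation()` and `orientation_diff()` in
#'   (-90, 90], `orientation_error()` in [0, 90].
#' @examples
#' orientation_error(-80, 80)   # 20, not 160
#' orientation_diff(10, 350)    # 20
#' @name orientation-space
NULL

#' @rdname orientation-space
#' @export
wrap_orientation <- function(theta) {
  stopifnot(is.numeric(theta))
  out <- theta - 180 * round(theta / 180)
  # round() sends exactly -90 to -90; use the (-90, 90] convention
  out[out == -90] <- 90
  out
}

#' @rdname orientation-space
#' @export
orientation_diff <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || anyNA(a) || anyNA(b)) {
    abort("`a` and `b` must be finite numeric angles.")
  }
  wrap_orientation(a - b)
}

#' @rdname orientation-space
#' @export
orientation_error <- function(reported, target) {
  abs(orientation_diff(reported, target))
}
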