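#' Wrap angles into the canonical (-180, 180] degree range
#'
#' @param x numeric vector of angles in degrees.
#' @return angles mapped into (-180, 180]; `NA` passes through.
#' @examples
#' wrap_angle(c(190, -180, 360, 180))
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * ceiling((x - 180) / 360)
  # ceiling() maps exact -180 to -180; the convention here is (-180, 180]
  w[!is.na(w) & w <= -180] <- w[!is.na(w) & w <= -180] + 360
  w
}

#' Minimal signed angular difference
#'
#' Difference `a - b` measured along the shorter arc, in degrees, so that
#' e.g. `angular_diff(179, -179)` is `-2`, not `358`.
#'
#' @param a,b numeric vectors of angles in degrees.
#' @return signed differences in (-180, 180].
#' @export
angular_diff <- function(a, b) {
  wrap_angle(a - b)
}
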