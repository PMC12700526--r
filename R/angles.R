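#' Angle utilities
#'
#' Workspace angles are measured in degrees, 0 pointing along +x (the
#' "3 o'clock" direction), counter-clockwise positive, and wrapped to
#' (-180, 180].
#'
#' @param a numeric vector of angles in degrees.
#' @return `wrap_deg()` returns angles wrapped to (-180, 180].
#' @examples
#' wrap_deg(c(190, -180, 540))
#' @export
wrap_deg <- function(a) {
  r <- (a + 180) %% 360 - 180
  r[r == -180] <- 180
  r
}

deg2rad <- function(a) a * pi / 180
rad2deg <- function(a) a * 180 / pi

#' Unit vector for a workspace angle
#'
#' @param a angle in degrees (0 = +x, CCW positive).
#' @return length-2 numeric (x, y) unit vector.
#' @export
unit_deg <- function(a) c(cos(deg2rad(a)), sin(deg2rad(a)))

#' Signed angle between two vectors
#'
#' Signed angle, in degrees, rotating `from` onto `to`; CCW positive.
#'
#' @param from,to length-2 numeric vectors.
#' @return angle in degrees in (-180, 180].
#' @export
signed_angle_deg <- function(from, to) {
  wrap_deg(rad2deg(atan2(
    from[1] * to[2] - from[2] * to[1],
    from[1] * to[1] + from[2] * to[2]
  )))
}

#' Direction of a vector in workspace degrees
#'
#' @param v length-2 numeric vector (or 2-column matrix).
#' @return angle(s) in degrees in (-180, 180].
#' @export
vec_angle_deg <- function(v) {
  if (is.matrix(v)) wrap_deg(rad2deg(atan2(v[, 2], v[, 1])))
  else wrap_deg(rad2deg(atan2(v[2], v[1])))
}
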