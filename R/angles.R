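# Angle conventions used throughout:
#   * arena coordinates: x east, y north, origin at the platform center
#     (= nest tube exit), units cm
#   * azimuths: degrees clockwise from +y (north), in [0, 360)
#   * the same clockwise-positive sign is used for magnetic declination and
#     for the field/goal alteration angle theta, so one parameter drives both
#     the coil geometry and the fictive-nest rotation

deg2rad <- function(d) d * pi / 180

rad2deg <- function(r) r * 180 / pi

#' Wrap angles to [0, 360)
#'
#' @param deg numeric vector of angles in degrees.
#' @return angles reduced modulo 360 into `[0, 360)`.
#' @export
wrap360 <- function(deg) deg %% 360

#' Signed circular difference
#'
#' Wraps angles (or angle differences) into `(-180, 180]`.
#'
#' @param deg numeric vector of angles in degrees.
#' @return signed representative in `(-180, 180]`.
#' @export
wrap180 <- function(deg) {
  w <- ((deg + 180) %% 360) - 180
  # map -180 to +180 so the interval is (-180, 180]
  w[w == -180] <- 180
  w
}

#' Absolute circular distance between two angles
#'
#' @param a,b angles in degrees (recycled).
#' @return absolute angular separation in `[0, 180]`.
#' @export
circ_dist <- function(a, b) abs(wrap180(a - b))

# azimuth (deg, clockwise from +y/north) of displacement (dx, dy)
azimuth_deg <- function(dx, dy) unname(wrap360(rad2deg(atan2(dx, dy))))

# clockwise (eastward, viewed from above) rotation of arena vectors.
# xy: length-2 vector or n x 2 matrix; returns same shape.
rotate_cw <- function(xy, theta_deg) {
  th <- deg2rad(theta_deg)
  co <- cos(th); si <- sin(th)
  if (is.matrix(xy)) {
    cbind(xy[, 1] * co + xy[, 2] * si, -xy[, 1] * si + xy[, 2] * co)
  } else {
    c(xy[1] * co + xy[2] * si, -xy[1] * si + xy[2] * co)
  }
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  invisible(x)
}
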