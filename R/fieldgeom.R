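# Magnetic field vector algebra for Helmholtz-coil alteration experiments.
#
# Field frame (magnetometer display convention):
#   x = horizontal component toward magnetic north (uT)
#   y = horizontal component toward magnetic east  (uT)
#   z = vertical component, positive downward      (uT)
# Declination D = atan2(y, x), degrees clockwise (eastward) from north,
# reported in (-180, 180].  Inclination I = dip below horizontal, positive
# downward, in [-90, 90].  Intensity B = |(x, y, z)|.

#' Magnetic field vector in component form
#'
#' @param x horizontal component toward magnetic north, µT.
#' @param y horizontal component toward magnetic east, µT.
#' @param z vertical component (positive downward), µT.
#' @return an object of class `field_xyz`.
#' @examples
#' field_xyz(26.824, -0.022, 39.922)
#' @export
field_xyz <- function(x, y, z) {
  stopifnot_scalar(x, "x"); stopifnot_scalar(y, "y"); stopifnot_scalar(z, "z")
  structure(list(x = x, y = y, z = z), class = "field_xyz")
}

#' Magnetic field vector in declination/inclination/intensity form
#'
#' @param declination degrees clockwise (eastward) from magnetic north, in
#'   `(-180, 180]`; may be `NA` when the horizontal component vanishes.
#' @param inclination dip angle in degrees, positive downward, in `[-90, 90]`.
#' @param intensity total field magnitude, µT (non-negative).
#' @return an object of class `field_dib`.
#' @export
field_dib <- function(declination, inclination, intensity) {
  stopifnot_scalar(inclination, "inclination")
  stopifnot_scalar(intensity, "intensity")
  if (!is.na(declination)) stopifnot_scalar(declination, "declination")
  if (intensity < 0) stop("`intensity` must be >= 0", call. = FALSE)
  if (inclination < -90 || inclination > 90)
    stop("`inclination` must lie in [-90, 90]", call. = FALSE)
  structure(list(declination = if (is.na(declination)) NA_real_ else wrap180(declination),
                 inclination = inclination, intensity = intensity),
            class = "field_dib")
}

#' @export
print.field_xyz <- function(x, ...) {
  cat(sprintf("field_xyz: x = %.3f, y = %.3f, z = %.3f uT (|B| = %.3f)\n",
              x$x, x$y, x$z, sqrt(x$x^2 + x$y^2 + x$z^2)))
  invisible(x)
}

#' @export
print.field_dib <- function(x, ...) {
  cat(sprintf("field_dib: D = %s deg, I = %.2f deg, B = %.3f uT\n",
              if (is.na(x$declination)) "undefined" else sprintf("%.2f", x$declination),
              x$inclination, x$intensity))
  invisible(x)
}

#' Convert a component-form field to declination/inclination/intensity
#'
#' When the horizontal component vanishes (`x = y = 0`) the declination is
#' undefined; it is returned as `NA` (with inclination ±90) rather than
#' defaulted to an arbitrary direction.
#'
#' @param f a [field_xyz()] vector.
#' @return a [field_dib()] vector.
#' @examples
#' dib_from_xyz(field_xyz(26.824, -0.022, 39.922))
#' @export
dib_from_xyz <- function(f) {
  stopifnot(inherits(f, "field_xyz"))
  h <- sqrt(f$x^2 + f$y^2)
  dec <- if (h == 0) NA_real_ else wrap180(rad2deg(atan2(f$y, f$x)))
  inc <- rad2deg(atan2(f$z, h))
  field_dib(dec, inc, sqrt(h^2 + f$z^2))
}

#' Convert a declination/inclination/intensity field to component form
#'
#' Inverse of [dib_from_xyz()]: round trips agree to 1e-9 relative.
#'
#' @param f a [field_dib()] vector; `declination` must not be `NA` unless the
#'   horizontal component is zero (|inclination| = 90 or intensity = 0).
#' @return a [field_xyz()] vector.
#' @export
xyz_from_dib <- function(f) {
  stopifnot(inherits(f, "field_dib"))
  h <- f$intensity * cos(deg2rad(f$inclination))
  z <- f$intensity * sin(deg2rad(f$inclination))
  if (is.na(f$declination)) {
    if (h > 1e-12 * max(f$intensity, 1))
      stop("declination is NA but the horizontal component is non-zero", call. = FALSE)
    return(field_xyz(0, 0, z))
  }
  field_xyz(h * cos(deg2rad(f$declination)), h * sin(deg2rad(f$declination)), z)
}

#' Coil field required for a horizontal-component alteration
#'
#' For an alteration of the horizontal geomagnetic component by `theta_deg`
#' (positive clockwise/eastward) that leaves the horizontal magnitude
#' unchanged, the required artificial field has magnitude
#' `b_coil = 2 * b_h_gmf * sin(|theta|/2)` and points along the chord between
#' the original and rotated horizontal vectors.  The two classical special
#' cases follow: a 180° alteration needs twice the horizontal component
#' (coil axis along north-south), and a ±120° alteration needs
#' `2 * cos(30°)` times the horizontal component.
#'
#' @param theta_deg alteration angle in degrees, in `(-360, 360)`.
#' @param b_h_gmf horizontal geomagnetic field magnitude, µT (> 0).
#' @return an object of class `coil_plan` with elements `alteration_deg`,
#'   `b_h_gmf`, `b_coil`, `axis_azimuth_deg` (azimuth of the generated field,
#'   degrees clockwise from magnetic north, `NA` for theta = 0),
#'   `axis_line_from_ns_deg` (acute angle of the generated-field axis line to
#'   the north-south line) and `coil_plane_from_ns_deg` (acute angle of the
#'   coil winding plane to the north-south line; the plane is perpendicular
#'   to the field axis).
#' @examples
#' coil_field_for_alteration(180, 26.824)  # b_coil = 2 * 26.824
#' coil_field_for_alteration(120, 1)       # b_coil = 2 * cos(30 deg)
#' @export
coil_field_for_alteration <- function(theta_deg, b_h_gmf) {
  stopifnot_scalar(theta_deg, "theta_deg"); stopifnot_scalar(b_h_gmf, "b_h_gmf")
  if (b_h_gmf <= 0) stop("`b_h_gmf` must be > 0", call. = FALSE)
  if (theta_deg <= -360 || theta_deg >= 360)
    stop("`theta_deg` must lie in (-360, 360)", call. = FALSE)
  th <- deg2rad(theta_deg)
  b_coil <- 2 * b_h_gmf * abs(sin(th / 2))
  # coil vector = rotated horizontal GMF vector minus original, for a GMF at
  # declination 0: north comp b_h*(cos th - 1), east comp b_h*sin th
  if (b_coil == 0) {
    axis <- NA_real_
  } else {
    axis <- wrap360(rad2deg(atan2(b_h_gmf * sin(th), b_h_gmf * (cos(th) - 1))))
  }
  axis_line <- if (is.na(axis)) NA_real_ else {
    a <- axis %% 180
    min(a, 180 - a)  # acute angle of the axis line to the N-S line
  }
  structure(list(alteration_deg = theta_deg, b_h_gmf = b_h_gmf, b_coil = b_coil,
                 axis_azimuth_deg = axis,
                 axis_line_from_ns_deg = axis_line,
                 coil_plane_from_ns_deg = if (is.na(axis_line)) NA_real_ else 90 - axis_line),
            class = "coil_plan")
}

#' @export
print.coil_plan <- function(x, ...) {
  cat(sprintf("coil_plan: theta = %g deg, B_H-GMF = %.3f uT\n", x$alteration_deg, x$b_h_gmf))
  cat(sprintf("  B_coil = %.3f uT (= %.6f x B_H-GMF)\n", x$b_coil, x$b_coil / x$b_h_gmf))
  if (is.na(x$axis_azimuth_deg)) {
    cat("  no coil field required (theta = 0)\n")
  } else {
    cat(sprintf("  generated-field azimuth = %.2f deg; axis line %.1f deg from N-S; coil plane %.1f deg from N-S\n",
                x$axis_azimuth_deg, x$axis_line_from_ns_deg, x$coil_plane_from_ns_deg))
  }
  invisible(x)
}

#' Vector addition of two magnetic fields
#'
#' @param a,b [field_xyz()] vectors.
#' @return their componentwise sum as a [field_xyz()].
#' @export
superpose <- function(a, b) {
  stopifnot(inherits(a, "field_xyz"), inherits(b, "field_xyz"))
  field_xyz(a$x + b$x, a$y + b$y, a$z + b$z)
}

# coil field vector (field frame) that turns the horizontal component of
# `gmf` by theta while leaving its magnitude and the vertical component
# untouched: rotated horizontal vector minus the original.
coil_vector <- function(gmf, theta_deg) {
  th <- deg2rad(theta_deg)
  co <- cos(th); si <- sin(th)
  # eastward (clockwise) rotation in the (north, east) plane
  nx <- gmf$x * co - gmf$y * si
  ny <- gmf$x * si + gmf$y * co
  field_xyz(nx - gmf$x, ny - gmf$y, 0)
}

#' Predicted total field after a horizontal alteration
#'
#' Superposes the geomagnetic field with the coil field designed for an
#' alteration by `theta_deg`: the declination shifts by exactly `theta_deg`,
#' while the horizontal magnitude and the vertical component are preserved.
#'
#' @param gmf the ambient field as a [field_xyz()]; must have a non-zero
#'   horizontal component.
#' @param theta_deg alteration angle, degrees clockwise (eastward).
#' @return the altered field as a [field_xyz()].
#' @export
predict_altered_field <- function(gmf, theta_deg) {
  stopifnot(inherits(gmf, "field_xyz"))
  stopifnot_scalar(theta_deg, "theta_deg")
  if (sqrt(gmf$x^2 + gmf$y^2) == 0)
    stop("`gmf` has zero horizontal component; the alteration is undefined", call. = FALSE)
  superpose(gmf, coil_vector(gmf, theta_deg))
}

#' Verify a measured field alteration against its design
#'
#' Compares magnetometer readings before and after switching the coil on
#' against the intended alteration: declination shift vs `theta_deg`,
#' horizontal magnitude, vertical component and total intensity (the latter
#' three should be unchanged by a pure horizontal rotation).
#'
#' @param before,after measured fields as [field_xyz()] vectors.
#' @param theta_deg intended alteration, degrees.
#' @param tol_deg tolerance on the declination shift, degrees (> 0).
#' @param tol_ut tolerance on magnitudes, µT (> 0).
#' @return a data frame of class `alteration_report` with one row per check
#'   (`declination_shift`, `horizontal_magnitude`, `vertical_component`,
#'   `total_intensity`) and columns `expected`, `observed`, `deviation`,
#'   `tolerance`, `pass`; attribute `pass` gives the overall verdict.
#' @export
verify_alteration <- function(before, after, theta_deg, tol_deg = 3, tol_ut = 1) {
  stopifnot(inherits(before, "field_xyz"), inherits(after, "field_xyz"))
  stopifnot_scalar(theta_deg, "theta_deg")
  if (tol_deg <= 0 || tol_ut <= 0) stop("tolerances must be > 0", call. = FALSE)
  db <- dib_from_xyz(before); da <- dib_from_xyz(after)
  hb <- sqrt(before$x^2 + before$y^2); ha <- sqrt(after$x^2 + after$y^2)
  shift <- if (is.na(db$declination) || is.na(da$declination)) NA_real_ else
    wrap180(da$declination - db$declination)
  dev_shift <- if (is.na(shift)) NA_real_ else circ_dist(shift, theta_deg)
  rep <- data.frame(
    check     = c("declination_shift", "horizontal_magnitude", "vertical_component", "total_intensity"),
    expected  = c(wrap180(theta_deg), hb, before$z, db$intensity),
    observed  = c(shift, ha, after$z, da$intensity),
    deviation = c(dev_shift, abs(ha - hb), abs(after$z - before$z),
                  abs(da$intensity - db$intensity)),
    tolerance = c(tol_deg, tol_ut, tol_ut, tol_ut),
    stringsAsFactors = FALSE)
  rep$pass <- !is.na(rep$deviation) & rep$deviation <= rep$tolerance
  structure(rep, pass = all(rep$pass), class = c("alteration_report", "data.frame"))
}

#' @export
print.alteration_report <- function(x, ...) {
  cat(sprintf("field alteration verification: %s\n",
              if (isTRUE(attr(x, "pass"))) "PASS" else "FAIL"))
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Read magnetometer measurements from CSV or JSON
#'
#' Accepts either component columns/keys (`x_ut`, `y_ut`, `z_ut`; aliases
#' `x`, `y`, `z`) or angular ones (`declination_deg`, `inclination_deg`,
#' `intensity_ut`; aliases `declination`, `inclination`, `intensity`).  Units
#' are µT and degrees.  A bundled example file with before/after readings for
#' a 180° and a +120° alteration ships as
#' `system.file("extdata", "field_measurements.csv", package = "antgaze")`.
#'
#' @param path CSV (with header) or JSON file (array of objects).
#' @return a list of [field_xyz()] vectors, one per row/record, with any
#'   additional columns attached as attribute `meta` (a data frame).
#' @export
read_field_measurements <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- as.data.frame(jsonlite::fromJSON(path))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(df)) return(df[[nm]])
    NULL
  }
  x <- pick("x_ut", "x"); y <- pick("y_ut", "y"); z <- pick("z_ut", "z")
  if (!is.null(x) && !is.null(y) && !is.null(z)) {
    fields <- lapply(seq_len(nrow(df)), function(i) field_xyz(x[i], y[i], z[i]))
  } else {
    d <- pick("declination_deg", "declination")
    i <- pick("inclination_deg", "inclination")
    b <- pick("intensity_ut", "intensity")
    if (is.null(d) || is.null(i) || is.null(b))
      stop("no (x, y, z) nor (declination, inclination, intensity) columns found in ", path,
           call. = FALSE)
    fields <- lapply(seq_len(nrow(df)), function(k) xyz_from_dib(field_dib(d[k], i[k], b[k])))
  }
  attr(fields, "meta") <- df
  fields
}
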