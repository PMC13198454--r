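# Headings, bearings, relative gaze, fictive-nest construction, speeds, and
# pirouette selection.
#
# The gaze axis is the thorax->mandible body axis.  Relative gaze maps
# perfect fixation of the goal to 180 degrees (the goal is "defined as 180"),
# so rose plots of goal-directed gazes concentrate around 180.

#' Heading azimuth of the body axis
#'
#' Azimuth of the thorax-to-mandible vector, degrees clockwise from +y
#' (north), in `[0, 360)`.
#'
#' @param mandible,thorax length-2 points `c(x, y)` or n x 2 matrices, cm.
#' @return numeric vector of azimuths; errors on a degenerate frame
#'   (mandible = thorax).
#' @examples
#' heading_azimuth(c(0, 1), c(0, 0))  # facing north: 0
#' heading_azimuth(c(1, 0), c(0, 0))  # facing east: 90
#' @export
heading_azimuth <- function(mandible, thorax) {
  m <- rbind(mandible); th <- rbind(thorax)
  dx <- m[, 1] - th[, 1]; dy <- m[, 2] - th[, 2]
  if (any(dx == 0 & dy == 0))
    stop("degenerate frame: mandible coincides with thorax", call. = FALSE)
  azimuth_deg(dx, dy)
}

#' Bearing from one point to another
#'
#' @param from_pt,to_pt length-2 points `c(x, y)` or n x 2 matrices, cm.
#' @return azimuth of `to_pt - from_pt`, degrees clockwise from north in
#'   `[0, 360)`; errors on coincident points.
#' @export
bearing <- function(from_pt, to_pt) {
  a <- rbind(from_pt); b <- rbind(to_pt)
  dx <- b[, 1] - a[, 1]; dy <- b[, 2] - a[, 2]
  if (any(dx == 0 & dy == 0)) stop("coincident points: bearing undefined", call. = FALSE)
  azimuth_deg(dx, dy)
}

#' Per-frame headings of a track
#'
#' @param track an [lw_track()].
#' @return numeric vector of heading azimuths (degrees), `NA` at degenerate
#'   frames.
#' @export
track_headings <- function(track) {
  m <- mand_xy(track); th <- thor_xy(track)
  dx <- m[, 1] - th[, 1]; dy <- m[, 2] - th[, 2]
  h <- azimuth_deg(dx, dy)
  h[dx == 0 & dy == 0] <- NA_real_
  h
}

#' Gaze direction relative to a goal
#'
#' `((heading - bearing(mandible, goal)) + 180) mod 360`: an ant gazing
#' exactly at the goal scores 180, an ant gazing exactly away scores 0.
#'
#' @param heading_deg heading azimuth(s), degrees.
#' @param mandible mandible position(s), `c(x, y)` or n x 2 matrix, cm.
#' @param goal goal point `c(x, y)`, cm; must not coincide with the mandible.
#' @return relative gaze in `[0, 360)`.
#' @examples
#' relative_gaze(0, c(0, 0), c(0, 10))  # fixating the goal: 180
#' @export
relative_gaze <- function(heading_deg, mandible, goal) {
  m <- rbind(mandible)
  b <- bearing(m, matrix(goal, nrow(m), 2, byrow = TRUE))
  wrap360(heading_deg - b + 180)
}

#' Fictive goal position under a field alteration
#'
#' Rotates the mandible-to-nest vector about the mandible position by the
#' alteration angle (positive clockwise/eastward, the same sign convention as
#' the field-geometry module): where the nest "should" lie if the ant reads
#' the altered magnetic compass.
#'
#' @param mandible_at_switch mandible position `c(x, y)` at the coil
#'   switch-on moment, cm.
#' @param nest nest position `c(x, y)`, cm; must differ from the mandible.
#' @param theta_deg alteration angle, degrees.
#' @return the fictive nest position `c(x, y)`.
#' @examples
#' fictive_nest(c(10, 0), c(0, 0), 180)  # reflects through the ant: (20, 0)
#' @export
fictive_nest <- function(mandible_at_switch, nest, theta_deg) {
  stopifnot(length(mandible_at_switch) == 2, length(nest) == 2)
  v <- nest - mandible_at_switch
  if (all(v == 0)) stop("mandible coincides with the nest: rotation undefined", call. = FALSE)
  mandible_at_switch + rotate_cw(v, theta_deg)
}

#' Forward speed of the thorax
#'
#' Central-difference speed of the thorax point (one-sided at the track
#' ends), cm/s.
#'
#' @param track an [lw_track()] with at least 2 frames.
#' @return numeric vector, one speed per frame.
#' @export
forward_speed <- function(track) {
  th <- thor_xy(track); t <- track$frames$t_s
  n <- nrow(th)
  if (n < 2) stop("track needs at least 2 frames", call. = FALSE)
  sp <- numeric(n)
  if (n > 2) {
    i <- 2:(n - 1)
    sp[i] <- sqrt(rowSums((th[i + 1, , drop = FALSE] - th[i - 1, , drop = FALSE])^2)) /
      (t[i + 1] - t[i - 1])
  }
  sp[1] <- sqrt(sum((th[2, ] - th[1, ])^2)) / (t[2] - t[1])
  sp[n] <- sqrt(sum((th[n, ] - th[n - 1, ])^2)) / (t[n] - t[n - 1])
  sp
}

#' Angular speed of the heading
#'
#' Central-difference of the heading azimuth using the circular (wrapped to
#' `(-180, 180]`) difference, deg/s; one-sided at the ends.  Frames whose
#' finite-difference stencil touches a degenerate frame get `NA`.
#'
#' @param track an [lw_track()] with at least 2 frames.
#' @return numeric vector of signed angular speeds (positive clockwise).
#' @export
angular_speed <- function(track) {
  h <- track_headings(track); t <- track$frames$t_s
  n <- length(h)
  if (n < 2) stop("track needs at least 2 frames", call. = FALSE)
  av <- rep(NA_real_, n)
  if (n > 2) {
    i <- 2:(n - 1)
    av[i] <- wrap180(h[i + 1] - h[i - 1]) / (t[i + 1] - t[i - 1])
  }
  av[1] <- wrap180(h[2] - h[1]) / (t[2] - t[1])
  av[n] <- wrap180(h[n] - h[n - 1]) / (t[n] - t[n - 1])
  av
}

#' Select the analyzed pirouette pair around the coil event
#'
#' Picks the last annotated pirouette ending before the switch-on time and
#' the first one starting after it, applying the nest-distance rule: the mean
#' mandible position over the pirouette must be at least `min_dist_cm` from
#' the nest entrance.  Absent slots are reported with a reason, never as an
#' error.
#'
#' @param track an [lw_track()].
#' @param annotations a [pirouette_annotations()] data frame.
#' @param event a [coil_event()].
#' @param min_dist_cm minimum mean mandible distance from the nest, cm
#'   (default 5).
#' @return a list with `before`, `after` (each a one-row annotation data
#'   frame or `NULL`) and `before_reason`, `after_reason` (`NULL` when the
#'   slot is filled).
#' @export
select_pirouettes <- function(track, annotations, event, min_dist_cm = 5) {
  stopifnot(inherits(track, "lw_track"), inherits(event, "coil_event"))
  if (is.null(annotations) || nrow(annotations) == 0)
    return(list(before = NULL, after = NULL,
                before_reason = "no annotations", after_reason = "no annotations"))
  f <- track$frames
  t_of <- function(frame_no) f$t_s[match(frame_no, f$frame)]
  m <- mand_xy(track)
  mean_dist <- vapply(seq_len(nrow(annotations)), function(i) {
    rows <- which(f$frame >= annotations$start[i] & f$frame <= annotations$end[i])
    mu <- colMeans(m[rows, , drop = FALSE])
    sqrt(sum((mu - track$nest)^2))
  }, numeric(1))
  far <- mean_dist >= min_dist_cm
  end_t <- t_of(annotations$end)
  start_t <- t_of(annotations$start)

  pre <- which(end_t < event$switch_on_t)
  pre_ok <- pre[far[pre]]
  before <- NULL; before_reason <- NULL
  if (!length(pre)) before_reason <- "no pirouette ends before switch-on"
  else if (!length(pre_ok)) before_reason <- sprintf("all pre-switch pirouettes closer than %g cm to the nest", min_dist_cm)
  else before <- annotations[pre_ok[which.max(end_t[pre_ok])], , drop = FALSE]

  post <- which(start_t > event$switch_on_t)
  post_ok <- post[far[post]]
  after <- NULL; after_reason <- NULL
  if (!length(post)) after_reason <- "no candidate after switch-on"
  else if (!length(post_ok)) after_reason <- sprintf("all post-switch pirouettes closer than %g cm to the nest", min_dist_cm)
  else after <- annotations[post_ok[which.min(start_t[post_ok])], , drop = FALSE]

  list(before = before, after = after,
       before_reason = before_reason, after_reason = after_reason)
}

#' Heuristic pirouette detector (convenience, not the primary path)
#'
#' Flags windows where the cumulative absolute heading change reaches
#' `min_turn_deg` while the net thorax displacement stays within one body
#' length.  Annotated pirouettes are the authoritative input for analysis;
#' this detector only helps to pre-annotate raw tracks.
#'
#' @param track an [lw_track()].
#' @param min_turn_deg cumulative heading change to qualify (default 180).
#' @param body_length_cm displacement cap (default the median
#'   mandible-thorax distance).
#' @return a [pirouette_annotations()] data frame (possibly empty).
#' @export
detect_pirouettes <- function(track, min_turn_deg = 180, body_length_cm = NULL) {
  h <- track_headings(track)
  th <- thor_xy(track)
  f <- track$frames
  n <- length(h)
  if (is.null(body_length_cm)) {
    bl <- sqrt(rowSums((mand_xy(track) - thor_xy(track))^2))
    body_length_cm <- stats::median(bl, na.rm = TRUE)
  }
  starts <- integer(); ends <- integer()
  i <- 1L
  while (i < n) {
    if (is.na(h[i])) { i <- i + 1L; next }
    turn <- 0; j <- i
    while (j < n && !is.na(h[j + 1]) &&
           sqrt(sum((th[j + 1, ] - th[i, ])^2)) <= body_length_cm) {
      turn <- turn + abs(wrap180(h[j + 1] - h[j]))
      j <- j + 1L
    }
    if (turn >= min_turn_deg) {
      starts <- c(starts, f$frame[i]); ends <- c(ends, f$frame[j])
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(starts)) return(pirouette_annotations(integer(), integer()))
  pirouette_annotations(starts, ends)
}
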