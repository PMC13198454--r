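# Stopping-phase detection.
#
# A stopping phase is a maximal frame window within a pirouette in which the
# ant neither advances (forward speed at or below a threshold) nor shifts its
# gaze (every heading within +/- gaze_tol_deg of the window's circular-mean
# heading) for at least min_duration_ms.  Gaze constancy is judged against
# the window mean, not frame-to-frame increments, which makes the definition
# order-independent and directly checkable by exhaustive enumeration.
# Durations count the inter-frame span (end - start)/fps: at 50 fps a
# 6-frame window is the shortest that reaches 100 ms.

#' Stop-detection criteria
#'
#' @param gaze_tol_deg maximum circular deviation of any in-window heading
#'   from the window's circular-mean heading, degrees (default 10).
#' @param min_duration_ms minimum window span `(end - start) / fps`,
#'   milliseconds (default 100).
#' @param max_forward_speed maximum forward (thorax) speed within the
#'   window, cm/s (default 0.5; the stop criterion in the source analysis
#'   does not state a numeric speed threshold, so this default is explicit
#'   and echoed in all outputs).
#' @param max_angular_speed optional cap on |angular speed| (deg/s) within
#'   the window; `NULL` (default) applies no separate cap, as gaze constancy
#'   already bounds rotation.
#' @return an object of class `stop_criteria`.
#' @export
stop_criteria <- function(gaze_tol_deg = 10, min_duration_ms = 100,
                          max_forward_speed = 0.5, max_angular_speed = NULL) {
  stopifnot(gaze_tol_deg > 0, min_duration_ms > 0, max_forward_speed > 0)
  if (!is.null(max_angular_speed)) stopifnot(max_angular_speed > 0)
  structure(list(gaze_tol_deg = gaze_tol_deg, min_duration_ms = min_duration_ms,
                 max_forward_speed = max_forward_speed,
                 max_angular_speed = max_angular_speed),
            class = "stop_criteria")
}

# circular mean (deg) of a set of angles via unit-vector sums; atan2(0,0) -> 0
circ_mean_deg <- function(angles_deg) {
  a <- deg2rad(angles_deg)
  wrap360(rad2deg(atan2(sum(sin(a)), sum(cos(a)))))
}

#' Detect stopping phases within a pirouette
#'
#' Returns all maximal windows satisfying the criteria: every frame slow,
#' every heading within `gaze_tol_deg` of the window's circular mean, span at
#' least `min_duration_ms`.  No returned window is strictly contained in
#' another qualifying window; overlapping windows are possible when neither
#' contains the other.  Degenerate frames (undefined heading) cannot belong
#' to any phase.
#'
#' @param track an [lw_track()].
#' @param pirouette one-row annotation (list or data frame with `start`,
#'   `end`, 0-based frame numbers) delimiting the pirouette.
#' @param criteria a [stop_criteria()].
#' @return a data frame of class `stopping_phases` with columns
#'   `start_index`, `end_index` (frame numbers, inclusive), `n_frames`,
#'   `duration_ms`, `gaze_mean_deg`, `max_dev_deg`; zero rows when the
#'   pirouette holds no qualifying window.
#' @export
detect_stopping_phases <- function(track, pirouette, criteria = stop_criteria()) {
  stopifnot(inherits(track, "lw_track"), inherits(criteria, "stop_criteria"))
  f <- track$frames
  rows <- which(f$frame >= pirouette$start[1] & f$frame <= pirouette$end[1])
  empty <- data.frame(start_index = integer(), end_index = integer(),
                      n_frames = integer(), duration_ms = numeric(),
                      gaze_mean_deg = numeric(), max_dev_deg = numeric())
  class(empty) <- c("stopping_phases", "data.frame")
  if (length(rows) < 2) return(empty)

  h <- track_headings(track)[rows]
  sp <- forward_speed(track)[rows]
  slow <- sp <= criteria$max_forward_speed & !is.na(h)
  if (!is.null(criteria$max_angular_speed)) {
    av <- angular_speed(track)[rows]
    slow <- slow & !is.na(av) & abs(av) <= criteria$max_angular_speed
  }
  fps <- track$fps
  tol <- criteria$gaze_tol_deg
  k_min <- max(2L, ceiling(criteria$min_duration_ms * fps / 1000 + 1 - 1e-9))

  # maximal runs of slow frames
  r <- rle(slow)
  ends_run <- cumsum(r$lengths)
  starts_run <- ends_run - r$lengths + 1L
  keep <- r$values & r$lengths >= k_min
  wins <- list()
  for (ri in which(keep)) {
    a <- starts_run[ri]; b <- ends_run[ri]
    hr <- h[a:b]
    L <- b - a + 1L
    cs <- cumsum(cos(deg2rad(hr))); sn <- cumsum(sin(deg2rad(hr)))
    run_best <- integer(0)  # best (largest) qualifying end per start, local idx
    run_starts <- integer(0)
    for (s in 1:(L - k_min + 1L)) {
      maxpair <- 0
      best_e <- NA_integer_
      for (e in (s + 1L):L) {
        # pairwise-spread bound: once two headings differ by > 2*tol no
        # superset window can satisfy the mean-deviation criterion
        maxpair <- max(maxpair, max(circ_dist(hr[s:(e - 1L)], hr[e])))
        if (maxpair > 2 * tol) break
        if (e - s + 1L >= k_min) {
          C <- cs[e] - if (s > 1L) cs[s - 1L] else 0
          S <- sn[e] - if (s > 1L) sn[s - 1L] else 0
          mu <- wrap360(rad2deg(atan2(S, C)))
          if (max(circ_dist(hr[s:e], mu)) <= tol) best_e <- e
        }
      }
      if (!is.na(best_e)) {
        run_starts <- c(run_starts, s)
        run_best <- c(run_best, best_e)
      }
    }
    if (length(run_starts)) {
      # maximality: drop (s, e) when an earlier start reaches at least e
      run_max <- cummax(run_best)
      keep_w <- run_best > c(0L, run_max[-length(run_max)])
      for (k in which(keep_w))
        wins[[length(wins) + 1L]] <- c(a + run_starts[k] - 1L, a + run_best[k] - 1L)
    }
  }
  if (!length(wins)) return(empty)
  out <- do.call(rbind, lapply(wins, function(w) {
    s <- w[1]; e <- w[2]
    mu <- circ_mean_deg(h[s:e])
    data.frame(start_index = f$frame[rows[s]], end_index = f$frame[rows[e]],
               n_frames = e - s + 1L,
               duration_ms = (f$t_s[rows[e]] - f$t_s[rows[s]]) * 1000,
               gaze_mean_deg = mu, max_dev_deg = max(circ_dist(h[s:e], mu)))
  }))
  out <- out[order(out$start_index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("stopping_phases", "data.frame")
  out
}

#' Longest stopping phase
#'
#' @param phases a `stopping_phases` data frame from
#'   [detect_stopping_phases()].
#' @return the one-row phase with maximal duration (ties broken by earliest
#'   start), or `NULL` for empty input.
#' @export
longest_stopping_phase <- function(phases) {
  if (is.null(phases) || nrow(phases) == 0) return(NULL)
  ord <- order(-phases$duration_ms, phases$start_index)
  phases[ord[1], , drop = FALSE]
}

#' Mean relative gaze over a stopping phase
#'
#' Circular mean, over the phase's frames, of the gaze direction relative to
#' a goal (goal fixation = 180°).  Degenerate frames are excluded; an
#' all-degenerate phase is an error.
#'
#' @param track an [lw_track()].
#' @param phase a one-row phase (with `start_index`, `end_index`).
#' @param goal goal point `c(x, y)`, cm.
#' @return relative gaze in degrees, `[0, 360)`.
#' @export
phase_gaze <- function(track, phase, goal) {
  f <- track$frames
  rows <- which(f$frame >= phase$start_index[1] & f$frame <= phase$end_index[1])
  if (!length(rows)) stop("phase lies outside the track", call. = FALSE)
  h <- track_headings(track)[rows]
  ok <- !is.na(h)
  if (!any(ok)) stop("all frames in the phase are degenerate", call. = FALSE)
  rel <- relative_gaze(h[ok], mand_xy(track)[rows[ok], , drop = FALSE], goal)
  circ_mean_deg(rel)
}
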