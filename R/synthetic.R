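# Synthetic learning-walk generator.
#
# Emulates the statistical structure the analysis assumes: 50-fps tracks on
# a 60 cm x 60 cm platform, correlated-random-walk legs between pirouettes,
# pirouettes as in-place body rotations containing stopping phases, and - in
# each pirouette - exactly one designated longest stop whose gaze is von
# Mises-distributed around the bearing to the current goal (the nest before
# the coil switch-on, the fictive nest after it).  Decoy stops have uniform
# random gaze directions.  Ground truth (goals, designated windows, drawn
# errors) is returned frame-consistently for parameter-recovery tests.

#' Von Mises random angles
#'
#' Best-Fisher rejection sampler; `kappa = 0` draws from the circular
#' uniform.
#'
#' @param n number of draws.
#' @param mu_deg mean direction, degrees.
#' @param kappa concentration (>= 0).
#' @return angles in degrees, `[0, 360)`.
#' @export
rvonmises_deg <- function(n, mu_deg = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(stats::runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  rr <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + rr * z) / (rr + z)
    cc <- kappa * (rr - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(f[ok])
    k <- length(th)
    if (k) {
      out[(got + 1):(got + k)] <- th
      got <- got + k
    }
  }
  wrap360(mu_deg + rad2deg(out))
}

#' Simulator configuration
#'
#' Defaults describe the emulated study conditions: 15 ants, 50 fps, a
#' 60 cm x 60 cm platform with the nest at its center, one analyzed
#' pirouette per epoch (before/after the coil switch-on), pirouettes at
#' 8-18 cm from the nest (all beyond the 5 cm selection threshold), and a
#' gaze concentration of kappa = 8 around the goal bearing, which yields
#' mean resultant lengths in the empirically typical 0.5-0.9 range at
#' n = 15.
#'
#' @param n_ants number of ants (>= 1).
#' @param kappa von Mises concentration of the designated-stop gaze error;
#'   a single value or `c(before, after)`.
#' @param alteration_deg the field alteration angle theta, degrees.
#' @param fps frame rate (default 50).
#' @param pirouettes_per_epoch pirouettes per epoch (default 1).
#' @param stops_per_pirouette stops per pirouette, the designated longest one
#'   included (default 3).
#' @param longest_stop_ms duration range (ms) of the designated longest stop
#'   (default 240-400; must be able to reach 100 ms, else the dataset would
#'   be unanalyzable by construction).
#' @param decoy_stop_ms duration range (ms) of decoy stops (default 120-180;
#'   kept strictly below `longest_stop_ms` so the designated stop is always
#'   the longest).
#' @param walk_step_cm step length of the inter-pirouette walk per frame, cm
#'   (default 0.2, i.e. 10 cm/s at 50 fps).
#' @param walk_turn_kappa heading concentration of the correlated random
#'   walk around the bearing to its waypoint (default 8).
#' @param stop_jitter_cm positional noise (sd, cm) of the thorax during
#'   pirouettes; default 0.002 cm, well below the stop speed threshold.
#' @param body_length_cm mandible-thorax distance, cm (default 0.6).
#' @param platform_cm side length of the square platform, cm (default 60).
#' @param pirouette_dist_cm radial range (cm) from the nest at which
#'   pirouettes are performed (default 8-18).
#' @param seed integer seed governing all draws, or `NULL` to use the
#'   current RNG state.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_ants = 15, kappa = 8, alteration_deg = 180, fps = 50,
                       pirouettes_per_epoch = 1, stops_per_pirouette = 3,
                       longest_stop_ms = c(240, 400), decoy_stop_ms = c(120, 180),
                       walk_step_cm = 0.2, walk_turn_kappa = 8,
                       stop_jitter_cm = 0.002, body_length_cm = 0.6,
                       platform_cm = 60, pirouette_dist_cm = c(8, 18),
                       seed = NULL) {
  stopifnot(n_ants >= 1, all(kappa >= 0), fps > 0, pirouettes_per_epoch >= 1,
            stops_per_pirouette >= 1, all(longest_stop_ms > 0),
            all(decoy_stop_ms > 0), walk_step_cm > 0, stop_jitter_cm >= 0,
            body_length_cm > 0)
  if (max(longest_stop_ms) < 100)
    stop("`longest_stop_ms` cannot reach 100 ms: the designated stops would never qualify",
         call. = FALSE)
  if (max(decoy_stop_ms) >= min(longest_stop_ms))
    stop("`decoy_stop_ms` must stay strictly below `longest_stop_ms`", call. = FALSE)
  kappa <- rep_len(kappa, 2)
  structure(list(n_ants = as.integer(n_ants), kappa = kappa,
                 alteration_deg = alteration_deg, fps = fps,
                 pirouettes_per_epoch = as.integer(pirouettes_per_epoch),
                 stops_per_pirouette = as.integer(stops_per_pirouette),
                 longest_stop_ms = longest_stop_ms, decoy_stop_ms = decoy_stop_ms,
                 walk_step_cm = walk_step_cm, walk_turn_kappa = walk_turn_kappa,
                 stop_jitter_cm = stop_jitter_cm, body_length_cm = body_length_cm,
                 platform_cm = platform_cm, pirouette_dist_cm = pirouette_dist_cm,
                 seed = seed),
            class = "sim_config")
}

unit_vec <- function(az_deg) cbind(sin(deg2rad(az_deg)), cos(deg2rad(az_deg)))

# rotation approach/retreat offsets: frames end (or start) 25 deg away from
# the stop heading, with 15 deg/frame steps - both margins exceed twice the
# 10 deg gaze tolerance, so no detection window can bridge a stop boundary
ROT_CLEAR_DEG <- 25
ROT_STEP_DEG <- 15

sim_one_ant <- function(cfg, ant_id) {
  bl <- cfg$body_length_cm
  th_list <- list(); hd_list <- list()
  nfr <- 0L
  pos <- c(stats::runif(1, -0.3, 0.3), stats::runif(1, -0.3, 0.3)) +
    0.5 * unit_vec(stats::runif(1, 0, 360))[1, ]
  heading <- stats::runif(1, 0, 360)
  add_seg <- function(th, hd) {
    th_list[[length(th_list) + 1L]] <<- th
    hd_list[[length(hd_list) + 1L]] <<- hd
    first <- nfr
    nfr <<- nfr + nrow(th)
    first  # 0-based frame number of the segment's first frame
  }
  walk_to <- function(target) {
    pts <- list(); hds <- numeric(0)
    p <- pos
    for (i in 1:5000) {
      d <- sqrt(sum((target - p)^2))
      if (d <= cfg$walk_step_cm) break
      h <- rvonmises_deg(1, bearing(p, target), cfg$walk_turn_kappa)
      p <- p + cfg$walk_step_cm * unit_vec(h)[1, ]
      half <- cfg$platform_cm / 2 - 1
      p <- pmin(pmax(p, -half), half)
      pts[[length(pts) + 1L]] <- p; hds <- c(hds, h)
    }
    pos <<- p
    if (length(hds)) heading <<- hds[length(hds)]
    if (!length(pts)) return(invisible(NULL))
    add_seg(do.call(rbind, pts), hds)
  }
  ms_to_frames <- function(ms) as.integer(round(ms * cfg$fps / 1000)) + 1L
  pirouette_at <- function(goal, kappa) {
    anchor <- pos
    n_stops <- cfg$stops_per_pirouette
    designated <- sample.int(n_stops, 1)
    hd <- numeric(0)
    stops <- data.frame(start_local = integer(), end_local = integer(),
                        designated = logical(), heading_deg = numeric(),
                        goal_bearing_deg = numeric(), gaze_error_deg = numeric())
    for (j in seq_len(n_stops)) {
      gb <- bearing(anchor, goal)
      if (j == designated) {
        err <- wrap180(rvonmises_deg(1, 0, kappa))
        h_stop <- wrap360(gb + err)
        dur <- stats::runif(1, cfg$longest_stop_ms[1], cfg$longest_stop_ms[2])
      } else {
        err <- NA_real_
        h_stop <- stats::runif(1, 0, 360)
        dur <- stats::runif(1, cfg$decoy_stop_ms[1], cfg$decoy_stop_ms[2])
      }
      sgn <- sample(c(-1, 1), 1)
      m <- sample(3:6, 1)
      approach <- wrap360(h_stop + sgn * (ROT_CLEAR_DEG + ROT_STEP_DEG * ((m - 1):0)))
      k <- ms_to_frames(dur)
      stops <- rbind(stops, data.frame(
        start_local = length(hd) + m + 1L, end_local = length(hd) + m + k,
        designated = j == designated, heading_deg = h_stop,
        goal_bearing_deg = gb, gaze_error_deg = err))
      hd <- c(hd, approach, rep(h_stop, k))
    }
    sgn <- sample(c(-1, 1), 1)
    m <- sample(3:6, 1)
    hd <- c(hd, wrap360(hd[length(hd)] + sgn * (ROT_CLEAR_DEG + ROT_STEP_DEG * (0:(m - 1)))))
    L <- length(hd)
    th <- matrix(rep(anchor, each = L), L, 2) +
      matrix(stats::rnorm(2 * L, 0, cfg$stop_jitter_cm), L, 2)
    first <- add_seg(th, hd)
    heading <<- hd[L]
    stops$start_frame <- first + stops$start_local - 1L
    stops$end_frame <- first + stops$end_local - 1L
    list(start = first, end = first + L - 1L, stops = stops)
  }
  draw_target <- function() {
    r <- stats::runif(1, cfg$pirouette_dist_cm[1], cfg$pirouette_dist_cm[2])
    r * unit_vec(stats::runif(1, 0, 360))[1, ]
  }

  ann <- list(); truth_stops <- list()
  # before epoch: goal is the real nest at the origin
  for (p in seq_len(cfg$pirouettes_per_epoch)) {
    walk_to(draw_target())
    pr <- pirouette_at(c(0, 0), cfg$kappa[1])
    ann[[length(ann) + 1L]] <- data.frame(start = pr$start, end = pr$end,
                                          label = "before")
    pr$stops$epoch <- "before"
    truth_stops[[length(truth_stops) + 1L]] <- pr$stops
  }
  # inter-epoch walk; the coil switches on mid-way through it.  Re-draw the
  # waypoint if it happens to land within a step of the current position,
  # so the walk always has frames to carry the switch-on moment.
  seg_first <- NULL
  for (try in 1:50) {
    sf <- walk_to(draw_target())
    if (is.null(seg_first)) seg_first <- sf
    if (!is.null(seg_first) && nfr - seg_first >= 4L) break
  }
  if (is.null(seg_first)) stop("internal: inter-epoch walk produced no frames")
  seg_len <- nfr - seg_first
  switch_frame <- seg_first + min(seg_len - 1L, max(1L, seg_len %/% 2L))
  # after epoch: goal is the fictive nest, fixed at switch-on
  all_th <- do.call(rbind, th_list); all_hd <- unlist(hd_list)
  mand_sw <- all_th[switch_frame + 1L, ] + bl * unit_vec(all_hd[switch_frame + 1L])[1, ]
  fict <- fictive_nest(mand_sw, c(0, 0), cfg$alteration_deg)
  for (p in seq_len(cfg$pirouettes_per_epoch)) {
    if (p > 1) walk_to(draw_target())
    pr <- pirouette_at(fict, cfg$kappa[2])
    ann[[length(ann) + 1L]] <- data.frame(start = pr$start, end = pr$end,
                                          label = "after")
    pr$stops$epoch <- "after"
    truth_stops[[length(truth_stops) + 1L]] <- pr$stops
  }
  # a short departure leg so the last pirouette does not end the track
  walk_to(pos + 3 * unit_vec(stats::runif(1, 0, 360))[1, ])

  th <- do.call(rbind, th_list); hd <- unlist(hd_list)
  n <- nrow(th)
  mand <- th + bl * unit_vec(hd)
  frames <- data.frame(frame = 0:(n - 1), t_s = (0:(n - 1)) / cfg$fps,
                       mand_x_cm = mand[, 1], mand_y_cm = mand[, 2],
                       thor_x_cm = th[, 1], thor_y_cm = th[, 2])
  half <- cfg$platform_cm / 2
  track <- lw_track(frames, fps = cfg$fps, ant_id = ant_id, nest = c(0, 0),
                    platform = c(-half, half, -half, half))
  anns <- do.call(rbind, ann)
  annotations <- pirouette_annotations(anns$start, anns$end, anns$label)
  switch_on_t <- frames$t_s[switch_frame + 1L]
  event <- coil_event(switch_on_t, cfg$alteration_deg)
  ts <- do.call(rbind, truth_stops)
  ts$start_local <- ts$end_local <- NULL
  list(track = track, annotations = annotations, event = event,
       truth = list(ant_id = ant_id, switch_on_t = switch_on_t,
                    mandible_at_switch = mand_sw, fictive_nest = fict,
                    stops = ts))
}

#' Simulate a field-alteration experiment
#'
#' Generates `n_ants` learning-walk tracks with annotations and coil events
#' in the exact formats [analyze_experiment()] consumes, plus frame-accurate
#' ground truth.  Each ant performs the before-epoch pirouette(s) gazing at
#' the nest, the coil switches on during the following walk leg, and the
#' after-epoch pirouette(s) are gazed at the fictive nest computed with
#' [fictive_nest()] from the mandible position at the switch-on frame.
#'
#' @param config a [sim_config()].
#' @return a list with `dataset` (per-ant `list(track, annotations, event)`),
#'   `truth` (per-ant ground truth: fictive nest, designated stop windows,
#'   goal bearings, drawn gaze errors) and `config`.
#' @examples
#' sim <- simulate_experiment(sim_config(n_ants = 2, seed = 1))
#' length(sim$dataset)
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ants <- lapply(seq_len(config$n_ants), function(i)
    sim_one_ant(config, sprintf("ant%03d", i)))
  list(dataset = lapply(ants, function(a) a[c("track", "annotations", "event")]),
       truth = lapply(ants, `[[`, "truth"),
       config = config)
}
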