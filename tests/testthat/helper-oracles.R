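# Independent oracles and fixture builders shared across tests.
# These deliberately re-derive quantities from first principles (plain loops,
# exhaustive enumeration) rather than calling the package's optimized paths.

# exhaustive stopping-phase oracle: every (start, end) window is checked
# directly against the stop definition, then windows strictly contained in
# another qualifying window are dropped
oracle_stopping_phases <- function(track, pirouette, criteria) {
  f <- track$frames
  rows <- which(f$frame >= pirouette$start[1] & f$frame <= pirouette$end[1])
  h <- track_headings(track)[rows]
  sp <- forward_speed(track)[rows]
  n <- length(rows)
  fps <- track$fps
  wins <- list()
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (is.na(h[e]) || sp[e] > criteria$max_forward_speed) break  # supersets share frame e
      if ((f$t_s[rows[e]] - f$t_s[rows[s]]) * 1000 < criteria$min_duration_ms - 1e-9) next
      ang <- h[s:e] * pi / 180
      mu <- atan2(sum(sin(ang)), sum(cos(ang))) * 180 / pi
      d <- (h[s:e] - mu) %% 360
      dev <- pmin(d, 360 - d)
      if (max(dev) <= criteria$gaze_tol_deg) wins[[length(wins) + 1L]] <- c(s, e)
    }
  }
  if (!length(wins)) return(matrix(integer(), 0, 2))
  w <- do.call(rbind, wins)
  keep <- vapply(seq_len(nrow(w)), function(i) {
    !any(w[, 1] <= w[i, 1] & w[, 2] >= w[i, 2] & (w[, 1] != w[i, 1] | w[, 2] != w[i, 2]))
  }, logical(1))
  w <- w[keep, , drop = FALSE]
  # map to frame numbers, sorted by start
  out <- cbind(f$frame[rows[w[, 1]]], f$frame[rows[w[, 2]]])
  out[order(out[, 1]), , drop = FALSE]
}

# random track with alternating slow/fast frames and piecewise-wobbly
# headings, exercising stop detection including degenerate frames
random_stop_track <- function(n_frames, fps = 50, p_degenerate = 0.01) {
  heading <- numeric(n_frames)
  heading[1] <- runif(1, 0, 360)
  for (i in 2:n_frames) {
    u <- runif(1)
    heading[i] <- if (u < 0.15) runif(1, 0, 360)
    else if (u < 0.5) (heading[i - 1] + rnorm(1, 0, 4)) %% 360
    else heading[i - 1]
  }
  step <- ifelse(runif(n_frames) < 0.55, 0.004, 0.3)
  dir <- runif(n_frames, 0, 2 * pi)
  th <- cbind(cumsum(step * sin(dir)), cumsum(step * cos(dir)))
  bl <- ifelse(runif(n_frames) < p_degenerate, 0, 0.6)
  mand <- th + bl * cbind(sin(heading * pi / 180), cos(heading * pi / 180))
  frames <- data.frame(frame = 0:(n_frames - 1), t_s = (0:(n_frames - 1)) / fps,
                       mand_x_cm = mand[, 1], mand_y_cm = mand[, 2],
                       thor_x_cm = th[, 1], thor_y_cm = th[, 2])
  lw_track(frames, fps = fps, platform = c(-1e4, 1e4, -1e4, 1e4))
}

# exact Mardia-Watson-Wheeler permutation p by enumerating all relabelings
mww_exhaustive_p <- function(a, b) {
  n1 <- length(a); N <- n1 + length(b)
  rk <- rank(c(a, b) %% 360, ties.method = "average")
  beta <- 2 * pi * rk / N
  W_of <- function(idx1) {
    c1 <- sum(cos(beta[idx1])); s1 <- sum(sin(beta[idx1]))
    c2 <- sum(cos(beta[-idx1])); s2 <- sum(sin(beta[-idx1]))
    2 * ((c1^2 + s1^2) / n1 + (c2^2 + s2^2) / (N - n1))
  }
  W_obs <- W_of(seq_len(n1))
  splits <- utils::combn(N, n1)
  W_all <- apply(splits, 2, W_of)
  mean(W_all >= W_obs - 1e-12)
}

# straight-line track builder: thorax path plus headings, for hand-built cases
make_track <- function(thorax, heading_deg, fps = 50, body_len = 0.6,
                       nest = c(0, 0)) {
  th <- rbind(thorax)
  if (nrow(th) == 1) th <- th[rep(1, length(heading_deg)), , drop = FALSE]
  n <- nrow(th)
  mand <- th + body_len * cbind(sin(heading_deg * pi / 180),
                                cos(heading_deg * pi / 180))
  frames <- data.frame(frame = 0:(n - 1), t_s = (0:(n - 1)) / fps,
                       mand_x_cm = mand[, 1], mand_y_cm = mand[, 2],
                       thor_x_cm = th[, 1], thor_y_cm = th[, 2])
  lw_track(frames, fps = fps, nest = nest, platform = c(-1e4, 1e4, -1e4, 1e4))
}

# n = 15 sample with an exact mean resultant length r around mean direction
# mu: seven symmetric pairs at +/- d plus one angle at the center, with
# cos(d) = (15 r - 1) / 14
sample_with_r15 <- function(r, mu = 0) {
  d <- acos((15 * r - 1) / 14) * 180 / pi
  mu + c(rep(c(-d, d), 7), 0)
}
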