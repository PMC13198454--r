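# Synthetic learning-walk generator: determinism, ground-truth consistency,
# noise-free recovery, and the goal-geometry property.

test_that("a fixed seed regenerates the identical dataset", {
  s1 <- simulate_experiment(sim_config(n_ants = 2, seed = 77))
  s2 <- simulate_experiment(sim_config(n_ants = 2, seed = 77))
  expect_identical(s1$dataset[[1]]$track$frames, s2$dataset[[1]]$track$frames)
  expect_identical(s1$dataset[[2]]$annotations, s2$dataset[[2]]$annotations)
  expect_identical(s1$truth[[1]]$fictive_nest, s2$truth[[1]]$fictive_nest)
  # and a different seed does not
  s3 <- simulate_experiment(sim_config(n_ants = 2, seed = 78))
  expect_false(identical(s1$dataset[[1]]$track$frames, s3$dataset[[1]]$track$frames))
})

test_that("unanalyzable stop configurations are rejected up front", {
  expect_error(sim_config(longest_stop_ms = c(40, 80)), "100 ms")
  expect_error(sim_config(longest_stop_ms = c(240, 400), decoy_stop_ms = c(200, 300)),
               "strictly below")
})

test_that("in the noise-free limit the pipeline recovers the fictive goal at 180 deg", {
  sim <- simulate_experiment(sim_config(n_ants = 10, kappa = 1e6,
                                        alteration_deg = 120, seed = 101))
  rep <- analyze_experiment(sim$dataset)
  expect_equal(sum(rep$ants$excluded), 0)
  s <- rep$summaries$after_fictive$summary
  expect_equal(s$n, 10)
  expect_lt(abs(((s$mu_deg - 180 + 180) %% 360) - 180), 0.5)
  expect_gt(s$r, 0.999)
  # the before pirouettes fixate the real nest just as tightly
  sb <- rep$summaries$before_nest$summary
  expect_lt(abs(((sb$mu_deg - 180 + 180) %% 360) - 180), 0.5)
})

test_that("designated longest stops are recovered frame-exactly from the tracks", {
  sim <- simulate_experiment(sim_config(n_ants = 5, alteration_deg = 180, seed = 103))
  crit <- stop_criteria()
  for (i in seq_along(sim$dataset)) {
    ant <- sim$dataset[[i]]; truth <- sim$truth[[i]]
    for (p in seq_len(nrow(ant$annotations))) {
      pir <- ant$annotations[p, ]
      des <- truth$stops[truth$stops$designated &
                         truth$stops$start_frame >= pir$start &
                         truth$stops$end_frame <= pir$end, ]
      ph <- longest_stopping_phase(detect_stopping_phases(ant$track, pir, crit))
      expect_equal(ph$start_index, des$start_frame)
      expect_equal(ph$end_index, des$end_frame)
    }
  }
})

test_that("ground truth matches the emitted frames", {
  sim <- simulate_experiment(sim_config(n_ants = 3, alteration_deg = 120, seed = 104))
  for (i in 1:3) {
    ant <- sim$dataset[[i]]; truth <- sim$truth[[i]]
    f <- ant$track$frames
    # the switch-on time is a frame time inside the track span
    expect_true(truth$switch_on_t >= min(f$t_s) && truth$switch_on_t <= max(f$t_s))
    expect_equal(ant$event$switch_on_t, truth$switch_on_t)
    # fictive nest re-derives from the mandible at the switch-on frame
    sw <- which(f$t_s >= truth$switch_on_t)[1]
    mand <- c(f$mand_x_cm[sw], f$mand_y_cm[sw])
    expect_equal(truth$mandible_at_switch, mand, tolerance = 1e-9)
    expect_equal(truth$fictive_nest, fictive_nest(mand, c(0, 0), 120), tolerance = 1e-9)
    # designated stop headings equal goal bearing + drawn error, frame by frame
    des <- truth$stops[truth$stops$designated, ]
    h <- track_headings(ant$track)
    for (k in seq_len(nrow(des))) {
      rows <- which(f$frame >= des$start_frame[k] & f$frame <= des$end_frame[k])
      expect_true(all(circ_dist(h[rows], des$heading_deg[k]) < 1e-9))
      expect_equal(des$heading_deg[k],
                   (des$goal_bearing_deg[k] + des$gaze_error_deg[k]) %% 360,
                   tolerance = 1e-9)
    }
    # pirouettes happen at analyzable distances from the nest
    m <- cbind(f$mand_x_cm, f$mand_y_cm)
    for (p in seq_len(nrow(ant$annotations))) {
      rows <- which(f$frame >= ant$annotations$start[p] & f$frame <= ant$annotations$end[p])
      expect_gt(sqrt(sum(colMeans(m[rows, ])^2)), 5)
    }
  }
})

test_that("with kappa = 0 the after/fictive gazes are uniform: nominal rejection rate", {
  set.seed(105)
  rejections <- replicate(200, {
    sim <- simulate_experiment(sim_config(n_ants = 8, kappa = 0, alteration_deg = 120))
    rep <- analyze_experiment(sim$dataset)
    s <- rep$summaries$after_fictive$summary
    !is.null(s) && s$p < 0.05
  })
  expect_gte(mean(rejections), 0.01)
  expect_lte(mean(rejections), 0.10)
})

test_that("the after nest-vs-fictive gaze difference equals theta almost nowhere", {
  sim <- simulate_experiment(sim_config(n_ants = 30, alteration_deg = 120, seed = 106))
  rep <- analyze_experiment(sim$dataset)
  ok <- !rep$ants$excluded
  d <- rep$ants$after_gaze_nest_deg[ok] - rep$ants$after_gaze_fictive_deg[ok]
  frac <- mean(abs((((d - 120) + 180) %% 360) - 180) < 0.1)
  expect_lt(frac, 0.01)
})

test_that("the von Mises sampler is calibrated", {
  set.seed(107)
  # concentration: mean resultant length approaches A(kappa) = I1/I0
  x <- rvonmises_deg(20000, mu = 90, kappa = 8)
  s <- circ_mean_and_r(x)
  expect_lt(abs(s$mu_deg - 90), 2)
  a8 <- besselI(8, 1) / besselI(8, 0)
  expect_lt(abs(s$r - a8), 0.01)
  # kappa = 0 reduces to the circular uniform
  u <- rvonmises_deg(20000, kappa = 0)
  expect_lt(circ_mean_and_r(u)$r, 0.02)
  expect_gt(suppressWarnings(ks.test(u / 360, "punif")$p.value), 0.001)
})
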