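# Headings, bearings, relative gaze, fictive nest, speeds, pirouette selection.

test_that("heading and bearing azimuths follow the clockwise-from-north convention", {
  expect_equal(heading_azimuth(c(0, 1), c(0, 0)), 0)
  expect_equal(heading_azimuth(c(1, 0), c(0, 0)), 90)
  expect_equal(heading_azimuth(c(0, 0), c(1, 1)), 225)
  expect_error(heading_azimuth(c(1, 1), c(1, 1)), "degenerate")

  expect_equal(bearing(c(0, 0), c(0, 5)), 0)
  expect_equal(bearing(c(0, 0), c(-1, 0)), 270)
  expect_equal(bearing(c(2, 3), c(5, 3)), 90)
  expect_error(bearing(c(1, 2), c(1, 2)), "coincident")
})

test_that("relative gaze maps goal fixation to 180 and anti-fixation to 0", {
  # ant at origin facing north, goal due north
  expect_equal(relative_gaze(0, c(0, 0), c(0, 10)), 180)
  # facing north, goal due east (bearing 90)
  expect_equal(relative_gaze(0, c(0, 0), c(10, 0)), 90)
  # facing exactly away from the goal
  expect_equal(relative_gaze(180, c(0, 0), c(0, 10)), 0)
  expect_error(relative_gaze(0, c(1, 1), c(1, 1)), "coincident")
})

test_that("relative gaze is invariant under a global rotation of the arena", {
  set.seed(31)
  rot <- function(p, phi) {
    th <- phi * pi / 180
    c(p[1] * cos(th) + p[2] * sin(th), -p[1] * sin(th) + p[2] * cos(th))
  }
  for (i in 1:100) {
    m <- runif(2, -20, 20); g <- runif(2, -20, 20)
    if (all(m == g)) next
    h <- runif(1, 0, 360); phi <- runif(1, 0, 360)
    expect_equal(relative_gaze((h + phi) %% 360, rot(m, phi), rot(g, phi)),
                 relative_gaze(h, m, g), tolerance = 1e-9)
  }
})

test_that("fictive nest rotates the mandible-nest vector with the field sign convention", {
  expect_equal(fictive_nest(c(10, 0), c(0, 0), 180), c(20, 0), tolerance = 1e-12)
  expect_equal(fictive_nest(c(3, 4), c(1, -2), 360), c(1, -2), tolerance = 1e-9)
  expect_equal(fictive_nest(c(0, 0), c(0, 10), 120),
               c(10 * sin(2 * pi / 3), 10 * cos(2 * pi / 3)), tolerance = 1e-12)
  expect_error(fictive_nest(c(1, 1), c(1, 1), 90), "coincides")

  set.seed(32)
  for (i in 1:50) {
    m <- runif(2, -20, 20); nst <- runif(2, -20, 20)
    t1 <- runif(1, -360, 360); t2 <- runif(1, -360, 360)
    f <- fictive_nest(m, nst, t1)
    # distance to the pivot is preserved
    expect_equal(sqrt(sum((f - m)^2)), sqrt(sum((nst - m)^2)), tolerance = 1e-9)
    # rotations about the same pivot compose additively
    expect_equal(fictive_nest(m, f, t2), fictive_nest(m, nst, t1 + t2),
                 tolerance = 1e-9)
  }
})

test_that("the nest/fictive gaze difference almost never equals the alteration angle", {
  # the angular offset between the two goals as seen by the ant depends on
  # where the ant stands; it matches theta only on a measure-zero locus
  set.seed(33)
  theta <- 120
  hits <- 0L
  for (i in 1:1000) {
    nst <- c(0, 0)
    sw <- runif(2, -25, 25)                   # mandible at switch-on
    fict <- fictive_nest(sw, nst, theta)
    m <- runif(2, -25, 25); h <- runif(1, 0, 360)
    rn <- relative_gaze(h, m, nst); rf <- relative_gaze(h, m, fict)
    d <- abs((((rn - rf) - theta + 180) %% 360) - 180)
    if (d < 0.1) hits <- hits + 1L
  }
  expect_lt(hits / 1000, 0.01)
})

test_that("forward and angular speeds are central differences with circular wrapping", {
  # thorax advancing 1 cm per frame at 50 fps
  tr <- make_track(cbind(0:9, 0), rep(0, 10))
  expect_equal(forward_speed(tr), rep(50, 10))
  # stationary thorax
  tr0 <- make_track(matrix(0, 5, 2), rep(10, 5))
  expect_equal(forward_speed(tr0), rep(0, 5))
  # heading stepping +2 deg/frame -> 100 deg/s, including across the 360 wrap
  h <- (355 + 2 * (0:9)) %% 360
  tra <- make_track(matrix(0, 10, 2), h)
  expect_equal(angular_speed(tra), rep(100, 10))
  # constant heading -> 0
  expect_equal(angular_speed(tr0), rep(0, 5))
})

test_that("pirouette selection picks last-before and first-after with the 5 cm rule", {
  # stationary hand-built track: frames 0-99, nest at origin
  th <- matrix(8, 100, 2)
  tr <- make_track(th, rep(0, 100))
  ev <- coil_event(switch_on_t = 1.0, alteration_deg = 180)

  ann <- pirouette_annotations(c(10, 60), c(30, 80))
  sel <- select_pirouettes(tr, ann, ev)
  expect_equal(sel$before$start, 10)
  expect_equal(sel$after$start, 60)

  # a pre-event pirouette too close to the nest is skipped in favor of a
  # farther one
  th2 <- rbind(matrix(c(1.2, 1.2), 20, 2, byrow = TRUE),   # ~1.7 cm from nest
               matrix(c(6, 6), 30, 2, byrow = TRUE),       # ~8.5 cm
               matrix(c(7, 7), 50, 2, byrow = TRUE))
  tr2 <- make_track(th2, rep(0, 100))
  ann2 <- pirouette_annotations(c(2, 25, 60), c(18, 45, 80))
  sel2 <- select_pirouettes(tr2, ann2, ev)
  expect_equal(sel2$before$start, 25)

  # no post-event candidate is a reported absence, not an error
  ann3 <- pirouette_annotations(10, 30)
  sel3 <- select_pirouettes(tr, ann3, ev)
  expect_null(sel3$after)
  expect_match(sel3$after_reason, "no candidate after switch-on")
})
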