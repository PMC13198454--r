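# Magnetic field vector algebra and coil-alteration geometry.

test_that("component <-> declination/inclination/intensity conversion matches magnetometer rows", {
  d1 <- dib_from_xyz(field_xyz(26.824, -0.022, 39.922))
  expect_lt(abs(d1$intensity - 48.095), 0.01)
  expect_lt(abs(d1$declination - 0), 0.1)
  expect_lt(abs(d1$inclination - 56.0), 0.2)

  d2 <- dib_from_xyz(field_xyz(26.551, 0.015, 37.955))
  expect_lt(abs(d2$intensity - 46.323), 0.01)

  # pure vertical field: declination undefined, not defaulted
  dv <- dib_from_xyz(field_xyz(0, 0, 10))
  expect_equal(dv$inclination, 90)
  expect_equal(dv$intensity, 10)
  expect_true(is.na(dv$declination))
})

test_that("xyz_from_dib inverts dib_from_xyz", {
  expect_equal(unlist(xyz_from_dib(field_dib(0, 0, 1))[c("x", "y", "z")]),
               c(x = 1, y = 0, z = 0), tolerance = 1e-12)
  expect_equal(unlist(xyz_from_dib(field_dib(90, 0, 1))[c("x", "y", "z")]),
               c(x = 0, y = 1, z = 0), tolerance = 1e-9)

  f <- xyz_from_dib(field_dib(0, 56.11, 48.097))
  expect_lt(abs(f$x - 26.824), 0.01)
  expect_lt(abs(f$z - 39.922), 0.01)

  # round trip on random fields
  set.seed(11)
  for (i in 1:50) {
    d0 <- field_dib(runif(1, -179, 180), runif(1, -89, 89), runif(1, 1, 100))
    d1 <- dib_from_xyz(xyz_from_dib(d0))
    expect_equal(d1$declination, d0$declination, tolerance = 1e-9)
    expect_equal(d1$inclination, d0$inclination, tolerance = 1e-9)
    expect_equal(d1$intensity, d0$intensity, tolerance = 1e-9)
  }
})

test_that("coil field magnitude follows 2 b_h sin(theta/2) with the two classical special cases", {
  expect_equal(coil_field_for_alteration(180, 26.824)$b_coil, 2 * 26.824, tolerance = 1e-12)
  expect_equal(coil_field_for_alteration(120, 1)$b_coil, 2 * cos(pi / 6), tolerance = 1e-12)
  expect_equal(coil_field_for_alteration(0, 26.824)$b_coil, 0)
  expect_error(coil_field_for_alteration(90, -1), "b_h_gmf")

  # generated-field azimuth (theta/2 + 90) and the coil frame geometry
  p <- coil_field_for_alteration(120, 1)
  expect_equal(p$axis_azimuth_deg, 150, tolerance = 1e-9)
  expect_equal(p$axis_line_from_ns_deg, 30, tolerance = 1e-9)
  expect_equal(p$coil_plane_from_ns_deg, 60, tolerance = 1e-9)
  expect_equal(coil_field_for_alteration(180, 1)$axis_azimuth_deg, 180, tolerance = 1e-9)

  # strictly increasing in theta on (0, 180]
  th <- seq(1, 180, by = 1)
  b <- vapply(th, function(t) coil_field_for_alteration(t, 5)$b_coil, numeric(1))
  expect_true(all(diff(b) > 0))
})

test_that("superposition is componentwise and realizes the designed alteration", {
  s <- superpose(field_xyz(1, 0, 0), field_xyz(0, 1, 0))
  expect_equal(c(s$x, s$y, s$z), c(1, 1, 0))
  s0 <- superpose(field_xyz(1, 0, 0), field_xyz(-1, 0, 0))
  expect_equal(c(s0$x, s0$y, s0$z), c(0, 0, 0))

  # independent trigonometric construction of the coil vector: rotate the
  # measured horizontal component eastward by 120 deg and subtract
  gmf <- field_xyz(26.551, 0.015, 37.955)
  th <- 120 * pi / 180
  rot <- c(gmf$x * cos(th) - gmf$y * sin(th), gmf$x * sin(th) + gmf$y * cos(th))
  coil <- field_xyz(rot[1] - gmf$x, rot[2] - gmf$y, 0)
  tot <- superpose(gmf, coil)
  d <- dib_from_xyz(tot)
  expect_lt(abs(d$declination - 120.03), 0.1)
  expect_lt(abs(sqrt(tot$x^2 + tot$y^2) - 26.551), 0.01)
})

test_that("predict_altered_field shifts declination by theta and preserves everything else", {
  g <- field_xyz(26.824, 0, 39.922)
  expect_equal(unlist(predict_altered_field(g, 0)[c("x", "y", "z")]),
               unlist(g[c("x", "y", "z")]), tolerance = 1e-12)
  r180 <- predict_altered_field(g, 180)
  expect_equal(c(r180$x, r180$y, r180$z), c(-26.824, 0, 39.922), tolerance = 1e-9)
  r120 <- predict_altered_field(field_xyz(1, 0, 0), 120)
  expect_equal(c(r120$x, r120$y, r120$z), c(cos(2 * pi / 3), sin(2 * pi / 3), 0),
               tolerance = 1e-12)
  expect_error(predict_altered_field(field_xyz(0, 0, 10), 90), "horizontal")

  set.seed(21)
  for (i in 1:50) {
    g <- xyz_from_dib(field_dib(runif(1, -179, 180), runif(1, -80, 80), runif(1, 5, 80)))
    theta <- runif(1, 0.5, 359.5)
    a <- predict_altered_field(g, theta)
    h0 <- sqrt(g$x^2 + g$y^2); h1 <- sqrt(a$x^2 + a$y^2)
    expect_equal(h1, h0, tolerance = 1e-9)
    expect_identical(a$z, g$z)
    shift <- (dib_from_xyz(a)$declination - dib_from_xyz(g)$declination) %% 360
    expect_lt(min(abs(shift - theta), abs(shift - theta + 360), abs(shift - theta - 360)),
              1e-9)
  }
})

test_that("verify_alteration reports per-check deviations against the measured rows", {
  g <- field_xyz(3, 4, 5)
  expect_true(attr(verify_alteration(g, g, 0, tol_deg = 1, tol_ut = 0.1), "pass"))

  fields <- read_field_measurements(system.file("extdata", "field_measurements.csv",
                                                package = "antgaze"))
  meta <- attr(fields, "meta")
  before <- fields[[which(meta$experiment == 2 & meta$condition == "before")]]
  after <- fields[[which(meta$experiment == 2 & meta$condition == "after")]]

  # the +120 deg pair verifies at 3 deg / 2 uT ...
  v <- verify_alteration(before, after, 120, tol_deg = 3, tol_ut = 2)
  expect_true(attr(v, "pass"))
  # ... but the measured declination shift (~117.6 deg) fails a 0.5 deg bound
  v2 <- verify_alteration(before, after, 120, tol_deg = 0.5, tol_ut = 2)
  expect_false(v2$pass[v2$check == "declination_shift"])
  # and the measured horizontal magnitude grew by ~1.7 uT, beyond a 1 uT bound
  v3 <- verify_alteration(before, after, 120, tol_deg = 3, tol_ut = 1)
  expect_false(v3$pass[v3$check == "horizontal_magnitude"])
  expect_lt(abs(v3$deviation[v3$check == "horizontal_magnitude"] - 1.72), 0.05)
})

test_that("field measurements load from CSV with either column convention", {
  path <- system.file("extdata", "field_measurements.csv", package = "antgaze")
  fields <- read_field_measurements(path)
  expect_length(fields, 4)
  expect_equal(fields[[1]]$x, 26.824)

  # angular-form input reconstructs components
  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(declination = 0, inclination = 56.11, intensity = 48.097),
            tmp, row.names = FALSE)
  f <- read_field_measurements(tmp)[[1]]
  expect_lt(abs(f$x - 26.824), 0.01)
  unlink(tmp)
})
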