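test_that("moment-based ellipse fit recovers orientation and axes", {
  # axis-aligned ellipse: orientation 0
  m0 <- oracle_ellipse_mask(60, 80, c(40, 30), 20, 10, 0)
  f0 <- fit_ellipse(m0)
  expect_lt(abs(f0$orientation_deg), 0.1)
  expect_lt(abs(f0$semi_major - 20), 0.5)
  expect_lt(abs(f0$semi_minor - 10), 0.5)
  expect_lt(max(abs(c(f0$center_x, f0$center_y) - c(40, 30))), 0.1)

  # rotated ellipses: fitted angle within 0.5 deg of the drawn one
  for (ang in c(-75, -30, 10, 30, 45, 80)) {
    f <- fit_ellipse(oracle_ellipse_mask(80, 80, c(40, 40), 22, 11, ang))
    expect_lt(abs(f$orientation_deg - ang), 0.5)
  }

  # circle: orientation undefined
  fc <- fit_ellipse(oracle_ellipse_mask(60, 60, c(30, 30), 15, 15, 0))
  expect_false(fc$eccentricity_ok)
  expect_true(is.na(fc$orientation_deg))

  expect_error(fit_ellipse(matrix(FALSE, 5, 5)), "empty")
})

test_that("fit agrees with an independent moment implementation", {
  skip_if_not_installed("EBImage")
  for (ang in c(-60, 15, 70)) {
    m <- oracle_ellipse_mask(90, 90, c(45, 45), 25, 10, ang)
    f <- fit_ellipse(m)
    ref <- EBImage::computeFeatures.moment(t(m) * 1)
    # EBImage measures theta with the y-axis pointing down, i.e.
    # clockwise-positive in the y-up convention used here
    ref_deg <- -ref[1, "m.theta"] * 180 / pi
    d <- abs(f$orientation_deg - ref_deg) %% 180
    expect_lt(min(d, 180 - d), 0.5)
    expect_equal(f$semi_major, unname(ref[1, "m.majoraxis"] / 2),
                 tolerance = 0.02)
  }
})

test_that("orientation is invariant to translation and uniform scaling", {
  base <- fit_ellipse(oracle_ellipse_mask(260, 260, c(70, 70), 40, 20, 25))
  moved <- fit_ellipse(oracle_ellipse_mask(260, 260, c(160, 140), 40, 20, 25))
  scaled <- fit_ellipse(oracle_ellipse_mask(260, 260, c(130, 130), 120, 60, 25))
  expect_lt(abs(base$orientation_deg - moved$orientation_deg), 0.1)
  expect_lt(abs(base$orientation_deg - scaled$orientation_deg), 0.1)
})

test_that("rotating a mask rotates the fitted orientation equivariantly", {
  for (phi in c(-40, 20, 65)) {
    a <- fit_ellipse(oracle_ellipse_mask(200, 200, c(100, 100), 60, 30, 10))
    b <- fit_ellipse(oracle_ellipse_mask(200, 200, c(100, 100), 60, 30,
                                         10 + phi))
    d <- (b$orientation_deg - a$orientation_deg - phi) %% 180
    expect_lt(min(d, 180 - d), 0.5)
  }
})

test_that("segmentation finds the rendered eyes", {
  geom <- render_geometry()
  stack <- render_frames(
    tibble::tibble(time_s = 0, left_deg = 20, right_deg = -35), geom
  )
  masks <- segment_eyes(stack$frames[, , 1], geom$rois)
  drawn_area <- pi * geom$semi_major * geom$semi_minor
  for (m in masks) {
    expect_false(is.null(m))
    expect_lt(abs(sum(m) - drawn_area) / drawn_area, 0.05)
  }
  # blank frame: both eyes missing
  blank <- matrix(200, 120, 200)
  expect_true(all(vapply(segment_eyes(blank, geom$rois), is.null,
                         logical(1))))
  # ROI outside the frame
  bad <- geom$rois
  bad$left["x_max"] <- 999
  expect_error(segment_eyes(stack$frames[, , 1], bad), "outside")
})

test_that("render_frames validates its geometry", {
  expect_error(render_geometry(semi_major = 10, semi_minor = 10),
               "orientation is undefined")
  expect_error(
    render_geometry(left_center = c(90, 60), right_center = c(110, 60)),
    "overlap"
  )
})

test_that("tracking a rendered sinusoidal rotation stays within 0.5 deg RMSE", {
  t <- seq(0, 4, by = 1 / 15)
  angles <- tibble::tibble(
    time_s = t,
    left_deg = 10 * sin(2 * pi * t / 4),
    right_deg = 10 * sin(2 * pi * t / 4 + 0.2)
  )
  stack <- render_frames(angles)
  track <- track_eyes(stack)
  expect_true(all(track$left_ok))
  rmse_l <- sqrt(mean((track$left_deg - angles$left_deg)^2))
  rmse_r <- sqrt(mean((track$right_deg - angles$right_deg)^2))
  expect_lt(rmse_l, 0.5)
  expect_lt(rmse_r, 0.5)
})

test_that("constant-angle phantom yields a constant series", {
  angles <- tibble::tibble(time_s = 0:5, left_deg = 15, right_deg = 15)
  track <- track_eyes(render_frames(angles))
  expect_lt(diff(range(track$left_deg)), 0.2)
})

test_that("unwrapping removes 180-deg jumps when crossing +90 deg", {
  true_deg <- seq(80, 100, by = 2) # crosses +90; raw fits flip to -90+
  angles <- tibble::tibble(time_s = seq_along(true_deg),
                           left_deg = true_deg, right_deg = true_deg)
  track <- track_eyes(render_frames(angles))
  expect_true(all(abs(diff(track$left_deg)) < 20))
  expect_lt(max(abs(track$left_deg - true_deg)), 1) # raster-limited accuracy
})
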