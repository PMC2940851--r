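test_that("principal-axis angle tracks the phantom orientation", {
  for (ang in c(0, -60, -30, -10, 10, 30, 45, 60)) {
    spec <- small_spec(disc_angle_deg = ang)
    ph <- generate_disc_phantom(spec)
    m <- nucleus_mask(ph$truth$nucleus_mask, ph$slice)
    fr <- estimate_disc_frame(m, ph$slice)
    expect_lt(abs(fr$angle_deg - ang), 1, label = paste("angle", ang))
    expect_equal(sum(fr$longitudinal_axis * fr$perpendicular_axis), 0,
                 tolerance = 1e-12)
  }
})

test_that("an isotropic mask falls back to the x-axis with a warning", {
  spec <- small_spec(disc_semi_axes_mm = c(6, 6),
                     nucleus_semi_axes_mm = c(3.5, 3.5))
  ph <- generate_disc_phantom(spec)
  m <- nucleus_mask(ph$truth$nucleus_mask, ph$slice)
  expect_warning(fr <- estimate_disc_frame(m, ph$slice),
                 class = "discmetrics_ambiguous_axis")
  expect_equal(fr$angle_deg, 0)
  expect_true(fr$ambiguous)
})

test_that("frame origin sits on the axis line at the posterior mask end", {
  spec <- small_spec(disc_angle_deg = 20, nucleus_offset_mm = 1)
  ph <- generate_disc_phantom(spec)
  m <- nucleus_mask(ph$truth$nucleus_mask, ph$slice)
  fr <- estimate_disc_frame(m, ph$slice)
  idx <- which(m$mask, arr.ind = TRUE)
  sp <- ph$slice$pixel_spacing_mm
  px <- (idx[, 2] - 0.5) * sp[2]; py <- (idx[, 1] - 0.5) * sp[1]
  ctr <- c(mean(px), mean(py))
  # origin lies on the longitudinal line through the centroid...
  expect_equal(sum((fr$origin_mm - ctr) * fr$perpendicular_axis), 0,
               tolerance = 1e-9)
  # ... at the minimum masked projection
  proj <- (px - fr$origin_mm[1]) * fr$longitudinal_axis[1] +
    (py - fr$origin_mm[2]) * fr$longitudinal_axis[2]
  expect_equal(min(proj), 0, tolerance = 1e-9)

  al <- to_disc_frame(ph$slice, m, fr)
  expect_true(all(al$axis_positions_mm >= 0))
  expect_equal(diff(al$axis_positions_mm),
               rep(al$pixel_spacing_mm, length(al$axis_positions_mm) - 1),
               tolerance = 1e-9)
  expect_equal(al$axis_positions_mm[1], 0, tolerance = 1e-9)
  expect_equal(al$conservation, 1, tolerance = 1e-9)
  expect_lt(abs(al$resample_bias - 1), 0.05)
})

test_that("an angle-0 frame reproduces the input raster exactly", {
  spec <- small_spec(intensity_gradient = 0.7, intensity_curvature = 0.3)
  ph <- generate_disc_phantom(spec)
  m <- nucleus_mask(ph$truth$nucleus_mask, ph$slice)
  fr <- truth_frame(ph$truth, ph$slice, 0)
  al <- to_disc_frame(ph$slice, m, fr)
  expect_equal(al$conservation, 1, tolerance = 1e-12)
  expect_equal(al$resample_bias, 1, tolerance = 1e-12)
  expect_equal(sum(al$intensity[al$mask]),
               sum(ph$slice$intensity[m$mask]), tolerance = 1e-12)
  expect_equal(sum(al$mask), sum(m$mask))
})

test_that("shifting the phantom by whole pixels changes no metric", {
  s1 <- small_spec(intensity_gradient = 0.7)
  s2 <- small_spec(disc_center_mm = c(45, 50), intensity_gradient = 0.7)
  a1 <- analyze_disc(generate_disc_phantom(s1)$slice, seed_at_nucleus(s1))
  a2 <- analyze_disc(generate_disc_phantom(s2)$slice, seed_at_nucleus(s2))
  expect_equal(analysis_metrics(a1), analysis_metrics(a2), tolerance = 1e-12)
})

test_that("a quarter-turn of the raster changes metrics by at most one pixel / 1%", {
  spec <- small_spec(intensity_gradient = 0.8, nucleus_offset_mm = 1.5,
                     intensity_curvature = 0.3)
  ph <- generate_disc_phantom(spec)
  img <- ph$slice$intensity
  rot <- t(img[nrow(img):1, ])            # clockwise quarter turn
  sl_rot <- sagittal_slice(rot, ph$slice$pixel_spacing_mm)
  seed <- seed_at_nucleus(spec)
  seed_rot <- c(seed[2], nrow(img) - seed[1] + 1L)
  a0 <- analyze_disc(ph$slice, seed)
  a90 <- analyze_disc(sl_rot, seed_rot)
  expect_equal(a90$frame$angle_deg, 90, tolerance = 1e-6)
  h <- min(ph$slice$pixel_spacing_mm)
  expect_lt(abs(a90$metrics$DX_mm - a0$metrics$DX_mm), h)
  expect_lt(abs(a90$metrics$H_mm - a0$metrics$H_mm), h + 1e-9)
  expect_lt(abs(a90$metrics$PSM_mm - a0$metrics$PSM_mm), h + 1e-9)
  expect_lt(abs(a90$metrics$SM / a0$metrics$SM - 1), 0.01)
})

test_that("frame/slice congruence is checked", {
  ph <- generate_disc_phantom(small_spec())
  m <- nucleus_mask(ph$truth$nucleus_mask, ph$slice)
  other <- sagittal_slice(matrix(10, 16, 16), 1)
  fr <- estimate_disc_frame(m, ph$slice)
  expect_error(to_disc_frame(other, m, fr), "congruent")
})
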