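test_that("spec validation names the offending field", {
  expect_error(phantom_spec(nucleus_intensity = 20), "nucleus_intensity")
  expect_error(phantom_spec(pixel_spacing_mm = -1), "pixel_spacing_mm")
  expect_error(phantom_spec(nucleus_semi_axes_mm = c(25, 3)), "contained")
  expect_error(phantom_spec(nucleus_offset_mm = 15), "contained")
  expect_error(phantom_spec(intensity_curvature = 1.2), "intensity_curvature")
  expect_error(phantom_spec(intensity_gradient = 20), "intensity_gradient")
  expect_error(phantom_spec(noise_sigma = -1), "noise_sigma")
})

test_that("default pixel grid spans a 320 mm field of view", {
  spec <- phantom_spec()
  expect_equal(spec$image_shape * spec$pixel_spacing_mm, c(320, 320))
  ph <- generate_disc_phantom(spec)
  expect_equal(dim(ph$slice$intensity), c(512L, 512L))
})

test_that("oracle centres agree with direct Eq.-style sums on the raster", {
  for (g in c(0, 0.9)) {
    spec <- small_spec(intensity_gradient = g)
    ph <- generate_disc_phantom(spec)
    # independent vectorized route over the noiseless raster
    idx <- which(ph$truth$nucleus_mask, arr.ind = TRUE)
    sp <- spec$pixel_spacing_mm
    px <- (idx[, 2] - 0.5) * sp[2]
    py <- (idx[, 1] - 0.5) * sp[1]
    si <- ph$slice$intensity[idx]   # noiseless (noise_sigma = 0)
    expect_equal(ph$truth$true_weighted_center_mm,
                 c(sum(px * si), sum(py * si)) / sum(si), tolerance = 1e-12)
    expect_equal(ph$truth$true_geometric_center_mm, c(mean(px), mean(py)),
                 tolerance = 1e-12)
    if (g == 0) {
      expect_identical(ph$truth$true_DX_mm, 0)
    } else {
      expect_gt(ph$truth$true_signed_DX_mm, 0)
    }
  }
})

test_that("plateau scaling and nucleus-offset translation behave as stated", {
  base <- small_spec(intensity_gradient = 0.6, intensity_curvature = 0.3)
  ph1 <- generate_disc_phantom(base)
  cc <- 3.5
  scaled <- small_spec(nucleus_intensity = base$nucleus_intensity * cc,
                       annulus_intensity = base$annulus_intensity * cc,
                       background_intensity = base$background_intensity * cc,
                       intensity_gradient = base$intensity_gradient * cc,
                       intensity_curvature = 0.3)
  ph2 <- generate_disc_phantom(scaled)
  expect_equal(ph2$truth$true_SM, cc * ph1$truth$true_SM, tolerance = 1e-12)
  expect_equal(ph2$truth$true_DX_mm, ph1$truth$true_DX_mm, tolerance = 1e-12)
  expect_identical(ph2$truth$true_H_mm, ph1$truth$true_H_mm)
  expect_identical(ph2$truth$true_PSM_mm, ph1$truth$true_PSM_mm)

  # translating the nucleus moves the disc-anchored PSM, not the
  # nucleus-anchored one
  off <- generate_disc_phantom(small_spec(nucleus_offset_mm = 2,
                                          intensity_curvature = 0.4))
  ctr <- generate_disc_phantom(small_spec(intensity_curvature = 0.4))
  h <- 0.625
  expect_lt(abs(off$truth$true_PSM_disc_mm - ctr$truth$true_PSM_disc_mm - 2),
            h + 1e-9)
  expect_lt(abs(off$truth$true_PSM_mm - ctr$truth$true_PSM_mm), h + 1e-9)
})

test_that("noisy phantoms are deterministic given the seed", {
  spec <- small_spec(noise_sigma = 5, rng_seed = 42L)
  ph1 <- generate_disc_phantom(spec)
  ph2 <- generate_disc_phantom(spec)
  expect_identical(ph1$slice$intensity, ph2$slice$intensity)
  expect_true(min(ph1$slice$intensity) >= 0)  # clipped at zero
})

test_that("cohort generation: counts, determinism, degenerate model", {
  m <- effect_model(n_per_cell = 5L, rng_seed = 11L)
  co <- generate_cohort(m, slices = FALSE)
  expect_length(co, 30L)
  rec <- cohort_truth_records(co)
  expect_equal(unname(table(rec$pathology, rec$severity)),
               matrix(5L, 2, 3), ignore_attr = TRUE)
  co2 <- generate_cohort(m, slices = FALSE)
  expect_identical(cohort_truth_records(co2), rec)

  flat <- matrix(10, 2, 3)
  m0 <- effect_model(mean_long_semi_axis = flat,
                     mean_perp_semi_axis = matrix(3.5, 2, 3),
                     mean_intensity = matrix(80, 2, 3),
                     sd_long_semi_axis = 0, sd_perp_semi_axis = 0,
                     sd_intensity = 0, sd_offset = 0, sd_gradient = 0,
                     mean_curvature = 0.3, sd_curvature = 0,
                     n_per_cell = 5L, rng_seed = 1L)
  r0 <- cohort_truth_records(generate_cohort(m0, slices = FALSE))
  for (v in c("DX_mm", "H_mm", "SM", "PSM_mm"))
    expect_length(unique(r0[[v]]), 1L)

  expect_error(effect_model(n_per_cell = 1L), "n_per_cell")
  expect_error(effect_model(mean_intensity = matrix(1, 3, 2)), "2x3")
})
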