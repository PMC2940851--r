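test_that("weighted centre is the intensity-weighted mean of pixel centres", {
  al <- aligned_stub(matrix(c(1, 1, 2), 1, 3))
  expect_equal(unname(weighted_center(al)["longitudinal"]), 1.25)

  uni <- aligned_stub(matrix(7, 4, 5))
  uni$mask[1, ] <- FALSE
  expect_equal(weighted_center(uni), geometric_center_for_test(uni),
               tolerance = 1e-12)

  z <- aligned_stub(matrix(0, 2, 2))
  expect_error(weighted_center(z), "zero-mass")
})

test_that("DX is the longitudinal centre offset, invariant to intensity scale", {
  sym <- generate_disc_phantom(small_spec())
  a <- analyze_disc(sym$slice, seed_at_nucleus(small_spec()))
  expect_lt(a$metrics$DX_mm, 1e-9)

  spec <- small_spec(intensity_gradient = 0.9)
  ph <- generate_disc_phantom(spec)
  m <- nucleus_mask(ph$truth$nucleus_mask, ph$slice)
  fr <- truth_frame(ph$truth, ph$slice, 0)
  an <- analyze_disc(ph$slice, mask = m, frame = fr)
  expect_gt(an$metrics$signed_DX_mm, 0)
  expect_equal(an$metrics$signed_DX_mm, ph$truth$true_signed_DX_mm,
               tolerance = 1e-9)

  sl2 <- sagittal_slice(ph$slice$intensity * 2, ph$slice$pixel_spacing_mm)
  m2 <- nucleus_mask(ph$truth$nucleus_mask, sl2)
  an2 <- analyze_disc(sl2, mask = m2, frame = fr)
  expect_equal(an2$metrics$DX_mm, an$metrics$DX_mm, tolerance = 1e-12)
  expect_equal(an2$metrics$SM, 2 * an$metrics$SM, tolerance = 1e-12)
  expect_equal(an2$metrics$H_mm, an$metrics$H_mm)
  expect_equal(an2$metrics$PSM_mm, an$metrics$PSM_mm)
})

test_that("profile sums masked columns and conserves the masked total", {
  al <- aligned_stub(rbind(c(1, 2), c(2, 3)), spacing = 0.625)
  p <- compute_profile(al)
  expect_equal(p$sums, c(3, 5))
  expect_equal(sum(p$sums), sum(al$intensity[al$mask]))

  # only columns intersecting the mask appear
  al2 <- aligned_stub(matrix(1, 3, 4))
  al2$mask[, 4] <- FALSE
  expect_length(compute_profile(al2)$positions_mm, 3L)

  # uniform rectangle: constant profile
  expect_length(unique(compute_profile(aligned_stub(matrix(2, 3, 5)))$sums), 1L)
})

test_that("SM is the profile maximum; ties go to the posterior-most position", {
  p <- structure(list(positions_mm = c(0, 0.625), sums = c(3, 5)),
                 class = "intensity_profile")
  res <- compute_SM_PSM(p)
  expect_equal(res$SM, 5)
  expect_equal(res$PSM_mm, 0.625)
  expect_false(res$tie)

  flat <- compute_SM_PSM(compute_profile(aligned_stub(matrix(2, 3, 5))))
  expect_equal(flat$PSM_mm, 0)
  expect_true(flat$tie)

  # centre-bright phantom: unique maximum within a pixel of the centre
  spec <- small_spec(intensity_curvature = 0.4)
  ph <- generate_disc_phantom(spec)
  an <- analyze_disc(ph$slice, seed_at_nucleus(spec))
  expect_lt(abs(an$metrics$PSM_mm - spec$nucleus_semi_axes_mm[1]),
            0.625 + 1e-9)
})

test_that("H spans the mask extent perpendicular to the axis", {
  line <- aligned_stub(matrix(5, 1, 6), spacing = 0.625)
  expect_equal(compute_H(line), 0.625)

  spec <- small_spec()   # nucleus perpendicular semi-axis 3.5 mm
  ph <- generate_disc_phantom(spec)
  an <- analyze_disc(ph$slice, seed_at_nucleus(spec))
  expect_lt(abs(an$metrics$H_mm - 7), 0.625 + 1e-9)
  expect_equal(an$metrics$H_mm, ph$truth$true_H_mm)

  # centre mode equals max mode on a symmetric ellipse
  an_c <- analyze_disc(ph$slice, seed_at_nucleus(spec), h_mode = "center")
  expect_equal(an_c$metrics$H_mm, an$metrics$H_mm)
})

test_that("analysis is deterministic, carries provenance, and names failing stages", {
  spec <- small_spec(noise_sigma = 3, rng_seed = 9L)
  ph <- generate_disc_phantom(spec)
  a1 <- analyze_disc(ph$slice, seed_at_nucleus(spec))
  a2 <- analyze_disc(ph$slice, seed_at_nucleus(spec))
  expect_identical(a1$metrics, a2$metrics)
  expect_match(a1$provenance$settings_hash, "^[0-9a-f]{32}$")
  expect_error(analyze_disc(ph$slice, seed = c(-1, 1)), "segmentation")
})

test_that("an injected nucleus offset shifts PSM in a common disc frame", {
  common <- disc_frame(c(40 - 20, 40), 0)  # posterior pole of the disc
  spec0 <- small_spec(intensity_curvature = 0.4)
  spec2 <- small_spec(intensity_curvature = 0.4, nucleus_offset_mm = 2)
  p0 <- analyze_disc(generate_disc_phantom(spec0)$slice,
                     seed_at_nucleus(spec0), frame = common)
  p2 <- analyze_disc(generate_disc_phantom(spec2)$slice,
                     seed_at_nucleus(spec2), frame = common)
  expect_lt(abs(p2$metrics$PSM_mm - p0$metrics$PSM_mm - 2), 0.625 + 1e-9)
})
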