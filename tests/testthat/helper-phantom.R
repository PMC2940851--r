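# shared fixtures: compact phantoms (128 px, 80 mm field of view) keep the
# unit tests fast; acceptance tests use the full 512 px geometry

small_spec <- function(...) {
  args <- utils::modifyList(list(image_shape = c(128L, 128L),
                                 disc_center_mm = c(40, 40)),
                            list(...))
  do.call(phantom_spec, args)
}

# pixel (row, col) of the nucleus centre for any spec
seed_at_nucleus <- function(spec) {
  th <- spec$disc_angle_deg * pi / 180
  ctr <- spec$disc_center_mm + spec$nucleus_offset_mm * c(cos(th), sin(th))
  as.integer(round(c(ctr[2] / spec$pixel_spacing_mm[1],
                     ctr[1] / spec$pixel_spacing_mm[2])))
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# frame with the default nucleus-anchored origin, built from a truth mask
# and a known angle (independent of estimate_disc_frame)
truth_frame <- function(truth, slice, angle_deg = 0) {
  idx <- which(truth$nucleus_mask, arr.ind = TRUE)
  sp <- slice$pixel_spacing_mm
  px <- (idx[, 2] - 0.5) * sp[2]
  py <- (idx[, 1] - 0.5) * sp[1]
  th <- angle_deg * pi / 180
  u <- c(cos(th), sin(th))
  proj <- px * u[1] + py * u[2]
  ctr <- c(mean(px), mean(py))
  origin <- ctr + (min(proj) - sum(ctr * u)) * u
  disc_frame(origin, angle_deg)
}

# hand-built disc_aligned_image for direct metric unit tests
aligned_stub <- function(intensity, mask = NULL, spacing = 1,
                         positions = NULL, perp = NULL) {
  intensity <- as.matrix(intensity)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(intensity), ncol(intensity))
  if (is.null(positions)) positions <- (seq_len(ncol(intensity)) - 1) * spacing
  if (is.null(perp)) perp <- (seq_len(nrow(intensity)) - 1) * spacing
  structure(list(intensity = intensity, mask = mask,
                 pixel_spacing_mm = spacing,
                 axis_positions_mm = positions, perp_positions_mm = perp,
                 frame = NULL, conservation = 1),
            class = "disc_aligned_image")
}

# independent unweighted centroid of the masked aligned pixels
geometric_center_for_test <- function(al) {
  idx <- which(al$mask, arr.ind = TRUE)
  c(longitudinal = mean(al$axis_positions_mm[idx[, 2]]),
    perpendicular = mean(al$perp_positions_mm[idx[, 1]]))
}

truth_metrics <- function(truth) {
  unlist(truth[c("true_DX_mm", "true_H_mm", "true_SM", "true_PSM_mm")])
}

analysis_metrics <- function(an) {
  unlist(an$metrics[c("DX_mm", "H_mm", "SM", "PSM_mm")])
}
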