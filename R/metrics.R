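#' Intensity-weighted centre of the masked nucleus zone
#'
#' Each coordinate of the weighted centre is `sum(Xi * Si) / sum(Si)`
#' over the masked pixels, with `Xi` the pixel-centre coordinate in mm
#' (longitudinal, perpendicular) and `Si` its signal intensity. With
#' uniform intensity this reduces to the geometric centre.
#'
#' @param aligned a [to_disc_frame()] result.
#' @return Named numeric `(longitudinal, perpendicular)` in mm (frame
#'   coordinates, 0 at the frame origin).
#' @export
weighted_center <- function(aligned) {
  stopifnot(inherits(aligned, "disc_aligned_image"))
  idx <- which(aligned$mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty", call. = FALSE)
  si <- aligned$intensity[idx]
  tot <- sum(si)
  if (tot <= 0)
    stop("zero-mass: total masked intensity is zero", call. = FALSE)
  s <- aligned$axis_positions_mm[idx[, 2]]
  t <- aligned$perp_positions_mm[idx[, 1]]
  c(longitudinal = sum(s * si) / tot, perpendicular = sum(t * si) / tot)
}

# unweighted mean of masked pixel centres (the Si == 1 case)
geometric_center <- function(aligned) {
  idx <- which(aligned$mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty", call. = FALSE)
  c(longitudinal = mean(aligned$axis_positions_mm[idx[, 2]]),
    perpendicular = mean(aligned$perp_positions_mm[idx[, 1]]))
}

#' Offset DX between the weighted and geometric centres
#'
#' DX is the distance, on the longitudinal axis of the disc, between the
#' intensity-weighted centre and the geometric centre of the nucleus
#' zone. The perpendicular component is discarded. The signed value
#' (positive toward anterior, i.e. increasing longitudinal position) is
#' retained alongside the reported absolute value.
#'
#' @param aligned a [to_disc_frame()] result.
#' @return list with `signed_DX_mm` and `DX_mm = |signed_DX_mm|`.
#' @export
compute_DX <- function(aligned) {
  wc <- weighted_center(aligned)
  gc <- geometric_center(aligned)
  signed <- unname(wc["longitudinal"] - gc["longitudinal"])
  list(signed_DX_mm = signed, DX_mm = abs(signed))
}

#' Longitudinal intensity-sum profile
#'
#' For each position on the longitudinal axis (each column of the
#' disc-aligned raster intersecting the mask), sums the masked signal
#' intensities along the perpendicular axis. The profile total equals
#' the total masked intensity of the aligned raster exactly.
#'
#' @param aligned a [to_disc_frame()] result.
#' @return Object of class `intensity_profile`: `positions_mm`
#'   (increasing, 0 at the frame origin) and `sums`.
#' @export
compute_profile <- function(aligned) {
  stopifnot(inherits(aligned, "disc_aligned_image"))
  if (!any(aligned$mask)) stop("mask is empty", call. = FALSE)
  sums <- colSums(aligned$intensity * aligned$mask)
  keep <- colSums(aligned$mask) > 0
  structure(list(positions_mm = aligned$axis_positions_mm[keep],
                 sums = unname(sums[keep])),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile> %d positions, %.4g-%.4g mm, max %.4g\n",
              length(x$sums), min(x$positions_mm), max(x$positions_mm),
              max(x$sums)))
  invisible(x)
}

#' @export
plot.intensity_profile <- function(x, ...) {
  graphics::plot(x$positions_mm, x$sums, type = "h", lwd = 2,
                 xlab = "longitudinal position (mm)",
                 ylab = "perpendicular intensity sum", ...)
  sm <- compute_SM_PSM(x)
  graphics::points(sm$PSM_mm, sm$SM, pch = 19, col = "red")
  invisible(x)
}

#' Maximum intensity sum SM and its position PSM
#'
#' SM is the maximum of the perpendicular intensity sums; PSM is the
#' longitudinal position (mm) where it occurs. Ties are broken to the
#' smallest (posterior-most) position and flagged.
#'
#' @param profile an [compute_profile()] result.
#' @return list with `SM`, `PSM_mm` and `tie` (logical).
#' @export
compute_SM_PSM <- function(profile) {
  stopifnot(inherits(profile, "intensity_profile"))
  if (length(profile$sums) == 0L) stop("empty profile", call. = FALSE)
  sm <- max(profile$sums)
  at <- profile$positions_mm[profile$sums == sm]
  list(SM = sm, PSM_mm = min(at), tie = length(at) > 1L)
}

#' Nucleus height H
#'
#' The mask's extent along the perpendicular axis: the span of masked
#' rows in a column, `(max - min + 1) * spacing`, either maximized over
#' columns (`h_mode = "max"`, the default) or taken at the column
#' nearest the geometric centre (`h_mode = "center"`).
#'
#' @param aligned a [to_disc_frame()] result.
#' @param h_mode `"max"` or `"center"`.
#' @return Height in mm.
#' @export
compute_H <- function(aligned, h_mode = c("max", "center")) {
  stopifnot(inherits(aligned, "disc_aligned_image"))
  h_mode <- match.arg(h_mode)
  if (!any(aligned$mask)) stop("mask is empty", call. = FALSE)
  h <- aligned$pixel_spacing_mm
  span <- function(col) {
    r <- which(aligned$mask[, col])
    if (!length(r)) return(NA_real_)
    (max(r) - min(r) + 1) * h
  }
  cols <- which(colSums(aligned$mask) > 0)
  if (h_mode == "max") {
    max(vapply(cols, span, numeric(1)))
  } else {
    gc_l <- geometric_center(aligned)["longitudinal"]
    col <- cols[which.min(abs(aligned$axis_positions_mm[cols] - gc_l))]
    span(col)
  }
}

#' Full per-disc analysis: segmentation, frame, and the four descriptors
#'
#' Chains the pipeline on one sagittal slice: seeded region growing
#' ([segment_nucleus()]), disc-frame estimation
#' ([estimate_disc_frame()]), resampling into the frame
#' ([to_disc_frame()]), and the descriptor computations. The result is
#' deterministic given the inputs and settings; every setting is carried
#' in the provenance together with a settings hash.
#'
#' @param slice a [sagittal_slice()].
#' @param seed integer `(row, col)` seed pixel inside the nucleus.
#' @param threshold_fraction relative segmentation threshold, (0, 1].
#' @param frame optional [disc_frame()] overriding the estimated frame
#'   (e.g. an endplate-based or disc-anchored frame; positions are then
#'   measured from that frame's origin).
#' @param axis_points optional endplate axis points forwarded to
#'   [estimate_disc_frame()].
#' @param mask optional precomputed [nucleus_mask()] (e.g. a manual
#'   outline from [polygon_mask()]); skips segmentation.
#' @param h_mode height mode for [compute_H()].
#' @return Object of class `disc_analysis`: `metrics` (named list
#'   `DX_mm`, `signed_DX_mm`, `H_mm`, `SM`, `PSM_mm`), `profile`,
#'   `mask`, `frame`, `aligned`, `provenance`.
#' @examples
#' ph <- generate_disc_phantom(phantom_spec())
#' an <- analyze_disc(ph$slice, seed = c(256, 256))
#' an$metrics$H_mm
#' @export
analyze_disc <- function(slice, seed = NULL, threshold_fraction = 0.5,
                         frame = NULL, axis_points = NULL, mask = NULL,
                         h_mode = c("max", "center")) {
  h_mode <- match.arg(h_mode)
  frame_supplied <- !is.null(frame)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  if (is.null(mask)) {
    if (is.null(seed))
      stop("stage 'segmentation': a seed (or a precomputed mask) is required",
           call. = FALSE)
    mask <- stage("segmentation",
                  segment_nucleus(slice, seed, threshold_fraction))
  }
  if (is.null(frame))
    frame <- stage("frame", estimate_disc_frame(mask, slice, axis_points))
  aligned <- stage("resampling", to_disc_frame(slice, mask, frame))
  dx <- stage("metrics", compute_DX(aligned))
  profile <- stage("metrics", compute_profile(aligned))
  smpsm <- stage("metrics", compute_SM_PSM(profile))
  hh <- stage("metrics", compute_H(aligned, h_mode))
  settings <- list(threshold_fraction = mask$provenance$threshold_fraction,
                   segmentation = mask$provenance$method,
                   h_mode = h_mode,
                   frame_supplied = frame_supplied,
                   axis_points_supplied = !is.null(axis_points))
  prov <- list(settings = c(list(seed = mask$provenance$seed), settings),
               settings_hash = settings_hash(settings),
               frame_angle_deg = frame$angle_deg,
               ambiguous_axis = isTRUE(frame$ambiguous),
               border_leak = isTRUE(mask$provenance$border_leak),
               sm_tie = smpsm$tie,
               resample_bias = aligned$resample_bias)
  structure(list(metrics = list(DX_mm = dx$DX_mm,
                                signed_DX_mm = dx$signed_DX_mm,
                                H_mm = hh,
                                SM = smpsm$SM,
                                PSM_mm = smpsm$PSM_mm),
                 profile = profile, mask = mask, frame = frame,
                 aligned = aligned, provenance = prov),
            class = "disc_analysis")
}

#' @export
print.disc_analysis <- function(x, ...) {
  m <- x$metrics
  cat("<disc_analysis>\n")
  cat(sprintf("  DX  %8.3f mm   (signed %+.3f)\n", m$DX_mm, m$signed_DX_mm))
  cat(sprintf("  H   %8.3f mm\n", m$H_mm))
  cat(sprintf("  SM  %8.1f      (arbitrary intensity units)\n", m$SM))
  cat(sprintf("  PSM %8.3f mm\n", m$PSM_mm))
  flags <- c(if (x$provenance$border_leak) "border-leak",
             if (x$provenance$ambiguous_axis) "ambiguous-axis",
             if (x$provenance$sm_tie) "sm-tie")
  if (length(flags)) cat("  flags:", paste(flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.disc_analysis <- function(object, ...) {
  print(object)
  cat(sprintf("  frame angle %.2f deg, %d mask px, resample bias %.4f\n",
              object$provenance$frame_angle_deg, sum(object$mask$mask),
              object$provenance$resample_bias))
  invisible(object)
}

#' @export
plot.disc_analysis <- function(x, slice = NULL, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  al <- x$aligned
  img <- t(al$intensity)[, nrow(al$intensity):1, drop = FALSE]
  graphics::image(x = al$axis_positions_mm, y = rev(-al$perp_positions_mm),
                  z = img, col = grDevices::gray.colors(256), asp = 1,
                  xlab = "longitudinal (mm)", ylab = "perpendicular (mm)",
                  main = "disc-aligned nucleus")
  plot(x$profile, main = "intensity profile")
  graphics::abline(v = x$metrics$PSM_mm, lty = 2, col = "red")
  invisible(x)
}

#' One CSV-ready record from a disc analysis
#'
#' @param analysis a [analyze_disc()] result.
#' @param subject,pathology,severity,disc_level cohort metadata labels.
#' @return one-row data.frame matching the cohort record layout.
#' @export
metrics_record <- function(analysis, subject = NA_character_,
                           pathology = NA_character_,
                           severity = NA_integer_,
                           disc_level = NA_character_) {
  m <- analysis$metrics
  data.frame(subject = subject, pathology = pathology,
             severity = severity, disc_level = disc_level,
             DX_mm = m$DX_mm, H_mm = m$H_mm, SM = m$SM, PSM_mm = m$PSM_mm,
             settings_hash = analysis$provenance$settings_hash,
             stringsAsFactors = FALSE)
}
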