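#' Synthetic sagittal disc-phantom specification
#'
#' Describes a synthetic sagittal slice: an elliptical disc of moderate
#' intensity (annulus) on a darker background, containing a brighter
#' elliptical nucleus zone — the "high intensity zone" segmented on
#' T2-weighted images of healthy discs. Defaults emulate a lumbar
#' acquisition: 512 x 512 matrix over a 320 mm field of view
#' (0.625 mm/px), disc semi-axes 20 x 5 mm and nucleus semi-axes
#' 10 x 3.5 mm, so that the nucleus height falls in the range observed
#' clinically (about 7-9 mm). Intensities are in arbitrary scanner-like
#' units; the default nucleus plateau of 100 puts the maximum
#' perpendicular intensity sum SM near 1100, the order of magnitude seen
#' on real T2 scans with this technique.
#'
#' @param image_shape integer length-2, pixel counts `(rows, cols)`.
#' @param pixel_spacing_mm positive spacing, scalar (isotropic) or
#'   `(row_mm, col_mm)`.
#' @param disc_center_mm disc centre `(x, y)` in mm.
#' @param disc_semi_axes_mm disc semi-axes `(longitudinal, perpendicular)`
#'   in mm.
#' @param disc_angle_deg rotation of the disc long axis from the image
#'   x-axis, degrees (positive toward +y).
#' @param nucleus_semi_axes_mm nucleus semi-axes
#'   `(longitudinal, perpendicular)` in mm.
#' @param nucleus_offset_mm signed longitudinal offset of the nucleus
#'   centre from the disc centre, mm.
#' @param nucleus_intensity,annulus_intensity,background_intensity
#'   intensity plateaus; must satisfy
#'   `nucleus > annulus > background >= 0`, and the nucleus plateau must
#'   stay above the annulus over the whole nucleus after applying the
#'   gradient.
#' @param intensity_gradient signed intensity change per mm applied along
#'   the longitudinal axis inside the nucleus, anchored at the nucleus
#'   centre (so the mean nucleus intensity is unchanged).
#' @param intensity_curvature relative longitudinal dome in `[0, 1)`:
#'   the nucleus intensity falls off as
#'   `nucleus_intensity * (1 - curvature * (u / a)^2)` with `u` the
#'   longitudinal distance from the nucleus centre and `a` its
#'   longitudinal semi-axis, emulating the centre-bright T2 appearance
#'   of a hydrated nucleus. 0 (the default) gives a flat plateau.
#' @param noise_sigma standard deviation of additive Gaussian noise
#'   (clipped at zero); 0 gives a noiseless phantom.
#' @param rng_seed integer seed used when noise is drawn, or `NULL` to
#'   use the current RNG state.
#'
#' @return An object of class `phantom_spec` (a validated named list).
#' @seealso [generate_disc_phantom()], [effect_model()]
#' @export
phantom_spec <- function(image_shape = c(512L, 512L),
                         pixel_spacing_mm = 0.625,
                         disc_center_mm = c(160, 160),
                         disc_semi_axes_mm = c(20, 5),
                         disc_angle_deg = 0,
                         nucleus_semi_axes_mm = c(10, 3.5),
                         nucleus_offset_mm = 0,
                         nucleus_intensity = 100,
                         annulus_intensity = 25,
                         background_intensity = 5,
                         intensity_gradient = 0,
                         intensity_curvature = 0,
                         noise_sigma = 0,
                         rng_seed = NULL) {
  spec <- list(image_shape = as.integer(image_shape),
               pixel_spacing_mm = {
                 s <- as.numeric(pixel_spacing_mm)
                 if (length(s) == 1L) rep(s, 2L) else s
               },
               disc_center_mm = as.numeric(disc_center_mm),
               disc_semi_axes_mm = as.numeric(disc_semi_axes_mm),
               disc_angle_deg = as.numeric(disc_angle_deg),
               nucleus_semi_axes_mm = as.numeric(nucleus_semi_axes_mm),
               nucleus_offset_mm = as.numeric(nucleus_offset_mm),
               nucleus_intensity = as.numeric(nucleus_intensity),
               annulus_intensity = as.numeric(annulus_intensity),
               background_intensity = as.numeric(background_intensity),
               intensity_gradient = as.numeric(intensity_gradient),
               intensity_curvature = as.numeric(intensity_curvature),
               noise_sigma = as.numeric(noise_sigma),
               rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  chk_len <- function(field, n) {
    if (length(spec[[field]]) != n || any(!is.finite(spec[[field]])))
      stop("phantom_spec: field '", field, "' must be ", n,
           " finite value(s)", call. = FALSE)
  }
  chk_len("image_shape", 2); chk_len("pixel_spacing_mm", 2)
  chk_len("disc_center_mm", 2); chk_len("disc_semi_axes_mm", 2)
  chk_len("nucleus_semi_axes_mm", 2)
  for (f in c("disc_angle_deg", "nucleus_offset_mm", "nucleus_intensity",
              "annulus_intensity", "background_intensity",
              "intensity_gradient", "intensity_curvature",
              "noise_sigma")) chk_len(f, 1)
  if (any(spec$image_shape < 8L))
    stop("phantom_spec: field 'image_shape' must be at least 8x8",
         call. = FALSE)
  pos <- function(field) {
    if (any(spec[[field]] <= 0))
      stop("phantom_spec: field '", field, "' must be strictly positive",
           call. = FALSE)
  }
  pos("pixel_spacing_mm"); pos("disc_semi_axes_mm")
  pos("nucleus_semi_axes_mm"); pos("nucleus_intensity")
  if (spec$annulus_intensity <= 0)
    stop("phantom_spec: field 'annulus_intensity' must be strictly positive",
         call. = FALSE)
  if (spec$background_intensity < 0)
    stop("phantom_spec: field 'background_intensity' must be nonnegative",
         call. = FALSE)
  if (spec$noise_sigma < 0)
    stop("phantom_spec: field 'noise_sigma' must be nonnegative",
         call. = FALSE)
  if (!(spec$nucleus_intensity > spec$annulus_intensity &&
        spec$annulus_intensity > spec$background_intensity))
    stop("phantom_spec: field 'nucleus_intensity' must exceed ",
         "'annulus_intensity', which must exceed 'background_intensity' ",
         "(the nucleus must be the high-intensity zone)", call. = FALSE)
  if (spec$intensity_curvature < 0 || spec$intensity_curvature >= 1)
    stop("phantom_spec: field 'intensity_curvature' must lie in [0, 1)",
         call. = FALSE)
  if (spec$nucleus_intensity * (1 - spec$intensity_curvature) -
      abs(spec$intensity_gradient) * spec$nucleus_semi_axes_mm[1] <=
      spec$annulus_intensity)
    stop("phantom_spec: fields 'intensity_gradient'/'intensity_curvature' ",
         "drive the nucleus intensity below the annulus intensity",
         call. = FALSE)
  # nucleus ellipse fully inside the disc ellipse (co-axial, offset along
  # the shared long axis); checked on a dense boundary sample
  t <- seq(0, 2 * pi, length.out = 721L)
  bx <- (spec$nucleus_offset_mm + spec$nucleus_semi_axes_mm[1] * cos(t)) /
    spec$disc_semi_axes_mm[1]
  by <- (spec$nucleus_semi_axes_mm[2] * sin(t)) / spec$disc_semi_axes_mm[2]
  if (max(bx^2 + by^2) > 1)
    stop("phantom geometry: nucleus ellipse is not contained in the disc ",
         "ellipse (check nucleus_semi_axes_mm / nucleus_offset_mm)",
         call. = FALSE)
  invisible(spec)
}

# unit longitudinal / perpendicular axes of a phantom spec
phantom_axes <- function(spec) {
  th <- spec$disc_angle_deg * pi / 180
  list(u = c(cos(th), sin(th)), v = c(-sin(th), cos(th)))
}

# Rasterize the noiseless phantom over a pixel window (1-based row/col
# ranges); pixel-centre inclusion rule. Returns global-coordinate-aware
# intensity and nucleus mask for that window.
rasterize_phantom <- function(spec, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_len(spec$image_shape[1])
  if (is.null(cols)) cols <- seq_len(spec$image_shape[2])
  sp <- spec$pixel_spacing_mm
  x <- (cols - 0.5) * sp[2]
  y <- (rows - 0.5) * sp[1]
  ax <- phantom_axes(spec)
  dx <- matrix(rep(x, each = length(rows)), length(rows)) -
    spec$disc_center_mm[1]
  dy <- matrix(rep(y, times = length(cols)), length(rows)) -
    spec$disc_center_mm[2]
  u <- dx * ax$u[1] + dy * ax$u[2]        # longitudinal coord, disc-centred
  v <- dx * ax$v[1] + dy * ax$v[2]
  in_disc <- (u / spec$disc_semi_axes_mm[1])^2 +
    (v / spec$disc_semi_axes_mm[2])^2 <= 1
  un <- u - spec$nucleus_offset_mm        # nucleus-centred longitudinal
  in_nuc <- (un / spec$nucleus_semi_axes_mm[1])^2 +
    (v / spec$nucleus_semi_axes_mm[2])^2 <= 1
  img <- matrix(spec$background_intensity, length(rows), length(cols))
  img[in_disc] <- spec$annulus_intensity
  img[in_nuc] <- spec$nucleus_intensity *
    (1 - spec$intensity_curvature *
       (un[in_nuc] / spec$nucleus_semi_axes_mm[1])^2) +
    spec$intensity_gradient * un[in_nuc]
  list(intensity = img, nucleus_mask = in_nuc, rows = rows, cols = cols)
}

# bounding pixel window guaranteed to contain the disc ellipse
phantom_disc_window <- function(spec) {
  sp <- spec$pixel_spacing_mm
  r_d <- max(spec$disc_semi_axes_mm) + 2 * max(sp)
  rows <- seq(max(1L, floor((spec$disc_center_mm[2] - r_d) / sp[1])),
              min(spec$image_shape[1],
                  ceiling((spec$disc_center_mm[2] + r_d) / sp[1]) + 1L))
  cols <- seq(max(1L, floor((spec$disc_center_mm[1] - r_d) / sp[2])),
              min(spec$image_shape[2],
                  ceiling((spec$disc_center_mm[1] + r_d) / sp[2]) + 1L))
  list(rows = as.integer(rows), cols = as.integer(cols))
}

#' Generate a synthetic disc phantom with ground truth
#'
#' Rasterizes the phantom described by a [phantom_spec()] (a pixel belongs
#' to an ellipse iff its centre lies inside), adds Gaussian noise of sd
#' `noise_sigma` clipped at zero, and computes ground-truth metrics on the
#' noiseless raster with an independent brute-force oracle
#' ([phantom_truth()]): the exact nucleus mask, geometric and
#' intensity-weighted centres, and the reference values of DX, H, SM and
#' PSM. Truth is always computed on the rasterized noiseless image, never
#' from the continuous geometry, so that the pipeline and the oracle see
#' the same discrete object.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `disc_phantom`: list with `slice` (a
#'   [sagittal_slice()], noisy if `noise_sigma > 0`), `truth` (see
#'   [phantom_truth()]) and `spec`.
#' @examples
#' ph <- generate_disc_phantom(phantom_spec(noise_sigma = 0))
#' ph$truth$true_H_mm
#' @export
generate_disc_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  ras <- rasterize_phantom(spec)
  truth <- phantom_truth(spec, ras)
  img <- ras$intensity
  if (spec$noise_sigma > 0) {
    if (!is.null(spec$rng_seed)) set.seed(spec$rng_seed)
    img <- img + stats::rnorm(length(img), 0, spec$noise_sigma)
    img[img < 0] <- 0
  }
  slice <- sagittal_slice(img, spec$pixel_spacing_mm,
                          meta = list(source = "phantom"))
  structure(list(slice = slice, truth = truth, spec = spec),
            class = "disc_phantom")
}

#' @export
print.disc_phantom <- function(x, ...) {
  cat("<disc_phantom>\n")
  print(x$slice)
  t <- x$truth
  cat(sprintf("  truth: DX %.3f mm, H %.3f mm, SM %.1f, PSM %.3f mm\n",
              t$true_DX_mm, t$true_H_mm, t$true_SM, t$true_PSM_mm))
  invisible(x)
}

#' @export
plot.disc_phantom <- function(x, ...) {
  plot(x$slice, main = "disc phantom", ...)
  invisible(x)
}

#' Pathology-by-severity cohort effect model
#'
#' Defines per-cell mean phantom parameters and between-subject noise
#' scales for a simulated cohort crossing pathology (scoliosis vs
#' spondylolisthesis) with severity (levels 1-3). The defaults encode the
#' clinically observed directions: the nucleus plateau intensity (hence
#' SM) is higher for scoliosis than for spondylolisthesis with no
#' systematic severity trend; the nucleus longitudinal half-length (hence
#' PSM, measured from the posterior end of the nucleus) is larger for
#' scoliosis and decreases with severity in both pathologies; and the
#' nucleus height H decreases with spondylolisthesis severity. Default
#' magnitudes are sized so the simulated cohort means land near the
#' ranges reported for adolescent patients (PSM roughly 6-15 mm, H 7-9 mm,
#' SM 500-1250), with between-subject dispersion (1.5 mm half-length,
#' 0.5 mm half-height, 15 intensity units, gradient SD 2 units/mm) sized
#' so the main-effect significance pattern of such cohorts — SM separating
#' the pathologies, PSM separating both pathology and severity — comes out
#' decisively at moderate cohort sizes.
#'
#' @param mean_long_semi_axis,mean_perp_semi_axis,mean_intensity 2x3
#'   matrices (rows: spondylolisthesis, scoliosis; columns: severity 1-3)
#'   of per-cell means for the nucleus longitudinal semi-axis (mm),
#'   perpendicular semi-axis (mm) and plateau intensity.
#' @param mean_offset 2x3 matrix of per-cell mean nucleus longitudinal
#'   offsets (mm); default 0 (the offset does not drive the descriptors).
#' @param mean_gradient 2x3 matrix of per-cell mean intensity gradients
#'   (units/mm); default 0. Subjects draw an individual gradient, which
#'   gives each nucleus the anterior-posterior signal asymmetry seen on
#'   real discs (and hence nonzero DX values).
#' @param mean_curvature,sd_curvature per-subject longitudinal intensity
#'   dome (see [phantom_spec()]), drawn once per subject and clipped to
#'   `[0, 0.6]`; the dome reflects the centre-bright appearance of a
#'   hydrated nucleus and makes the profile maximum unique and stable.
#' @param sd_long_semi_axis,sd_perp_semi_axis,sd_intensity,sd_offset,sd_gradient
#'   between-subject standard deviations.
#' @param n_per_cell subjects per pathology-severity cell (>= 2).
#' @param base_spec [phantom_spec()] providing everything the cell means
#'   do not override; its disc is enlarged to 22 x 5.5 mm so every drawn
#'   nucleus stays contained.
#' @param rng_seed integer seed, or `NULL`.
#'
#' @return An object of class `effect_model`.
#' @seealso [generate_cohort()]
#' @export
effect_model <- function(
    mean_long_semi_axis = rbind(spondylolisthesis = c(10.2, 9.4, 6.4),
                                scoliosis = c(15.1, 14.0, 12.3)),
    mean_perp_semi_axis = rbind(spondylolisthesis = c(4.46, 4.05, 3.44),
                                scoliosis = c(3.93, 3.81, 3.73)),
    mean_intensity = rbind(spondylolisthesis = c(56, 56, 56),
                           scoliosis = c(97, 97, 97)),
    mean_offset = matrix(0, 2, 3,
                         dimnames = list(c("spondylolisthesis", "scoliosis"),
                                         NULL)),
    mean_gradient = matrix(0, 2, 3,
                           dimnames = list(c("spondylolisthesis", "scoliosis"),
                                           NULL)),
    mean_curvature = 0.35,
    sd_curvature = 0.08,
    sd_long_semi_axis = 1.5,
    sd_perp_semi_axis = 0.5,
    sd_intensity = 15,
    sd_offset = 0.5,
    sd_gradient = 0.5,
    n_per_cell = 10L,
    base_spec = phantom_spec(disc_semi_axes_mm = c(22, 5.5),
                             annulus_intensity = 15,
                             background_intensity = 3),
    rng_seed = NULL) {
  model <- list(pathologies = c("spondylolisthesis", "scoliosis"),
                severities = 1:3,
                mean_long_semi_axis = mean_long_semi_axis,
                mean_perp_semi_axis = mean_perp_semi_axis,
                mean_intensity = mean_intensity,
                mean_offset = mean_offset,
                mean_gradient = mean_gradient,
                mean_curvature = mean_curvature,
                sd_curvature = sd_curvature,
                sd_long_semi_axis = sd_long_semi_axis,
                sd_perp_semi_axis = sd_perp_semi_axis,
                sd_intensity = sd_intensity,
                sd_offset = sd_offset,
                sd_gradient = sd_gradient,
                n_per_cell = as.integer(n_per_cell),
                base_spec = base_spec,
                rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed))
  for (f in c("mean_long_semi_axis", "mean_perp_semi_axis",
              "mean_intensity", "mean_offset", "mean_gradient"))
    if (!all(dim(model[[f]]) == c(2L, 3L)))
      stop("effect_model: '", f, "' must be a 2x3 matrix ",
           "(pathology x severity)", call. = FALSE)
  if (length(model$pathologies) < 1L || length(model$severities) < 1L)
    stop("effect_model: empty factor level set", call. = FALSE)
  if (model$n_per_cell < 2L)
    stop("effect_model: n_per_cell must be at least 2", call. = FALSE)
  class(model) <- "effect_model"
  model
}

# one subject's phantom_spec drawn from the effect model (clipped into the
# spec's validity region)
draw_subject_spec <- function(model, i_path, i_sev) {
  bs <- model$base_spec
  off <- min(3, max(-3, stats::rnorm(1, model$mean_offset[i_path, i_sev],
                                     model$sd_offset)))
  a_max <- 0.95 * (bs$disc_semi_axes_mm[1] - abs(off))
  a <- min(a_max, max(3, stats::rnorm(1, model$mean_long_semi_axis[i_path, i_sev],
                                      model$sd_long_semi_axis)))
  b_max <- 0.95 * bs$disc_semi_axes_mm[2]
  b <- min(b_max, max(1, stats::rnorm(1, model$mean_perp_semi_axis[i_path, i_sev],
                                      model$sd_perp_semi_axis)))
  cv <- min(0.6, max(0, stats::rnorm(1, model$mean_curvature,
                                     model$sd_curvature)))
  inten <- max(1.15 * bs$annulus_intensity / (1 - cv),
               stats::rnorm(1, model$mean_intensity[i_path, i_sev],
                            model$sd_intensity))
  g <- stats::rnorm(1, model$mean_gradient[i_path, i_sev], model$sd_gradient)
  g_max <- 0.9 * (inten * (1 - cv) - 1.1 * bs$annulus_intensity) / a
  g <- min(g_max, max(-g_max, g))
  phantom_spec(image_shape = bs$image_shape,
               pixel_spacing_mm = bs$pixel_spacing_mm,
               disc_center_mm = bs$disc_center_mm,
               disc_semi_axes_mm = bs$disc_semi_axes_mm,
               disc_angle_deg = bs$disc_angle_deg,
               nucleus_semi_axes_mm = c(a, b),
               nucleus_offset_mm = off,
               nucleus_intensity = inten,
               annulus_intensity = bs$annulus_intensity,
               background_intensity = bs$background_intensity,
               intensity_gradient = g,
               intensity_curvature = cv,
               noise_sigma = bs$noise_sigma,
               rng_seed = NULL)
}

#' Generate a simulated pathology-by-severity cohort
#'
#' Draws `n_per_cell` subjects for each of the six pathology x severity
#' cells of an [effect_model()]. Each subject gets a phantom spec sampled
#' around the cell means, its ground truth from the brute-force oracle on
#' the noiseless raster, and (optionally) the rasterized slice. The draw
#' is deterministic given `rng_seed`.
#'
#' @param model an [effect_model()].
#' @param slices if `FALSE`, skip assembling the full-image slices and
#'   return truths only (the truth is computed on the disc's bounding
#'   window, which is identical to the full-image computation since the
#'   raster is background outside the disc). Useful for large simulation
#'   studies.
#' @return An object of class `disc_cohort`: a list of subject records
#'   `list(subject, pathology, severity, spec, truth, slice)`.
#' @examples
#' co <- generate_cohort(effect_model(n_per_cell = 2, rng_seed = 7),
#'                       slices = FALSE)
#' length(co)
#' @export
generate_cohort <- function(model, slices = TRUE) {
  stopifnot(inherits(model, "effect_model"))
  if (!is.null(model$rng_seed)) set.seed(model$rng_seed)
  out <- list()
  for (i_path in seq_along(model$pathologies)) {
    for (i_sev in seq_along(model$severities)) {
      for (k in seq_len(model$n_per_cell)) {
        spec <- draw_subject_spec(model, i_path, i_sev)
        if (slices) {
          ph <- generate_disc_phantom(spec)
          truth <- ph$truth; slice <- ph$slice
        } else {
          win <- phantom_disc_window(spec)
          ras <- rasterize_phantom(spec, win$rows, win$cols)
          truth <- phantom_truth(spec, ras)
          slice <- NULL
        }
        out[[length(out) + 1L]] <- list(
          subject = sprintf("%s-s%d-%02d",
                            substr(model$pathologies[i_path], 1, 5),
                            model$severities[i_sev], k),
          pathology = model$pathologies[i_path],
          severity = model$severities[i_sev],
          spec = spec, truth = truth, slice = slice)
      }
    }
  }
  class(out) <- "disc_cohort"
  out
}

#' Cohort ground-truth metric records
#'
#' Flattens a [generate_cohort()] result into the record data frame
#' consumed by [two_way_anova()] and [cohort_report()], using the oracle
#' ground-truth metrics as responses.
#'
#' @param cohort a `disc_cohort`.
#' @return data.frame with columns `subject`, `pathology`, `severity`,
#'   `disc_level`, `DX_mm`, `H_mm`, `SM`, `PSM_mm`.
#' @export
cohort_truth_records <- function(cohort) {
  stopifnot(inherits(cohort, "disc_cohort"))
  do.call(rbind, lapply(cohort, function(rec) {
    data.frame(subject = rec$subject,
               pathology = rec$pathology,
               severity = rec$severity,
               disc_level = NA_character_,
               DX_mm = rec$truth$true_DX_mm,
               H_mm = rec$truth$true_H_mm,
               SM = rec$truth$true_SM,
               PSM_mm = rec$truth$true_PSM_mm,
               stringsAsFactors = FALSE)
  }))
}
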