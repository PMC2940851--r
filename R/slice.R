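#' Sagittal slice container
#'
#' A `sagittal_slice` holds one 2D grayscale raster (a sagittal T2-weighted
#' MR slice, or a synthetic phantom) together with its physical pixel
#' spacing in mm and free-form acquisition metadata. All mm-valued metrics
#' downstream are grounded in this spacing.
#'
#' Coordinate convention used throughout the package: the raster is an R
#' matrix indexed `[row, col]`; the physical coordinate of the centre of
#' pixel `(r, c)` (1-based) is `x = (c - 0.5) * spacing_col`,
#' `y = (r - 0.5) * spacing_row`, so `x` runs along image columns
#' (anterior approximately +x in standard sagittal display) and `y` along
#' rows. Angles are measured from the +x axis toward +y.
#'
#' @param intensity numeric matrix of nonnegative, finite intensities
#'   (arbitrary scanner units), at least 8x8.
#' @param pixel_spacing_mm numeric length-2 vector `(row_mm, col_mm)`,
#'   strictly positive. A scalar is recycled to isotropic spacing.
#' @param meta named list of free-form acquisition tags (TR, TE, disc
#'   level, patient id, ...).
#'
#' @return An object of class `sagittal_slice` with elements `intensity`,
#'   `pixel_spacing_mm` and `meta`.
#' @examples
#' sl <- sagittal_slice(matrix(runif(64, 0, 100), 8, 8), 0.625)
#' dim(sl$intensity)
#' @export
sagittal_slice <- function(intensity, pixel_spacing_mm, meta = list()) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("intensity must be a numeric matrix", call. = FALSE)
  if (nrow(intensity) < 8L || ncol(intensity) < 8L)
    stop("intensity raster must be at least 8x8 pixels", call. = FALSE)
  if (any(!is.finite(intensity)))
    stop("intensity values must be finite", call. = FALSE)
  if (any(intensity < 0))
    stop("intensity values must be nonnegative", call. = FALSE)
  pixel_spacing_mm <- as.numeric(pixel_spacing_mm)
  if (length(pixel_spacing_mm) == 1L)
    pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  if (length(pixel_spacing_mm) != 2L || any(!is.finite(pixel_spacing_mm)) ||
      any(pixel_spacing_mm <= 0))
    stop("pixel_spacing_mm must be two strictly positive finite values",
         call. = FALSE)
  if (!is.list(meta)) stop("meta must be a list", call. = FALSE)
  structure(list(intensity = intensity,
                 pixel_spacing_mm = pixel_spacing_mm,
                 meta = meta),
            class = "sagittal_slice")
}

#' @export
print.sagittal_slice <- function(x, ...) {
  cat(sprintf("<sagittal_slice> %d x %d px, spacing %.4g x %.4g mm/px\n",
              nrow(x$intensity), ncol(x$intensity),
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$intensity), max(x$intensity)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.sagittal_slice <- function(x, main = "sagittal slice", ...) {
  img <- t(x$intensity)[, nrow(x$intensity):1, drop = FALSE]
  graphics::image(x = (seq_len(nrow(img)) - 0.5) * x$pixel_spacing_mm[2],
                  y = (seq_len(ncol(img)) - 0.5) * x$pixel_spacing_mm[1],
                  z = img, col = grDevices::gray.colors(256, 0, 1),
                  asp = 1, xlab = "x (mm)", ylab = "y (mm)", main = main, ...)
  invisible(x)
}

# pixel-centre coordinates (mm) of every pixel in a raster of given shape
pixel_centers_mm <- function(nr, nc, spacing) {
  list(x = (seq_len(nc) - 0.5) * spacing[2],
       y = (seq_len(nr) - 0.5) * spacing[1])
}

#' Read a sagittal slice from disk
#'
#' Supported formats: NIfTI (`.nii`, `.nii.gz`; spacing from the header
#' zooms), PNG with a JSON sidecar (`f.png` + `f.json` carrying
#' `pixel_spacing_mm` and an optional `intensity_scale` undoing the 8-bit
#' normalisation), and a plain-text TSV raster with the same JSON sidecar
#' (`f.tsv` + `f.json`). DICOM is not supported.
#'
#' @param path path to the image file.
#' @return A [sagittal_slice()].
#' @export
read_slice <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) > 2L && prod(dim(arr)[-(1:2)]) != 1L)
      stop("NIfTI volume is not a single slice: ", path, call. = FALSE)
    arr <- matrix(as.numeric(arr), dim(arr)[1], dim(arr)[2])
    pd <- RNifti::pixdim(img)[1:2]
    return(sagittal_slice(arr, pd, meta = list(source = path)))
  }
  if (grepl("\\.png$", lower)) {
    side <- read_sidecar(path)
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3L) arr <- arr[, , 1]
    scale <- if (!is.null(side$intensity_scale)) side$intensity_scale else 1
    return(sagittal_slice(arr * scale, unlist(side$pixel_spacing_mm),
                          meta = list(source = path)))
  }
  if (grepl("\\.tsv$", lower)) {
    side <- read_sidecar(path)
    arr <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
    dimnames(arr) <- NULL
    return(sagittal_slice(arr, unlist(side$pixel_spacing_mm),
                          meta = list(source = path)))
  }
  stop("unsupported image format (expect .nii/.nii.gz/.png/.tsv): ", path,
       call. = FALSE)
}

sidecar_path <- function(path) sub("\\.[A-Za-z.]+$", ".json", path)

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("missing JSON sidecar for ", path, " (expected ", sp, ")",
         call. = FALSE)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write a sagittal slice to disk
#'
#' `.nii`/`.nii.gz` keep full precision (spacing in the header). `.png`
#' stores an 8-bit normalised image plus a JSON sidecar with
#' `pixel_spacing_mm`, `intensity_scale` (the factor recovering original
#' units) and any extra fields in `sidecar`; `.tsv` stores the raster as
#' tab-separated text at full precision with the same sidecar.
#'
#' @param slice a [sagittal_slice()].
#' @param path output path; the extension selects the format.
#' @param sidecar named list merged into the JSON sidecar (PNG/TSV only).
#' @return `path`, invisibly.
#' @export
write_slice <- function(slice, path, sidecar = list()) {
  stopifnot(inherits(slice, "sagittal_slice"))
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::asNifti(slice$intensity)
    RNifti::pixdim(img) <- slice$pixel_spacing_mm
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  if (grepl("\\.png$", lower)) {
    mx <- max(slice$intensity)
    scale <- if (mx > 0) mx else 1
    png::writePNG(slice$intensity / scale, path)
    write_sidecar(path, slice, c(list(intensity_scale = scale), sidecar))
    return(invisible(path))
  }
  if (grepl("\\.tsv$", lower)) {
    utils::write.table(slice$intensity, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
    write_sidecar(path, slice, sidecar)
    return(invisible(path))
  }
  stop("unsupported output format: ", path, call. = FALSE)
}

write_sidecar <- function(path, slice, extra = list()) {
  side <- c(list(pixel_spacing_mm = slice$pixel_spacing_mm), extra)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}
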