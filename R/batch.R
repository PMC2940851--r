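# canonical settings hash: md5 of the canonical JSON encoding
settings_hash <- function(settings) {
  settings <- settings[order(names(settings))]
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(settings, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Batch run configuration
#'
#' Bundles everything a batch run needs: the input images, the per-image
#' seed points (the one manual input of the semi-automatic workflow,
#' supplied as a sidecar table so batch runs stay reproducible),
#' segmentation and metric settings, and the output directory. All
#' referenced paths must exist when the config is built.
#'
#' @param images character vector of image paths (formats of
#'   [read_slice()]), or one directory to scan for them.
#' @param seeds data.frame with columns `image`, `row`, `col` (optional
#'   `subject`, `pathology`, `severity`, `disc_level`), or the path of a
#'   CSV with those columns. `image` entries are matched to `images` by
#'   file name.
#' @param out_dir output directory (created if missing).
#' @param threshold_fraction,h_mode settings forwarded to
#'   [analyze_disc()].
#' @param axis_points optional endplate axis points (2x2 matrix, mm)
#'   applied to every image.
#' @param log_level `"info"` or `"quiet"`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(images, seeds, out_dir,
                       threshold_fraction = 0.5,
                       h_mode = c("max", "center"),
                       axis_points = NULL,
                       log_level = c("info", "quiet")) {
  h_mode <- match.arg(h_mode)
  log_level <- match.arg(log_level)
  if (length(images) == 1L && dir.exists(images))
    images <- list.files(images, pattern = "\\.(nii|nii\\.gz|png|tsv)$",
                         full.names = TRUE)
  missing <- images[!file.exists(images)]
  if (length(missing))
    stop("missing input image(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.character(seeds)) {
    if (!file.exists(seeds)) stop("missing seeds file: ", seeds, call. = FALSE)
    seeds <- utils::read.csv(seeds, stringsAsFactors = FALSE)
  }
  seeds <- as.data.frame(seeds)
  if (!all(c("image", "row", "col") %in% names(seeds)))
    stop("seeds must have columns image, row, col", call. = FALSE)
  structure(list(images = images, seeds = seeds, out_dir = out_dir,
                 threshold_fraction = threshold_fraction, h_mode = h_mode,
                 axis_points = axis_points, log_level = log_level),
            class = "run_config")
}

#' Read a run configuration from a JSON or YAML file
#'
#' File fields mirror the [run_config()] arguments (`images`, `seeds`,
#' `out_dir`, `threshold_fraction`, `h_mode`, `axis_points`); relative
#' paths are resolved against the config file's directory.
#'
#' @param path config file (`.json`, `.yaml`/`.yml`).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", tolower(path))) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  run_config(images = resolve(cfg$images),
             seeds = if (is.character(cfg$seeds)) resolve(cfg$seeds)
                     else as.data.frame(cfg$seeds),
             out_dir = resolve(cfg$out_dir),
             threshold_fraction = cfg$threshold_fraction %||% 0.5,
             h_mode = cfg$h_mode %||% "max",
             axis_points = if (!is.null(cfg$axis_points))
               matrix(unlist(cfg$axis_points), 2, 2, byrow = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline over a batch of images
#'
#' Analyses every configured image with [analyze_disc()]. Each input
#' yields either a metrics row in `cohort.csv` (carrying the settings
#' hash, so rows from different settings never mix silently) plus a
#' per-disc JSON under `out_dir/json/`, or a logged, typed failure; the
#' run continues past failures. A structured log (one line per stage per
#' disc, including tie-break and warning flags) is written to
#' `out_dir/run.log`. Outputs are deterministic given the config.
#'
#' @param config a [run_config()].
#' @return Object of class `batch_result`: `records` (data.frame),
#'   `failures` (data.frame image/error), `n_ok`, `n_fail`,
#'   `exit_status` (0 when every image succeeded, 1 otherwise) and the
#'   output paths.
#' @export
run_batch <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  json_dir <- file.path(config$out_dir, "json")
  dir.create(json_dir, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con))
  logline <- function(...) {
    msg <- paste0(...)
    writeLines(msg, log_con)
    if (config$log_level == "info") message(msg)
  }
  rows <- list(); fails <- list()
  for (img_path in config$images) {
    name <- basename(img_path)
    srow <- config$seeds[basename(config$seeds$image) == name, , drop = FALSE]
    res <- tryCatch({
      if (nrow(srow) == 0L) stop("no seed configured for ", name)
      slice <- read_slice(img_path)
      logline("[", name, "] read: ", nrow(slice$intensity), "x",
              ncol(slice$intensity))
      an <- withCallingHandlers(
        analyze_disc(slice, seed = c(srow$row[1], srow$col[1]),
                     threshold_fraction = config$threshold_fraction,
                     axis_points = config$axis_points,
                     h_mode = config$h_mode),
        warning = function(w) {
          logline("[", name, "] warning: ", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      logline(sprintf(
        "[%s] metrics: DX=%.3f H=%.3f SM=%.1f PSM=%.3f%s%s%s", name,
        an$metrics$DX_mm, an$metrics$H_mm, an$metrics$SM, an$metrics$PSM_mm,
        if (an$provenance$border_leak) " border-leak" else "",
        if (an$provenance$ambiguous_axis) " ambiguous-axis" else "",
        if (an$provenance$sm_tie) " sm-tie" else ""))
      rec <- metrics_record(an,
                            subject = srow$subject[1] %||% name,
                            pathology = srow$pathology[1] %||% NA_character_,
                            severity = srow$severity[1] %||% NA_integer_,
                            disc_level = srow$disc_level[1] %||% NA_character_)
      rec$image <- name
      jsonlite::write_json(
        c(rec, list(flags = an$provenance[c("border_leak", "ambiguous_axis",
                                            "sm_tie")])),
        file.path(json_dir, paste0(sub("\\.[A-Za-z.]+$", "", name), ".json")),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
      rec
    }, error = function(e) {
      logline("[", name, "] FAILED: ", conditionMessage(e))
      structure(list(image = name, error = conditionMessage(e)),
                class = "batch_failure")
    })
    if (inherits(res, "batch_failure")) fails[[length(fails) + 1L]] <- res
    else rows[[length(rows) + 1L]] <- res
  }
  records <- if (length(rows)) do.call(rbind, rows) else NULL
  csv_path <- file.path(config$out_dir, "cohort.csv")
  if (!is.null(records))
    utils::write.csv(records, csv_path, row.names = FALSE)
  failures <- if (length(fails))
    data.frame(image = vapply(fails, `[[`, "", "image"),
               error = vapply(fails, `[[`, "", "error"))
  else data.frame(image = character(), error = character())
  logline(sprintf("done: %d ok, %d failed", length(rows), length(fails)))
  structure(list(records = records, failures = failures,
                 n_ok = length(rows), n_fail = length(fails),
                 exit_status = as.integer(length(fails) > 0L),
                 csv = csv_path, log = log_path, json_dir = json_dir),
            class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("<batch_result> %d ok, %d failed (exit %d)\n  csv: %s\n",
              x$n_ok, x$n_fail, x$exit_status, x$csv))
  invisible(x)
}
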