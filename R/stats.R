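#' Repeated-measures reproducibility standard deviations
#'
#' Summarises repeated measurements of one disc by one or more
#' observers: the pooled sample SD (n - 1 denominator) over all repeats
#' and the per-observer SDs, for each descriptor. DX, H and PSM are
#' reported in mm; SM, whose units are scanner-arbitrary, is reported as
#' a percentage of its mean (the coefficient of variation), so
#' reproducibility statements like "below 0.1%" are scale-free.
#'
#' @param records data.frame with columns `observer`, `DX_mm`, `H_mm`,
#'   `SM`, `PSM_mm`; one row per repetition.
#' @return list with `pooled` (named vector: `DX_mm`, `H_mm`, `PSM_mm`
#'   in mm; `SM_pct` in percent of the mean) and `per_observer` (matrix,
#'   one row per observer).
#' @examples
#' reps <- data.frame(observer = rep(c("A", "B"), each = 3),
#'                    DX_mm = rnorm(6, 1, 0.01), H_mm = rnorm(6, 7, 0.01),
#'                    SM = rnorm(6, 1000, 0.5), PSM_mm = rnorm(6, 9, 0.01))
#' reproducibility_sd(reps)$pooled
#' @export
reproducibility_sd <- function(records) {
  records <- as.data.frame(records)
  need <- c("observer", "DX_mm", "H_mm", "SM", "PSM_mm")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(records) < 2L)
    stop("insufficient data: at least 2 repeats are required", call. = FALSE)
  one <- function(df) {
    c(DX_mm = stats::sd(df$DX_mm),
      H_mm = stats::sd(df$H_mm),
      PSM_mm = stats::sd(df$PSM_mm),
      SM_pct = 100 * stats::sd(df$SM) / mean(df$SM))
  }
  per <- do.call(rbind, lapply(split(records, records$observer), one))
  list(pooled = one(records), per_observer = per)
}

#' Two-way pathology-by-severity ANOVA of one descriptor
#'
#' Fixed-effects two-way analysis of variance with interaction of one
#' descriptor on pathology (two levels) and severity (levels 1-3,
#' treated as categorical). Type III sums of squares are used so that
#' main effects are interpretable in the unbalanced designs typical of
#' retrospective cohorts; the factors are coded with sum-to-zero
#' contrasts as Type III requires. The interaction is estimated but
#' reported as supplementary (clinical reports of this design typically
#' show main effects only). When one or more cells are empty the
#' interaction is dropped with a warning; a factor observed at a single
#' level is a rank-deficiency error.
#'
#' @param records data.frame with columns `pathology`, `severity` and
#'   the response named by `response`.
#' @param response one of `"DX_mm"`, `"H_mm"`, `"SM"`, `"PSM_mm"` (any
#'   numeric column).
#' @return Object of class `disc_anova`: `response`; `table`
#'   (data.frame with rows pathology, severity, interaction and columns
#'   `df`, `F`, `p`); `cell_means` (data.frame with mean, SE, n per
#'   cell); `degenerate` (TRUE when the residual variance is zero, in
#'   which case F/p are undefined and returned as NA).
#' @export
two_way_anova <- function(records, response) {
  records <- as.data.frame(records)
  if (!response %in% names(records))
    stop("no column '", response, "' in records", call. = FALSE)
  records$pathology <- factor(records$pathology)
  records$severity <- factor(records$severity)
  for (f in c("pathology", "severity"))
    if (nlevels(records[[f]]) < 2L)
      stop("rank deficiency: factor '", f, "' has fewer than 2 levels",
           call. = FALSE)
  tab <- table(records$pathology, records$severity)
  if (any(tab == 0L)) {
    warning("empty pathology x severity cells; interaction dropped",
            call. = FALSE)
    fml <- stats::reformulate(c("pathology", "severity"), response)
  } else {
    fml <- stats::reformulate("pathology * severity", response)
  }
  m <- stats::lm(fml, data = records,
                 contrasts = list(pathology = "contr.sum",
                                  severity = "contr.sum"))
  degenerate <- stats::sigma(m) < 1e-10 * max(1, mean(abs(records[[response]])))
  if (degenerate) {
    warning("zero residual variance: F statistics are undefined",
            call. = FALSE)
    a3 <- NULL
  } else {
    a3 <- car::Anova(m, type = 3)
  }
  rows <- c("pathology", "severity", "pathology:severity")
  out <- data.frame(term = c("pathology", "severity", "interaction"),
                    df = NA_real_, F = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(a3)) {
    rn <- rownames(a3)
    for (i in seq_along(rows)) {
      j <- match(rows[i], rn)
      if (!is.na(j)) {
        out$df[i] <- a3[j, "Df"]
        out$F[i] <- a3[j, "F value"]
        out$p[i] <- a3[j, "Pr(>F)"]
      }
    }
  }
  agg <- stats::aggregate(records[[response]],
                          by = list(pathology = records$pathology,
                                    severity = records$severity),
                          FUN = function(v) c(mean = mean(v),
                                              se = stats::sd(v) / sqrt(length(v)),
                                              n = length(v)))
  cell_means <- data.frame(pathology = agg$pathology,
                           severity = agg$severity,
                           mean = agg$x[, "mean"], se = agg$x[, "se"],
                           n = agg$x[, "n"])
  structure(list(response = response, table = out, cell_means = cell_means,
                 degenerate = degenerate, model = m),
            class = "disc_anova")
}

#' @export
print.disc_anova <- function(x, ...) {
  cat(sprintf("<disc_anova> response: %s%s\n", x$response,
              if (x$degenerate) " [degenerate: zero residual variance]" else ""))
  tab <- x$table
  tab$F <- signif(tab$F, 4); tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Per-cell mean and standard error table for all four descriptors
#'
#' Lays out the cohort as a 6-column table (spondylolisthesis severity
#' 1-3, then scoliosis severity 1-3) with one `mean +/- SE` cell per
#' pathology-severity combination and descriptor; `SE = SD / sqrt(n)`
#' and is reported as NA for single-record cells. Means here equal the
#' cell means of [two_way_anova()] exactly.
#'
#' @param records data.frame with columns `pathology`, `severity`,
#'   `DX_mm`, `H_mm`, `SM`, `PSM_mm`.
#' @return Object of class `cohort_report`: list of per-metric matrices
#'   `mean`, `se`, `n` (rows: metrics, columns: cells in the layout
#'   order above).
#' @export
cohort_report <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  pathologies <- c("spondylolisthesis", "scoliosis")
  severities <- sort(unique(records$severity))
  metrics <- c("DX_mm", "SM", "PSM_mm", "H_mm")
  cells <- expand.grid(severity = severities, pathology = pathologies,
                       stringsAsFactors = FALSE)[, c(2, 1)]
  lab <- paste(cells$pathology, cells$severity, sep = ".")
  mk <- function(fun) {
    m <- matrix(NA_real_, length(metrics), nrow(cells),
                dimnames = list(metrics, lab))
    for (i in seq_len(nrow(cells))) {
      sub <- records[records$pathology == cells$pathology[i] &
                       records$severity == cells$severity[i], , drop = FALSE]
      for (met in metrics) m[met, i] <- fun(sub[[met]])
    }
    m
  }
  structure(list(
    mean = mk(function(v) if (length(v)) mean(v) else NA_real_),
    se = mk(function(v) if (length(v) >= 2) stats::sd(v) / sqrt(length(v))
            else NA_real_),
    n = mk(length)),
    class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, digits = 3, ...) {
  cat("<cohort_report> mean +/- SE per pathology x severity cell\n")
  txt <- matrix(sprintf("%.*g +/- %.*g", digits, x$mean, digits, x$se),
                nrow(x$mean), ncol(x$mean),
                dimnames = dimnames(x$mean))
  print(txt, quote = FALSE)
  invisible(x)
}

#' Markdown rendering of a cohort report
#'
#' @param x a [cohort_report()].
#' @param digits significant digits.
#' @return character vector of Markdown table lines.
#' @export
format_markdown <- function(x, digits = 3) {
  stopifnot(inherits(x, "cohort_report"))
  hdr <- c("metric", colnames(x$mean))
  lines <- c(paste0("| ", paste(hdr, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"))
  for (i in seq_len(nrow(x$mean))) {
    cells <- sprintf("%.*g ± %.*g", digits, x$mean[i, ], digits, x$se[i, ])
    lines <- c(lines, paste0("| ", rownames(x$mean)[i], " | ",
                             paste(cells, collapse = " | "), " |"))
  }
  lines
}

#' Simulate a null cohort of descriptor records
#'
#' Draws a balanced pathology-by-severity cohort whose descriptors have
#' identical distributions in every cell (no injected effects), for
#' type-I-error studies of [two_way_anova()].
#'
#' @param n_per_cell records per cell.
#' @param means,sds named numeric vectors over the four descriptors.
#' @return record data.frame (same layout as [cohort_truth_records()]).
#' @export
simulate_null_cohort <- function(n_per_cell = 10L,
                                 means = c(DX_mm = 1, H_mm = 8, SM = 900,
                                           PSM_mm = 11),
                                 sds = c(DX_mm = 0.5, H_mm = 1.2, SM = 280,
                                         PSM_mm = 2)) {
  cells <- expand.grid(pathology = c("spondylolisthesis", "scoliosis"),
                       severity = 1:3, stringsAsFactors = FALSE)
  n <- nrow(cells) * n_per_cell
  idx <- rep(seq_len(nrow(cells)), each = n_per_cell)
  data.frame(subject = sprintf("sim-%03d", seq_len(n)),
             pathology = cells$pathology[idx],
             severity = cells$severity[idx],
             disc_level = NA_character_,
             DX_mm = stats::rnorm(n, means["DX_mm"], sds["DX_mm"]),
             H_mm = stats::rnorm(n, means["H_mm"], sds["H_mm"]),
             SM = stats::rnorm(n, means["SM"], sds["SM"]),
             PSM_mm = stats::rnorm(n, means["PSM_mm"], sds["PSM_mm"]),
             stringsAsFactors = FALSE)
}
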