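make_repeats <- function(dx, h = 7, sm = 1000, psm = 9,
                         observer = rep("A", length(dx))) {
  data.frame(observer = observer, DX_mm = dx, H_mm = h, SM = sm, PSM_mm = psm)
}

test_that("reproducibility SDs use the n-1 denominator and % for SM", {
  same <- make_repeats(rep(1.2, 6), observer = rep(c("A", "B"), each = 3))
  r <- reproducibility_sd(same)
  expect_equal(unname(r$pooled), rep(0, 4))

  r2 <- reproducibility_sd(make_repeats(c(1, 2, 3)))
  expect_equal(unname(r2$pooled["DX_mm"]), 1.0)

  r3 <- reproducibility_sd(make_repeats(c(1, 1), sm = c(1000, 1001)))
  expect_equal(unname(r3$pooled["SM_pct"]), 0.0707, tolerance = 1e-3)

  expect_error(reproducibility_sd(make_repeats(1)), "insufficient")
})

test_that("reproducibility is invariant to permuting repeats within observers", {
  set.seed(3)
  df <- make_repeats(rnorm(6, 1, 0.2), h = rnorm(6, 7, 0.1),
                     sm = rnorm(6, 1000, 5), psm = rnorm(6, 9, 0.3),
                     observer = rep(c("A", "B"), each = 3))
  shuffled <- df[c(3, 1, 2, 6, 5, 4), ]
  expect_equal(reproducibility_sd(df)$pooled,
               reproducibility_sd(shuffled)$pooled)
  expect_equal(reproducibility_sd(df)$per_observer,
               reproducibility_sd(shuffled)$per_observer)
})

sim_records <- function(n_per_cell, effects = c(path = 0, sev = 0)) {
  cells <- expand.grid(pathology = c("spondylolisthesis", "scoliosis"),
                       severity = 1:3, stringsAsFactors = FALSE)
  idx <- rep(seq_len(nrow(cells)), times = n_per_cell)
  n <- length(idx)
  mu <- effects["path"] * (cells$pathology[idx] == "scoliosis") +
    effects["sev"] * cells$severity[idx]
  data.frame(pathology = cells$pathology[idx], severity = cells$severity[idx],
             PSM_mm = stats::rnorm(n, 10 + mu, 1))
}

test_that("balanced two-way ANOVA matches the base-R sequential fit", {
  set.seed(21)
  rec <- sim_records(rep(6L, 6), c(path = 2, sev = 0.8))
  mine <- two_way_anova(rec, "PSM_mm")
  # balanced design: Type III and sequential sums of squares coincide
  ref <- stats::anova(stats::lm(PSM_mm ~ factor(pathology) * factor(severity),
                                data = rec))
  expect_equal(mine$table$F, ref$`F value`[1:3], tolerance = 1e-9)
  expect_equal(mine$table$p, ref$`Pr(>F)`[1:3], tolerance = 1e-9)
})

test_that("unbalanced Type-III F matches an independent model comparison", {
  set.seed(22)
  rec <- sim_records(c(3L, 9L, 5L, 7L, 4L, 8L), c(path = 1.5, sev = 0.5))
  mine <- two_way_anova(rec, "PSM_mm")
  # independent route: full sum-contrast model vs the model with the
  # factor's columns removed, compared by an extra-sum-of-squares F test
  X <- stats::model.matrix(~ pathology * severity,
                           data = transform(rec,
                                            pathology = factor(pathology),
                                            severity = factor(severity)),
                           contrasts.arg = list(pathology = "contr.sum",
                                                severity = "contr.sum"))
  y <- rec$PSM_mm
  rss <- function(M) sum(stats::lsfit(M, y, intercept = FALSE)$residuals^2)
  full <- rss(X)
  df_res <- nrow(X) - ncol(X)
  for (i in 1:2) {
    cols <- if (i == 1) "pathology1" else c("severity1", "severity2")
    red <- rss(X[, setdiff(colnames(X), cols), drop = FALSE])
    Fval <- ((red - full) / length(cols)) / (full / df_res)
    expect_equal(mine$table$F[i], Fval, tolerance = 1e-8)
  }
})

test_that("degenerate and rank-deficient designs are flagged", {
  rec <- sim_records(rep(3L, 6))
  one_level <- rec[rec$pathology == "scoliosis", ]
  expect_error(two_way_anova(one_level, "PSM_mm"), "pathology")
  one_sev <- rec[rec$severity == 1, ]
  expect_error(two_way_anova(one_sev, "PSM_mm"), "severity")

  holes <- rec[!(rec$pathology == "scoliosis" & rec$severity == 3), ]
  expect_warning(a <- two_way_anova(holes, "PSM_mm"), "interaction dropped")
  expect_true(is.na(a$table$F[3]))
  expect_false(is.na(a$table$p[1]))

  flat <- rec; flat$PSM_mm <- 5
  expect_warning(d <- two_way_anova(flat, "PSM_mm"), "residual variance")
  expect_true(d$degenerate)
  expect_true(all(is.na(d$table$F)))
})

test_that("cohort report lays out cells and matches ANOVA cell means", {
  rec <- data.frame(pathology = rep(c("spondylolisthesis", "scoliosis"),
                                    each = 6),
                    severity = rep(rep(1:3, each = 2), 2),
                    DX_mm = 1, H_mm = 7,
                    SM = 900, PSM_mm = c(8, 10, rep(9, 10)))
  rep_ <- cohort_report(rec)
  expect_equal(colnames(rep_$mean),
               c("spondylolisthesis.1", "spondylolisthesis.2",
                 "spondylolisthesis.3", "scoliosis.1", "scoliosis.2",
                 "scoliosis.3"))
  expect_equal(rep_$mean["PSM_mm", "spondylolisthesis.1"], 9)  # mean(8, 10)
  expect_equal(rep_$se["PSM_mm", "spondylolisthesis.1"], 1)    # sd/sqrt(2)

  a <- suppressWarnings(two_way_anova(rec, "PSM_mm"))
  for (i in seq_len(nrow(a$cell_means))) {
    lab <- paste(a$cell_means$pathology[i], a$cell_means$severity[i], sep = ".")
    expect_identical(rep_$mean["PSM_mm", lab], a$cell_means$mean[i])
  }

  single <- rec[c(1, 3, 5, 7, 9, 11), ]
  expect_true(all(is.na(cohort_report(single)$se)))
  expect_error(cohort_report(rec[0, ]), "no records")

  md <- format_markdown(rep_)
  expect_match(md[1], "spondylolisthesis.1")
})
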