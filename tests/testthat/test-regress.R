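# Score regression, LOOCV, covariate significance and percentile shapes.

test_that("feature matrix shape, standardization and error paths", {
  rec <- tibble::tibble(
    subject_id = sprintf("s%d", 1:10),
    cranial_length = seq(110, 140, length.out = 10),
    cranial_width = seq(95, 115, length.out = 10),
    cranial_circumference = seq(340, 400, length.out = 10),
    total_surface_area = seq(2000, 3000, length.out = 10),
    average_si = seq(1.01, 1.2, length.out = 10))
  fm <- build_features(rec)
  expect_equal(dim(fm$F), c(10, 6))
  expect_equal(colnames(fm$F)[1], "(Intercept)")
  expect_lt(max(abs(colMeans(fm$F[, -1]))), 1e-12)

  fm1 <- build_features(rec, "L")
  expect_equal(dim(fm1$F), c(10, 2))

  recz <- rec
  recz$cranial_length <- 120
  expect_error(build_features(recz, "L"), "degenerate covariate")
  recn <- rec
  recn$average_si[3] <- NA
  expect_error(build_features(recn, "SI"), "missing covariate.*s3")
})

test_that("pseudoinverse regression recovers a constructed coefficient
           matrix", {
  pop <- linear_population(n = 20)
  sm <- standardize_shapes(geometry_matrix(pop$sl))
  pca <- fit_shape_pca(sm, 4)
  set.seed(2)
  F0 <- cbind(1, matrix(stats::rnorm(20 * 3), 20))
  colnames(F0) <- c("(Intercept)", "f1", "f2", "f3")
  C0 <- matrix(stats::rnorm(16), 4, 4)
  fake <- pca
  fake$scores <- F0 %*% t(C0)
  fm <- structure(list(F = F0, feature_names = c("f1", "f2", "f3"),
                       center = rep(0, 3), scale = rep(1, 3),
                       ranges = rbind(rep(-9, 3), rep(9, 3)),
                       intercept = TRUE), class = "feature_matrix")
  reg <- fit_shape_regression(fake, fm)
  expect_lt(max(abs(reg$coef - C0)), 1e-10)

  # square invertible F: exact inverse
  F_sq <- matrix(stats::rnorm(16), 4, 4)
  fake2 <- pca
  fake2$scores <- fake$scores[1:4, ]
  fm2 <- fm
  fm2$F <- F_sq
  reg2 <- fit_shape_regression(fake2, fm2)
  expect_lt(max(abs(reg2$coef - t(solve(F_sq) %*% fake2$scores))), 1e-8)

  # least-squares optimality: random perturbations never do better
  reg3 <- fit_shape_regression(pca, pop$records, c("size", "area", "si"))
  rss <- sum((pca$scores - reg3$fitted_scores)^2)
  set.seed(3)
  for (r in 1:10) {
    Cp <- reg3$coef + matrix(stats::rnorm(length(reg3$coef), 0, 0.01),
                             nrow(reg3$coef))
    expect_gte(sum((pca$scores - reg3$features$F %*% t(Cp))^2), rss - 1e-10)
  }
})

test_that("predict_shape is affine: midpoints map to midpoints, mean covariates
           to the mean-score shape", {
  pop <- linear_population(n = 15)
  sm <- standardize_shapes(geometry_matrix(pop$sl))
  pca <- fit_shape_pca(sm, 3)
  reg <- fit_shape_regression(pca, pop$records, c("size", "area", "si"))
  c1 <- list(size = 0.95, area = 0.98, si = 0.9)
  c2 <- list(size = 1.05, area = 1.04, si = 1.2)
  mid <- list(size = 1.00, area = 1.01, si = 1.05)
  g1 <- suppressWarnings(predict_shape(reg, c1))
  g2 <- suppressWarnings(predict_shape(reg, c2))
  gm <- suppressWarnings(predict_shape(reg, mid))
  expect_lt(max(abs((as.matrix(g1[, c("x", "y", "z")]) +
                     as.matrix(g2[, c("x", "y", "z")])) / 2 -
                    as.matrix(gm[, c("x", "y", "z")]))), 1e-9)

  mean_cov <- as.list(colMeans(pop$records[, c("size", "area", "si")]))
  g_mean <- predict_shape(reg, mean_cov)
  g_scores <- reconstruct_subject(pca, colMeans(reg$fitted_scores))
  expect_lmd_lt(g_mean, g_scores, 1e-9)

  expect_warning(predict_shape(reg, list(size = 3, area = 1, si = 1)),
                 "extrapolation")
})

test_that("noiseless linear population: every LOOCV held-out LMD < 1e-6 and the
           per-part table has 9 parts", {
  pop <- linear_population(n = 20)
  part <- suppressWarnings(
    partition_sutures(pop$sl[pop$sl$subject_id == "S001", ]))
  lo <- suppressWarnings(loocv_shape_model(pop$sl, pop$records,
                                           c("size", "area", "si"),
                                           k = 3, partition = part))
  expect_equal(nrow(lo$per_subject), 20)
  expect_lt(max(lo$per_subject$lmd), 1e-6)
  expect_setequal(unique(lo$per_part$part), suturemorph:::part_names)
  expect_equal(nrow(lo$per_part), 20 * 9)
  expect_equal(sort(unique(lo$measures$suture)),
               sort(c("metopic", "sagittal", "coronal", "squamosal",
                      "lambdoid")))
  expect_equal(glance(lo)$n, 20)
})

test_that("LOOCV works at the minimal N = 3 and never uses the held-out
           geometry (poisoned-subject check)", {
  pop <- linear_population(n = 12)
  sl3 <- pop$sl[pop$sl$subject_id %in% c("S001", "S002", "S003"), ]
  lo3 <- suppressWarnings(loocv_shape_model(sl3, pop$records[1:3, ],
                                            c("size", "area"), k = 1))
  expect_equal(nrow(lo3$per_subject), 3)

  # poison subject S005's geometry: its own prediction must not change,
  # because the fold fits on the other subjects and predicts from covariates
  lo_clean <- suppressWarnings(loocv_shape_model(
    pop$sl, pop$records, c("size", "area", "si"), k = 3))
  poisoned <- pop$sl
  rows <- poisoned$subject_id == "S005"
  set.seed(99)
  poisoned$x[rows] <- stats::rnorm(sum(rows), 0, 100)
  lo_poison <- suppressWarnings(loocv_shape_model(
    poisoned, pop$records, c("size", "area", "si"), k = 3))
  # compare the predicted-vs-true LMD indirectly: rebuild the prediction
  i <- which(lo_clean$per_subject$subject_id == "S005")
  expect_equal(lo_clean$per_subject$lmd[-i] > 0,
               lo_poison$per_subject$lmd[-i] > 0)
  # direct check: prediction for S005 from both runs coincides
  predict_for <- function(sl) {
    G0 <- geometry_matrix(sl)
    topo <- attr(G0, "topology")
    idx <- which(rownames(G0) == "S005")
    Gtrain <- G0[-idx, , drop = FALSE]
    attr(Gtrain, "topology") <- topo
    sm <- standardize_shapes(Gtrain)
    pca <- fit_shape_pca(sm, 3)
    reg <- fit_shape_regression(pca, pop$records[-idx, ],
                                c("size", "area", "si"))
    suppressWarnings(predict_shape(reg, pop$records[idx, ]))
  }
  p1 <- predict_for(pop$sl)
  p2 <- predict_for(poisoned)
  expect_identical(p1$x, p2$x)
})

test_that("covariate significance: perfect fits, nested-model dominance and
           Bonferroni option", {
  pop <- linear_population(n = 25)
  sm <- standardize_shapes(geometry_matrix(pop$sl))
  pca <- fit_shape_pca(sm, 3)
  rec <- pop$records
  rec$exact <- pca$scores[, 1] * 2 + 5   # scores exactly proportional
  sig <- suppressWarnings(covariate_significance(pca, rec,
                                                 c("exact", "area", "si")))
  row1 <- sig[sig$pc == 1 & sig$covariate == "exact", ]
  expect_equal(row1$r_squared, 1, tolerance = 1e-9)
  expect_lt(row1$p_value, 1e-10)
  expect_equal(row1$stars, "***")
  for (j in unique(sig$pc)) {
    all_r2 <- sig$r_squared[sig$pc == j & sig$covariate == "ALL"]
    singles <- sig$r_squared[sig$pc == j & sig$covariate != "ALL"]
    expect_true(all(all_r2 >= singles - 1e-10))
  }
  sig_b <- suppressWarnings(covariate_significance(
    pca, rec, c("exact", "area", "si"), bonferroni = TRUE))
  expect_true(all(sig_b$p_value >= sig$p_value - 1e-15))
})

test_that("null p-values are calibrated (type-I error within 2 SE of 5%)", {
  set.seed(77)
  n_rep <- 600
  n <- 25
  rejections <- 0L
  for (r in seq_len(n_rep)) {
    scores <- matrix(stats::rnorm(n), n, 1)
    rec <- tibble::tibble(subject_id = as.character(seq_len(n)),
                          cov = stats::rnorm(n))
    sig <- covariate_significance(scores, rec, "cov")
    p <- sig$p_value[sig$covariate == "cov"]
    rejections <- rejections + (p < 0.05)
  }
  rate <- rejections / n_rep
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), 2 * se + 1e-12)
})

test_that("percentile shapes: counts, self-normalization and the symmetric
           median", {
  pop <- linear_population(n = 21)
  # symmetric covariates about their mean: median = mean
  rec <- pop$records
  delta <- seq(-0.05, 0.05, length.out = 21)
  rec$size <- 1 + delta
  rec$area <- 1 + 0.5 * delta
  rec$si <- 1 - delta
  G0 <- pop$latents$size %o% rep(1, 2400)  # not used; rebuild geometry linear
  sm <- standardize_shapes(geometry_matrix(pop$sl))
  pca <- fit_shape_pca(sm, 3)
  reg <- fit_shape_regression(pca, rec, c("size", "area", "si"))
  part <- suppressWarnings(
    partition_sutures(pop$sl[pop$sl$subject_id == "S001", ]))
  pct <- suppressWarnings(percentile_shapes(reg, rec, partition = part))
  expect_equal(unique(pct$shapes$percentile), c(5, 25, 50, 75, 95))
  expect_equal(nrow(pct$shapes), 5 * 800)
  norm_row1 <- as.numeric(pct$normalized_sizes[1, -1])
  expect_equal(norm_row1, rep(1, length(norm_row1)))

  g50 <- pct$shapes[pct$shapes$percentile == 50, ]
  g_mean <- suppressWarnings(
    predict_shape(reg, as.list(colMeans(rec[, c("size", "area", "si")]))))
  expect_lmd_lt(g50, g_mean, 1e-9)

  expect_error(percentile_shapes(reg, rec, percentiles = c(0, 50)),
               "must lie in")
})
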