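# Standardization, PCA, kernel PCA, LMD and the cross-validation harness.

test_that("standardization uses the population SD and inverts exactly", {
  G0 <- cbind(c(1, 2, 3), c(5, 5, 5), c(0, 10, 20))
  rownames(G0) <- c("a", "b", "c")
  sm <- standardize_shapes(G0)
  expect_equal(unname(sm$G[, 1]), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-12)
  expect_true(sm$zero_var[2])
  expect_equal(unname(sm$G[, 2]), c(0, 0, 0))
  expect_lt(max(abs(inverse_standardize(sm, sm$G) - G0)), 1e-12)
})

test_that("classic PCA: orthonormal basis, nonincreasing variance ratios,
           low-rank recovery", {
  G0 <- rank2_matrix()
  sm <- standardize_shapes(G0)
  pca <- fit_shape_pca(sm, 5)
  expect_lt(max(abs(tcrossprod(pca$basis) - diag(5))), 1e-8)
  expect_true(all(diff(pca$evr) <= 1e-12))
  expect_lte(sum(pca$evr), 1 + 1e-12)
  expect_gt(sum(pca$evr[1:2]), 0.999)
  expect_error(fit_shape_pca(sm, 0), "k must be")
  expect_error(fit_shape_pca(sm, 25), "k must be")
})

test_that("full-rank reconstruction and the mean shape at zero scores", {
  pop <- linear_population(n = 8)
  sm <- standardize_shapes(geometry_matrix(pop$sl))
  pca <- fit_shape_pca(sm, 7)
  for (i in c(1, 5)) {
    rec <- reconstruct_subject(pca, pca$scores[i, ])
    expect_lmd_lt(rec, pop$sl[pop$sl$subject_id == rownames(pca$scores)[i], ],
                  1e-8)
  }
  mean_shape <- reconstruct_subject(pca, rep(0, 7))
  expect_lmd_lt(mean_shape, suturemorph:::rows_to_points(sm$center), 1e-10)
  expect_error(reconstruct_subject(pca, rep(0, 3)), "scores length")
})

test_that("train LMD is nonincreasing in k", {
  G0 <- rank2_matrix(n = 15, p = 40, seed = 21) +
    matrix(stats::rnorm(15 * 40, 0, 0.3), 15)
  sm <- standardize_shapes(G0)
  lmds <- vapply(c(1, 3, 6, 10), function(k) {
    pca <- fit_shape_pca(sm, k)
    rec <- inverse_standardize(sm, reconstruct_rows(pca, pca$scores))
    mean(abs(rec - G0))
  }, numeric(1))
  expect_true(all(diff(lmds) <= 1e-10))
})

test_that("linear-kernel kPCA reconstructions match classic PCA", {
  G0 <- rank2_matrix(n = 12, p = 24, seed = 5) +
    matrix(stats::rnorm(12 * 24, 0, 0.2), 12)
  sm <- standardize_shapes(G0)
  pca <- fit_shape_pca(sm, 4)
  kp <- fit_shape_kpca(sm, "linear", 4)
  r1 <- inverse_standardize(sm, reconstruct_rows(pca, pca$scores))
  r2 <- inverse_standardize(sm, reconstruct_rows(kp, kp$scores))
  expect_lt(max(abs(r1 - r2)), 1e-6)
  # held-out projection agrees too
  new <- matrix(stats::rnorm(2 * 24), 2)
  ns <- standardize_rows(sm, new)
  expect_lt(max(abs(reconstruct_rows(pca, project_scores(pca, ns)) -
                    reconstruct_rows(kp, project_scores(kp, ns)))), 1e-6)
})

test_that("nonlinear kernels fit and reconstruct finitely; k bounds enforced", {
  G0 <- rank2_matrix(n = 10, p = 18, seed = 7)
  sm <- standardize_shapes(G0)
  for (kern in c("cosine", "rbf", "laplacian")) {
    # rank-deficient fixtures may trigger the eigenvalue-clipping warning
    m <- suppressWarnings(fit_shape_kpca(sm, kern, 3))
    rec <- inverse_standardize(sm, reconstruct_rows(m, m$scores))
    expect_true(all(is.finite(rec)))
  }
  expect_warning(fit_shape_kpca(sm, "sigmoid", 9), "clipped")
  expect_error(fit_shape_kpca(sm, "rbf", 10), "k must be")
})

test_that("kernel PCA scores agree with an independent implementation", {
  skip_if_not_installed("kernlab")
  G0 <- rank2_matrix(n = 12, p = 20, seed = 3) +
    matrix(stats::rnorm(12 * 20, 0, 0.5), 12)
  sm <- standardize_shapes(G0)
  gamma <- 0.05
  ours <- fit_shape_kpca(sm, "rbf", 3, gamma = gamma)
  ref <- kernlab::kpca(sm$G, kernel = "rbfdot",
                       kpar = list(sigma = gamma), features = 3)
  sc_ref <- kernlab::rotated(ref)
  for (j in 1:3) {
    expect_equal(abs(stats::cor(ours$scores[, j], sc_ref[, j])), 1,
                 tolerance = 1e-6)
  }
})

test_that("LMD: identity, uniform offset and a direct arithmetic oracle", {
  set.seed(44)
  A <- matrix(stats::rnorm(30), 10, 3)
  expect_identical(lmd(A, A), 0)
  expect_equal(lmd(A, sweep(A, 2, c(0, 0, -2))), 2)
  B <- matrix(stats::rnorm(30), 10, 3)
  expect_equal(lmd(A, B), mean(sqrt(rowSums((A - B)^2))))
  expect_error(lmd(A, B[1:5, ]), "differ in length")
})

test_that("fold sizes are as equal as possible (9x7 + 1x6 for N = 69)", {
  f <- make_folds(69, 10, seed = 3)
  expect_equal(sort(as.integer(table(f))), c(6, rep(7, 9)))
  expect_identical(make_folds(69, 10, 3), make_folds(69, 10, 3))
})

test_that("cross-validation recovers a noiseless low-rank population and is
           deterministic", {
  pop <- linear_population(n = 30)
  cv <- crossval_reduction(pop$sl, methods = c("classic_pca", "kpca_linear"),
                           k = 3, folds = 10, seed = 5)
  expect_lt(cv$table$test_lmd[cv$table$method == "classic_pca"], 1e-6)
  expect_lt(abs(cv$table$test_lmd[1] - cv$table$test_lmd[2]), 1e-6)
  cv2 <- crossval_reduction(pop$sl, methods = c("classic_pca", "kpca_linear"),
                            k = 3, folds = 10, seed = 5)
  expect_identical(cv$table, cv2$table)
  expect_true(all(cv$detail$test_lmd >= 0))
})

test_that("a failing method is recorded without stopping the run", {
  G0 <- rank2_matrix(n = 8, p = 12, seed = 2)
  cv <- suppressWarnings(
    crossval_reduction(G0, methods = c("classic_pca", "nonsense_method"),
                       k = 2, folds = 4, seed = 1))
  expect_equal(cv$table$failed_folds[cv$table$method == "nonsense_method"], 4)
  expect_equal(cv$table$failed_folds[cv$table$method == "classic_pca"], 0)
})

test_that("components_for_variance finds the stated threshold", {
  G0 <- rank2_matrix()
  sm <- standardize_shapes(G0)
  expect_lte(components_for_variance(sm, 0.999), 2)
  pca <- fit_shape_pca(sm, components_for_variance(sm, 0.95))
  expect_gte(sum(pca$evr), 0.95)
})

test_that("tidy and glance methods return the expected summaries", {
  G0 <- rank2_matrix()
  pca <- fit_shape_pca(standardize_shapes(G0), 3)
  td <- tidy(pca)
  expect_equal(td$cumulative, cumsum(td$evr))
  gl <- glance(pca)
  expect_equal(gl$k, 3)
  expect_equal(gl$n, 20)
})
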