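# Standardization, classic PCA, kernel PCA, the LMD metric, and the k-fold
# cross-validated comparison of dimension-reduction methods.

#' Flatten semilandmarks to a subjects-by-coordinates geometry matrix
#'
#' Row i holds subject i's coordinates as (x1, y1, z1, x2, y2, z2, ...), so a
#' set of 800 semilandmarks yields 2400 columns.
#'
#' @param sl Multi-subject semilandmark tibble with identical topology.
#' @return Matrix with subject ids as row names and attribute `topology`.
#' @export
geometry_matrix <- function(sl) {
  arr <- sl_to_array(sl)
  N <- dim(arr)[3]
  G0 <- t(vapply(seq_len(N), function(i) as.numeric(t(arr[, , i])),
                 numeric(dim(arr)[1] * 3)))
  rownames(G0) <- dimnames(arr)[[3]]
  attr(G0, "topology") <- attr(arr, "topology")
  G0
}

rows_to_points <- function(row) matrix(row, ncol = 3, byrow = TRUE)

#' Standardize a geometry matrix
#'
#' Column-wise z-scoring with the population (divide-by-N) standard deviation;
#' the mean/SD pair is stored for exact inversion. Zero-variance columns are
#' passed through (SD treated as 1) and flagged.
#'
#' @param G0 Raw geometry matrix from [geometry_matrix()] (N >= 2 rows).
#' @return Object of class `shape_matrix`: `G0`, standardized `G`, `center`,
#'   `scale`, `zero_var` (logical per column), `topology`.
#' @export
standardize_shapes <- function(G0) {
  if (is.data.frame(G0) || (!is.matrix(G0) && !is.null(G0$subject_id))) {
    G0 <- geometry_matrix(G0)
  }
  if (nrow(G0) < 2) stop("standardization needs >= 2 subjects", call. = FALSE)
  center <- colMeans(G0)
  centered <- sweep(G0, 2, center)
  scale_ <- sqrt(colMeans(centered^2))
  zero_var <- scale_ < 1e-12
  scale_[zero_var] <- 1
  structure(
    list(G0 = G0, G = sweep(centered, 2, scale_, "/"), center = center,
         scale = scale_, zero_var = zero_var,
         topology = attr(G0, "topology")),
    class = "shape_matrix"
  )
}

#' Apply / invert a stored standardization
#'
#' @param sm A `shape_matrix`.
#' @param rows Matrix of raw (for `standardize_rows`) or standardized (for
#'   `inverse_standardize`) coordinate rows.
#' @return Matrix of the same shape.
#' @export
standardize_rows <- function(sm, rows) {
  sweep(sweep(rows, 2, sm$center), 2, sm$scale, "/")
}

#' @rdname standardize_rows
#' @export
inverse_standardize <- function(sm, rows) {
  sweep(sweep(rows, 2, sm$scale, "*"), 2, -sm$center)
}

#' Classic PCA of the standardized geometry matrix
#'
#' Eigendecomposition via the SVD of the standardized matrix G: scores
#' `Sk = U_k D_k` (N x k) and orthonormal component rows `Pk` (k x 2400), so
#' `G ~ Sk %*% Pk` is the best rank-k approximation in the Frobenius norm.
#' Component signs are fixed so each component's largest-magnitude loading is
#' positive.
#'
#' @param sm A `shape_matrix` from [standardize_shapes()].
#' @param k Number of components, `1 <= k <= min(N - 1, ncol(G))`.
#' @return Object of class `shape_pca` with `basis` (k x p), `scores` (N x k),
#'   `evr` (explained variance ratio per component), `sdev`, and the embedded
#'   standardization.
#' @export
fit_shape_pca <- function(sm, k) {
  stopifnot(inherits(sm, "shape_matrix"))
  N <- nrow(sm$G)
  kmax <- min(N - 1L, ncol(sm$G))
  if (k < 1 || k > kmax) {
    stop("k must be in [1, ", kmax, "]", call. = FALSE)
  }
  dec <- svd(sm$G, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- dec$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  basis <- t(dec$v[, seq_len(k), drop = FALSE] %*% diag(flip, k))
  scores <- dec$u[, seq_len(k), drop = FALSE] %*% diag(dec$d[seq_len(k)] *
                                                         flip, k)
  rownames(scores) <- rownames(sm$G)
  structure(
    list(method = "classic_pca", k = k, basis = basis, scores = scores,
         sdev = dec$d[seq_len(k)] / sqrt(N),
         evr = dec$d[seq_len(k)]^2 / sum(dec$d^2), sm = sm),
    class = c("shape_pca", "shape_reduction")
  )
}

#' Project new subjects into a fitted reduction
#'
#' @param model A fitted `shape_reduction` (classic PCA, kernel PCA or VAE).
#' @param G_std Standardized coordinate rows (use the model's own
#'   standardization via [standardize_rows()]).
#' @return Score matrix (rows x k).
#' @export
project_scores <- function(model, G_std) UseMethod("project_scores")

#' @export
project_scores.shape_pca <- function(model, G_std) {
  G_std %*% t(model$basis)
}

#' Reconstruct standardized coordinate rows from scores
#'
#' @inheritParams project_scores
#' @param scores Score matrix (rows x k).
#' @return Standardized coordinate rows.
#' @export
reconstruct_rows <- function(model, scores) UseMethod("reconstruct_rows")

#' @export
reconstruct_rows.shape_pca <- function(model, scores) {
  scores %*% model$basis
}

#' Reconstruct a subject's geometry from component scores
#'
#' Inverse-standardizes the rank-k reconstruction and reshapes it to an
#' 800 x 3 point set (zero scores give the standardization mean shape).
#'
#' @param model A fitted `shape_reduction`.
#' @param scores_row Numeric vector of length k (one subject's scores).
#' @return Tibble with `border`, `ordinal`, `x`, `y`, `z` (if topology is
#'   known) or a point matrix.
#' @export
reconstruct_subject <- function(model, scores_row) {
  scores_row <- matrix(as.numeric(scores_row), nrow = 1)
  if (ncol(scores_row) != model$k) {
    stop("scores length ", ncol(scores_row), " != k = ", model$k,
         call. = FALSE)
  }
  row <- inverse_standardize(model$sm, reconstruct_rows(model, scores_row))
  pts <- rows_to_points(row)
  topo <- model$sm$topology
  if (is.null(topo)) return(pts)
  tibble::tibble(border = topo$border, ordinal = topo$ordinal,
                 x = pts[, 1], y = pts[, 2], z = pts[, 3])
}

#' Number of components needed to reach a variance threshold
#'
#' @param sm A `shape_matrix`.
#' @param threshold Cumulative explained-variance fraction (default 0.95).
#' @return Integer component count.
#' @export
components_for_variance <- function(sm, threshold = 0.95) {
  full <- fit_shape_pca(sm, min(nrow(sm$G) - 1L, ncol(sm$G)))
  max(1L, which(cumsum(full$evr) >= threshold)[1])
}

# ---- kernel PCA --------------------------------------------------------------

kernel_matrix <- function(X, Y, kernel, gamma, coef0) {
  switch(kernel,
    linear = tcrossprod(X, Y),
    cosine = {
      nx <- sqrt(rowSums(X^2)); ny <- sqrt(rowSums(Y^2))
      tcrossprod(X, Y) / outer(pmax(nx, 1e-300), pmax(ny, 1e-300))
    },
    rbf = exp(-gamma * cross_dist2(X, Y)),
    sigmoid = tanh(gamma * tcrossprod(X, Y) + coef0),
    laplacian = {
      n <- nrow(X); m <- nrow(Y)
      D <- matrix(0, n, m)
      for (j in seq_len(ncol(X))) D <- D + abs(outer(X[, j], Y[, j], "-"))
      exp(-gamma * D)
    },
    stop("unknown kernel: ", kernel, call. = FALSE))
}

#' Kernel PCA of the standardized geometry matrix
#'
#' Kernel principal components with one of five kernels (linear, cosine, rbf,
#' sigmoid, laplacian). Reconstruction uses a learned pre-image map: a
#' ridge-regularized least-squares map from score space back to standardized
#' input space, so the LMD of kernel-PCA reconstructions is computable; for
#' the linear kernel this reproduces classic PCA reconstructions. Non-PSD
#' kernel matrices (sigmoid) have negative eigenvalues clipped with a warning.
#'
#' @inheritParams fit_shape_pca
#' @param kernel One of `"linear"`, `"cosine"`, `"rbf"`, `"sigmoid"`,
#'   `"laplacian"`.
#' @param gamma Kernel bandwidth; default `1 / ncol(G)`.
#' @param coef0 Sigmoid offset; default 1.
#' @param preimage_ridge Ridge of the pre-image map; default 1e-8.
#' @return Object of class `shape_kpca` (a `shape_reduction`).
#' @export
fit_shape_kpca <- function(sm, kernel = c("linear", "cosine", "rbf",
                                          "sigmoid", "laplacian"),
                           k, gamma = NULL, coef0 = 1,
                           preimage_ridge = 1e-8) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(sm, "shape_matrix"))
  N <- nrow(sm$G)
  if (k < 1 || k > N - 1L) {
    stop("k must be in [1, ", N - 1L, "] for kernel PCA", call. = FALSE)
  }
  gamma <- gamma %||% (1 / ncol(sm$G))
  K <- kernel_matrix(sm$G, sm$G, kernel, gamma, coef0)
  one <- matrix(1 / N, N, N)
  Kc <- K - one %*% K - K %*% one + one %*% K %*% one
  eig <- eigen((Kc + t(Kc)) / 2, symmetric = TRUE)
  lam <- eig$values[seq_len(k)]
  lam_floor <- 1e-12 * max(abs(eig$values), 1e-300)
  if (any(lam <= lam_floor)) {
    warning("non-positive kernel eigenvalues clipped (", kernel, " kernel)",
            call. = FALSE)
    lam <- pmax(lam, lam_floor)
  }
  alpha <- eig$vectors[, seq_len(k), drop = FALSE]
  # normalize so that projections are alpha-weighted centered kernel rows
  alpha_n <- sweep(alpha, 2, sqrt(lam), "/")
  scores <- Kc %*% alpha_n
  # pre-image: ridge least squares from scores to standardized inputs
  StS <- crossprod(scores)
  ridge <- max(preimage_ridge, 1e-12 * mean(diag(StS)))
  W <- tryCatch(solve(StS + diag(ridge, k), crossprod(scores, sm$G)),
                error = function(e) {
                  MASS::ginv(StS + diag(ridge, k)) %*%
                    crossprod(scores, sm$G)
                })
  structure(
    list(method = paste0("kpca_", kernel), kernel = kernel, k = k,
         gamma = gamma, coef0 = coef0, alpha = alpha_n, K_train = K,
         scores = scores, preimage = W, sm = sm,
         evr = pmax(eig$values, 0)[seq_len(k)] / sum(pmax(eig$values, 0))),
    class = c("shape_kpca", "shape_reduction")
  )
}

#' @export
project_scores.shape_kpca <- function(model, G_std) {
  sm <- model$sm
  N <- nrow(sm$G)
  Kx <- kernel_matrix(G_std, sm$G, model$kernel, model$gamma, model$coef0)
  # center against the training kernel
  colm <- colMeans(model$K_train)
  Kxc <- sweep(Kx, 2, colm) -
    matrix(rowMeans(Kx), nrow(Kx), N) + mean(model$K_train)
  Kxc %*% model$alpha
}

#' @export
reconstruct_rows.shape_kpca <- function(model, scores) {
  scores %*% model$preimage
}

# ---- LMD and the cross-validated comparison ---------------------------------

#' Location mean deviation between two corresponding point sets
#'
#' Mean Euclidean distance between corresponding points of two configurations
#' (mm). Inputs may be n x 3 matrices, tibbles with `x,y,z`, or flattened
#' coordinate rows of equal length.
#'
#' @param A,B Corresponding point sets.
#' @return LMD in mm.
#' @export
lmd <- function(A, B) {
  to_pts <- function(x) {
    if (is.data.frame(x)) as.matrix(x[, c("x", "y", "z")])
    else if (is.matrix(x) && ncol(x) == 3) x
    else rows_to_points(as.numeric(x))
  }
  A <- to_pts(A); B <- to_pts(B)
  if (nrow(A) != nrow(B)) {
    stop("point sets differ in length (", nrow(A), " vs ", nrow(B), ")",
         call. = FALSE)
  }
  mean(sqrt(rowSums((A - B)^2)))
}

fit_reduction_method <- function(sm, method, k, vae_args = list()) {
  if (method == "classic_pca") {
    fit_shape_pca(sm, k)
  } else if (grepl("^kpca_", method)) {
    fit_shape_kpca(sm, sub("^kpca_", "", method), k)
  } else if (grepl("^vae_", method)) {
    do.call(fit_shape_vae,
            c(list(sm = sm, latent_dim = k, arch = sub("^vae_", "", method)),
              vae_args))
  } else {
    stop("unknown reduction method: ", method, call. = FALSE)
  }
}

#' Fold assignment with sizes as equal as possible
#'
#' For N subjects and `folds` folds, returns a shuffled assignment whose fold
#' sizes differ by at most one (e.g. 9 folds of 7 and 1 fold of 6 for N = 69).
#'
#' @param n Number of subjects.
#' @param folds Number of folds.
#' @param seed RNG seed.
#' @return Integer vector of fold labels.
#' @export
make_folds <- function(n, folds = 10L, seed = 1L) {
  stopifnot(n >= folds)
  set.seed(seed)
  sample(rep(seq_len(folds), length.out = n))
}

#' Cross-validated comparison of dimension-reduction methods
#'
#' Randomly partitions the subjects into folds of as-equal-as-possible size
#' (fixed seed), and for every method and fold fits on the training subjects
#' (standardization refit on the training fold), reconstructs both training
#' and held-out subjects, and records the LMD between reconstruction and
#' original geometry in mm. A method failure in a fold is recorded and the run
#' continues.
#'
#' @param sl Multi-subject semilandmark tibble (or raw geometry matrix).
#' @param methods Character vector: `"classic_pca"`, `"kpca_<kernel>"`,
#'   `"vae_dense"`, `"vae_conv"`.
#' @param k Number of components / latent dimensions.
#' @param folds Number of folds; default 10.
#' @param seed RNG seed for the fold assignment (and any stochastic method).
#' @param vae_args Extra arguments for the VAE methods.
#' @return Object of class `reduction_cv`: `table` (per-method mean train/test
#'   LMD), `detail` (per fold), `folds`, `seed`.
#' @export
crossval_reduction <- function(sl,
                               methods = c("classic_pca", "kpca_linear",
                                           "kpca_cosine", "kpca_rbf",
                                           "kpca_sigmoid", "kpca_laplacian"),
                               k = 10L, folds = 10L, seed = 1L,
                               vae_args = list()) {
  G0 <- if (is.matrix(sl)) sl else geometry_matrix(sl)
  N <- nrow(G0)
  assign_ <- make_folds(N, folds, seed)
  detail <- purrr::map_dfr(seq_len(folds), function(f) {
    train <- G0[assign_ != f, , drop = FALSE]
    test <- G0[assign_ == f, , drop = FALSE]
    sm <- standardize_shapes(train)
    kf <- min(k, nrow(train) - 1L)
    purrr::map_dfr(methods, function(m) {
      out <- tryCatch({
        model <- fit_reduction_method(sm, m, kf,
                                      c(vae_args, list(seed = seed + f)))
        rec_tr <- inverse_standardize(sm,
                                      reconstruct_rows(model, model$scores))
        train_lmd <- mean(vapply(seq_len(nrow(train)), function(i) {
          lmd(rec_tr[i, ], train[i, ])
        }, numeric(1)))
        sc_te <- project_scores(model, standardize_rows(sm, test))
        rec_te <- inverse_standardize(sm, reconstruct_rows(model, sc_te))
        test_lmd <- mean(vapply(seq_len(nrow(test)), function(i) {
          lmd(rec_te[i, ], test[i, ])
        }, numeric(1)))
        tibble::tibble(method = m, fold = f, train_lmd = train_lmd,
                       test_lmd = test_lmd, failed = FALSE)
      }, error = function(e) {
        tibble::tibble(method = m, fold = f, train_lmd = NA_real_,
                       test_lmd = NA_real_, failed = TRUE)
      })
      out
    })
  })
  table <- dplyr::summarise(
    dplyr::group_by(detail, .data$method),
    train_lmd = mean(.data$train_lmd[!.data$failed]),
    test_lmd = mean(.data$test_lmd[!.data$failed]),
    failed_folds = sum(.data$failed), .groups = "drop")
  table <- table[match(methods, table$method), ]
  structure(list(table = table, detail = detail, folds = folds, seed = seed),
            class = "reduction_cv")
}

#' @export
print.reduction_cv <- function(x, ...) {
  cat("<reduction_cv>:", x$folds, "folds, seed", x$seed, "\n")
  print(x$table, n = Inf)
  invisible(x)
}
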