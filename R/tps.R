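#' Thin-plate-spline interpolation of a height field
#'
#' Fits the interpolating thin-plate spline
#' \deqn{h(u,v) = a_0 + a_1 u + a_2 v + \sum_i c_i U(\|(u,v) - (u_i,v_i)\|)}
#' with kernel \eqn{U(r) = r^2 \log r} (and \eqn{U(0) = 0}) through scattered
#' height samples over a base plane. With the default `lambda = 0` the spline
#' interpolates the data exactly; a positive `lambda` gives a smoothing spline.
#' Duplicate base-plane locations are merged by averaging their heights; if the
#' heights at a duplicated location disagree by more than `dup_tol` this is an
#' error, because no single-valued height field exists.
#'
#' @param uv Two-column matrix (or data frame) of base-plane coordinates (mm).
#' @param h Numeric vector of heights (mm), one per row of `uv`.
#' @param lambda Non-negative regularization; 0 (default) interpolates.
#' @param dup_tol Maximum allowed height disagreement between duplicated
#'   base-plane points (mm).
#' @return An object of class `tps` with the spline coefficients. Evaluate it
#'   with [predict.tps()].
#' @examples
#' uv <- cbind(runif(20), runif(20))
#' f <- fit_tps(uv, 2 * uv[, 1] + 3 * uv[, 2] + 1)
#' max(abs(predict(f, uv) - (2 * uv[, 1] + 3 * uv[, 2] + 1))) < 1e-8
#' @export
fit_tps <- function(uv, h, lambda = 0, dup_tol = 1e-6) {
  uv <- as.matrix(uv)
  storage.mode(uv) <- "double"
  h <- as.numeric(h)
  stopifnot(ncol(uv) == 2, nrow(uv) == length(h))
  if (anyNA(uv) || anyNA(h)) stop("non-finite input to fit_tps", call. = FALSE)

  # merge duplicate projections (averaging heights)
  key <- paste(format_full(uv[, 1]), format_full(uv[, 2]))
  if (anyDuplicated(key)) {
    grp <- match(key, unique(key))
    rng <- tapply(h, grp, function(v) diff(range(v)))
    if (any(rng > dup_tol)) {
      stop("duplicate base-plane projections with conflicting heights",
           call. = FALSE)
    }
    h <- as.numeric(tapply(h, grp, mean))
    uv <- uv[!duplicated(grp), , drop = FALSE]
  }
  n <- nrow(uv)
  if (n < 4) stop("degenerate patch: need >= 4 points", call. = FALSE)
  sv <- svd(sweep(uv, 2, colMeans(uv)), nu = 0)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    stop("degenerate patch: collinear base-plane projections", call. = FALSE)
  }

  K <- tps_kernel2(cross_dist2(uv, uv))
  P <- cbind(1, uv)
  A <- rbind(cbind(K + diag(lambda, n), P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(h, 0, 0, 0)
  coefs <- solve(A, rhs)
  structure(
    list(centers = uv, weights = coefs[seq_len(n)],
         affine = coefs[n + 1:3], lambda = lambda),
    class = "tps"
  )
}

tps_kernel <- function(r) {
  out <- r * r * log(r)
  out[r == 0] <- 0
  out
}

# same kernel on squared distances: r^2 log r = 0.5 r^2 log r^2
tps_kernel2 <- function(r2) {
  out <- 0.5 * r2 * log(r2)
  out[r2 == 0] <- 0
  out
}

#' Evaluate a fitted thin-plate spline
#'
#' @param object A `tps` object from [fit_tps()].
#' @param newdata Two-column matrix of base-plane coordinates.
#' @param chunk Evaluation block size (memory control for large meshes).
#' @param ... Unused.
#' @return Numeric vector of interpolated heights.
#' @export
predict.tps <- function(object, newdata, chunk = 16384L, ...) {
  uv <- as.matrix(newdata)
  storage.mode(uv) <- "double"
  n <- nrow(uv)
  out <- numeric(n)
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    blk <- uv[i0:i1, , drop = FALSE]
    K <- tps_kernel2(cross_dist2(blk, object$centers))
    out[i0:i1] <- object$affine[1] + blk %*% object$affine[2:3] +
      K %*% object$weights
  }
  out
}

#' Bending-energy matrix of a 3D landmark configuration
#'
#' Returns the k x k bending-energy matrix of the thin-plate spline anchored on
#' the reference configuration (3D biharmonic kernel U(r) = -r), i.e. the upper
#' left block of the inverse of the bordered kernel matrix. The bending energy
#' of a target configuration Y relative to the reference is
#' `sum over coordinate axes a of  t(Y[,a]) %*% Be %*% Y[,a]` — one thin-plate
#' spline per axis (the "triplet").
#'
#' @param ref k x 3 reference landmark matrix.
#' @param ridge Small ridge added to the kernel diagonal if the bordered system
#'   is numerically singular.
#' @return k x k symmetric positive semidefinite matrix.
#' @export
bending_energy_matrix <- function(ref, ridge = 0) {
  ref <- as_point_matrix(ref)
  k <- nrow(ref)
  K <- -sqrt(cross_dist2(ref, ref))
  if (ridge > 0) K <- K + diag(ridge, k)
  Q <- cbind(1, ref)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 4, 4)))
  Linv <- tryCatch(solve(L), error = function(e) {
    warning("singular bending-energy system; ridge-stabilized solve",
            call. = FALSE)
    solve(L + diag(1e-8, nrow(L)))
  })
  Be <- Linv[seq_len(k), seq_len(k), drop = FALSE]
  (Be + t(Be)) / 2
}

#' Bending energy of a configuration against a reference
#'
#' @param Be Bending-energy matrix from [bending_energy_matrix()].
#' @param Y k x 3 target configuration.
#' @return Scalar bending energy (summed over the x, y, z splines).
#' @export
bending_energy <- function(Be, Y) {
  Y <- as_point_matrix(Y)
  sum(vapply(seq_len(ncol(Y)), function(a) {
    drop(crossprod(Y[, a], Be %*% Y[, a]))
  }, numeric(1)))
}
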