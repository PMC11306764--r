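# Internal geometry helpers. All coordinates are millimetres; point sets are
# n x 3 (or n x 2) numeric matrices with one point per row.

`%||%` <- function(x, y) if (is.null(x)) y else x

as_point_matrix <- function(x, cols = c("x", "y", "z")) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  as.matrix(x[, cols, drop = FALSE])
}

#' Segment lengths of a polyline
#' @noRd
segment_lengths <- function(mat) {
  if (nrow(mat) < 2) return(numeric(0))
  d <- diff(mat)
  sqrt(rowSums(d^2))
}

polyline_length <- function(mat) sum(segment_lengths(mat))

#' Resample a polyline to n points at equal arc-length spacing
#'
#' First and last output points coincide with the curve endpoints and every
#' output point lies on a segment of the input polyline (linear interpolation
#' in arc length).
#' @noRd
resample_polyline <- function(mat, n) {
  if (n < 2) stop("resampling requires n >= 2", call. = FALSE)
  seg <- segment_lengths(mat)
  total <- sum(seg)
  if (!is.finite(total) || total <= 0) {
    stop("degenerate border: zero arc length", call. = FALSE)
  }
  s <- c(0, cumsum(seg))
  at_arclength <- function(targets) {
    idx <- findInterval(targets, s, rightmost.closed = TRUE)
    idx[idx >= nrow(mat)] <- nrow(mat) - 1L
    frac <- (targets - s[idx]) / seg[idx]
    frac[!is.finite(frac)] <- 0
    out <- mat[idx, , drop = FALSE] * (1 - frac) +
      mat[idx + 1L, , drop = FALSE] * frac
    out[1, ] <- mat[1, ]
    out[n, ] <- mat[nrow(mat), ]
    out
  }
  # fixed-point chord equalization: iterate until the output's own segment
  # lengths are equal, which makes resampling idempotent at fixed n
  targets <- seq(0, total, length.out = n)
  out <- at_arclength(targets)
  for (it in 1:80) {
    cl <- c(0, cumsum(segment_lengths(out)))
    dev <- max(abs(diff(cl) - cl[n] / (n - 1)))
    if (dev <= 1e-12 * max(cl[n], 1)) break
    targets <- stats::approx(cl / cl[n], targets, xout = seq(0, 1,
                                                             length.out = n),
                             rule = 2)$y
    out <- at_arclength(targets)
  }
  out
}

#' Squared cross-distance matrix between two point sets
#' @noRd
cross_dist2 <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' For each row of A, the distance to the nearest row of B
#' @noRd
nearest_distances <- function(A, B, chunk = 2048L) {
  n <- nrow(A)
  out <- numeric(n)
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    d2 <- cross_dist2(A[i0:i1, , drop = FALSE], B)
    cur <- d2[, 1]
    if (ncol(d2) > 1) for (j in 2:ncol(d2)) cur <- pmin(cur, d2[, j])
    out[i0:i1] <- sqrt(cur)
  }
  out
}

#' Apply a rigid transform y = R x + t to an n x 3 matrix
#' @noRd
apply_rigid <- function(mat, rotation, translation) {
  sweep(mat %*% t(rotation), 2, -as.numeric(translation))
}

#' Random proper rotation matrix (uniform via QR of Gaussian matrix)
#' @noRd
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  R <- R %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Centroid size: sqrt of summed squared deviations from the centroid
#' @noRd
centroid_size <- function(mat) {
  ctr <- colMeans(mat)
  sqrt(sum(sweep(mat, 2, ctr)^2))
}

#' Arc length of a (possibly closed) contour given as an ordered point matrix
#' @noRd
contour_length <- function(mat, closed = TRUE) {
  len <- polyline_length(mat)
  if (closed && sqrt(sum((mat[1, ] - mat[nrow(mat), ])^2)) > 1e-9) {
    len <- len + sqrt(sum((mat[1, ] - mat[nrow(mat), ])^2))
  }
  len
}

#' Fit a plane to points, return max absolute out-of-plane deviation
#' @noRd
planarity_deviation <- function(mat) {
  ctr <- colMeans(mat)
  X <- sweep(mat, 2, ctr)
  sv <- svd(X, nu = 0, nv = 3)
  normal <- sv$v[, 3]
  max(abs(X %*% normal))
}

format_full <- function(x) sprintf("%.17g", x)
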