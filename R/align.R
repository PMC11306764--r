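# Rigid three-point alignment, form-space generalized Procrustes analysis,
# and bending-energy sliding of curve semilandmarks.

sl_topology <- function(sl) paste(sl$border, sl$ordinal, sep = "-")

#' Convert a multi-subject semilandmark table to a k x 3 x N array
#' @noRd
sl_to_array <- function(sl) {
  sl <- dplyr::arrange(sl, .data$subject_id, .data$border, .data$ordinal)
  ids <- unique(sl$subject_id)
  topos <- split(sl_topology(sl), sl$subject_id)[ids]
  if (length(unique(vapply(topos, paste, character(1), collapse = ";"))) > 1) {
    stop("subjects have mismatched semilandmark topology", call. = FALSE)
  }
  k <- length(topos[[1]])
  arr <- array(NA_real_, c(k, 3, length(ids)),
               dimnames = list(NULL, c("x", "y", "z"), ids))
  for (i in seq_along(ids)) {
    arr[, , i] <- as.matrix(sl[sl$subject_id == ids[i], c("x", "y", "z")])
  }
  attr(arr, "topology") <- sl[sl$subject_id == ids[1], c("border", "ordinal")]
  arr
}

array_to_sl <- function(arr) {
  topo <- attr(arr, "topology")
  ids <- dimnames(arr)[[3]]
  purrr::map_dfr(seq_along(ids), function(i) {
    tibble::tibble(subject_id = ids[i], border = topo$border,
                   ordinal = topo$ordinal, x = arr[, 1, i], y = arr[, 2, i],
                   z = arr[, 3, i])
  })
}

#' Least-squares rigid transform between corresponding point sets
#'
#' Kabsch/Horn solution: the proper rotation (det = +1, no scaling) and
#' translation minimizing the sum of squared distances between corresponding
#' points. If the unconstrained optimum is a reflection, the proper-rotation
#' fallback (smallest singular direction flipped) is returned with a warning.
#'
#' @param moving,fixed n x 3 matrices of corresponding points (n >= 3,
#'   non-collinear).
#' @return List with `rotation` (3 x 3), `translation` (length 3) and `rmsd`
#'   (root-mean-square residual, mm). Apply as `x %*% t(rotation) +
#'   translation`, or with [transform_points()].
#' @export
rigid_fit <- function(moving, fixed) {
  X <- as_point_matrix(moving)
  Y <- as_point_matrix(fixed)
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 3)
  cm <- colMeans(X); cf <- colMeans(Y)
  Xc <- sweep(X, 2, cm); Yc <- sweep(Y, 2, cf)
  sv <- svd(Xc, nu = 0)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    stop("collinear point triplet: rigid alignment is ill-posed",
         call. = FALSE)
  }
  H <- crossprod(Xc, Yc)
  dec <- svd(H)
  d <- sign(det(dec$v %*% t(dec$u)))
  # warn only for a genuine reflection optimum: with coplanar points the
  # third singular value is 0 and the sign flip is a harmless null direction
  if (d < 0 && dec$d[3] > 1e-9 * max(dec$d[1], 1)) {
    warning("reflection-optimal correspondence; proper-rotation fallback",
            call. = FALSE)
  }
  R <- dec$v %*% diag(c(1, 1, d)) %*% t(dec$u)
  t_ <- cf - as.numeric(R %*% cm)
  fitted <- sweep(Xc %*% t(R), 2, -cf)
  list(rotation = R, translation = t_,
       rmsd = sqrt(mean(rowSums((fitted - Y)^2))))
}

#' Apply a rigid transform to a point table
#'
#' @param data Tibble with `x`, `y`, `z` columns (other columns preserved).
#' @param transform List with `rotation` and `translation` (see [rigid_fit()]).
#' @return The table with transformed coordinates.
#' @export
transform_points <- function(data, transform) {
  m <- as.matrix(data[, c("x", "y", "z")]) %*% t(transform$rotation)
  m <- sweep(m, 2, -transform$translation)
  data$x <- m[, 1]; data$y <- m[, 2]; data$z <- m[, 3]
  data
}

#' Three-point rigid alignment of a subject to a reference
#'
#' Computes the least-squares rigid transform mapping the subject's alignment
#' triplet (rhinion, fmoR, fmoL) onto the reference's, and applies it to the
#' subject's border curves, landmarks and axial contour.
#'
#' @param subject List with `curves` (border-curve tibble) and `landmarks`.
#' @param reference Landmarks of the reference subject (same structure).
#' @return The subject with transformed geometry, plus `transform` (with
#'   `rmsd`, the triplet residual in mm).
#' @export
align_three_point <- function(subject, reference) {
  triplet <- function(lm) {
    pts <- lm$points
    as.matrix(pts[match(c("rhinion", "fmoR", "fmoL"), pts$landmark),
                  c("x", "y", "z")])
  }
  validate_landmarks(subject$landmarks)
  validate_landmarks(reference)
  tf <- rigid_fit(triplet(subject$landmarks), triplet(reference))
  out <- subject
  out$curves <- transform_points(subject$curves, tf)
  out$landmarks$points <- transform_points(subject$landmarks$points, tf)
  if (!is.null(subject$landmarks$axial_contour)) {
    out$landmarks$axial_contour <-
      transform_points(subject$landmarks$axial_contour, tf)
  }
  out$transform <- tf
  out
}

#' Serialize a rigid transform as a 4 x 4 homogeneous matrix (JSON)
#'
#' @param transform List with `rotation`, `translation`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(transform, path) {
  m <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
  jsonlite::write_json(list(matrix = m), path, digits = NA)
  invisible(path)
}

#' Generalized Procrustes analysis in form space
#'
#' Iterative superimposition without scaling: every configuration is
#' translated to a common centroid and rotated to the evolving consensus;
#' centroid sizes are preserved exactly, so the analysis lives in form space
#' (size retained). Iteration stops when the consensus moves less than `tol`
#' (root-mean-square) or after `max_iter` rounds.
#'
#' @param sl Multi-subject semilandmark tibble with identical topology.
#' @param tol Consensus-change convergence tolerance; default 1e-10.
#' @param max_iter Maximum iterations; default 100.
#' @return List of class `gpa_alignment`: `aligned` (tibble), `consensus`
#'   (tibble `border`, `ordinal`, `x,y,z`), `iterations`, `converged`, and
#'   `rss` (per-iteration sum of squared distances to the consensus).
#' @export
gpa_align <- function(sl, tol = 1e-10, max_iter = 100L) {
  arr <- sl_to_array(sl)
  N <- dim(arr)[3]
  if (N < 2) stop("GPA requires at least 2 shapes", call. = FALSE)
  for (i in seq_len(N)) {
    arr[, , i] <- sweep(arr[, , i], 2, colMeans(arr[, , i]))
  }
  consensus <- apply(arr, c(1, 2), mean)
  rss <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(N)) {
      H <- crossprod(arr[, , i], consensus)
      dec <- svd(H)
      d <- sign(det(dec$v %*% t(dec$u)))
      R <- dec$v %*% diag(c(1, 1, d)) %*% t(dec$u)
      arr[, , i] <- arr[, , i] %*% t(R)
    }
    new_consensus <- apply(arr, c(1, 2), mean)
    rss <- c(rss, sum(vapply(seq_len(N), function(i) {
      sum((arr[, , i] - new_consensus)^2)
    }, numeric(1))))
    delta <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  topo <- attr(arr, "topology")
  structure(
    list(aligned = array_to_sl(arr),
         consensus = tibble::tibble(border = topo$border,
                                    ordinal = topo$ordinal,
                                    x = consensus[, 1], y = consensus[, 2],
                                    z = consensus[, 3]),
         iterations = iter, converged = converged, rss = rss),
    class = "gpa_alignment"
  )
}

# project each row of P onto the polyline `poly`, searching only segments in a
# window around the point's own ordinal (vectorized over points)
project_to_polyline <- function(P, poly, window = 5L) {
  k <- nrow(P)
  np <- nrow(poly)
  best <- P
  bestd <- rep(Inf, k)
  i <- seq_len(k)
  for (delta in (-window):(window - 1L)) {
    seg <- pmin(pmax(i + delta, 1L), np - 1L)
    a <- poly[seg, , drop = FALSE]
    ab <- poly[seg + 1L, , drop = FALSE] - a
    len2 <- rowSums(ab^2)
    tt <- pmin(1, pmax(0, rowSums((P - a) * ab) / pmax(len2, 1e-300)))
    proj <- a + ab * tt
    d2 <- rowSums((proj - P)^2)
    upd <- d2 < bestd
    best[upd, ] <- proj[upd, , drop = FALSE]
    bestd[upd] <- d2[upd]
  }
  best
}

#' Slide semilandmarks by bending-energy minimization
#'
#' Tangential relaxation of curve semilandmarks against the Procrustes
#' consensus: per iteration the bending-energy matrix of the consensus is
#' computed (one thin-plate spline per coordinate axis, the "triplet"); each
#' non-anchor semilandmark of each shape moves along its local curve tangent
#' (central difference of its border neighbours) by the closed-form
#' energy-minimizing step, is re-projected onto its source border polyline,
#' and the step is halved if re-projection would raise the energy; GPA is
#' re-run between iterations. Anchors (junction points and border endpoints)
#' never move.
#'
#' @param gpa A `gpa_alignment` from [gpa_align()].
#' @param anchors Tibble with `border`, `ordinal` of points that must not
#'   slide (e.g. the junctions of a [partition_sutures()] result); border
#'   endpoints are always anchored.
#' @param iterations Number of slide/GPA rounds; default 3.
#' @param ridge Ridge added to the tangent normal matrix if singular.
#' @return List of class `slid_semilandmarks`: `aligned` (tibble),
#'   `consensus`, and `energy` (tibble `subject_id`, `iteration`, `before`,
#'   `after` bending energies).
#' @export
slide_semilandmarks <- function(gpa, anchors = NULL, iterations = 3L,
                                ridge = 1e-10) {
  arr <- sl_to_array(gpa$aligned)
  topo <- attr(arr, "topology")
  k <- dim(arr)[1]; N <- dim(arr)[3]
  ids <- dimnames(arr)[[3]]

  is_anchor <- rep(FALSE, k)
  for (b in unique(topo$border)) {
    rows <- which(topo$border == b)
    is_anchor[rows[1]] <- TRUE
    is_anchor[rows[length(rows)]] <- TRUE
  }
  if (!is.null(anchors)) {
    if (inherits(anchors, "suture_partition")) anchors <- anchors$junctions
    for (r in seq_len(nrow(anchors))) {
      is_anchor[topo$border == anchors$border[r] &
                  topo$ordinal == anchors$ordinal[r]] <- TRUE
    }
  }
  sliders <- which(!is_anchor)
  source_poly <- lapply(seq_len(N), function(i) arr[, , i])

  tangents <- function(Y) {
    T_ <- matrix(0, k, 3)
    for (b in unique(topo$border)) {
      rows <- which(topo$border == b)
      nb <- length(rows)
      if (nb < 3) next
      mid <- rows[2:(nb - 1)]
      T_[mid, ] <- Y[rows[3:nb], ] - Y[rows[1:(nb - 2)], ]
    }
    nrm <- sqrt(rowSums(T_^2))
    T_[nrm > 0, ] <- T_[nrm > 0, ] / nrm[nrm > 0]
    T_[is_anchor, ] <- 0
    T_
  }

  energy_log <- NULL
  ridge_warned <- FALSE
  consensus <- as.matrix(gpa$consensus[, c("x", "y", "z")])
  for (it in seq_len(iterations)) {
    if (it > 1L) {
      # GPA re-run between iterations (never after the last, so anchors of a
      # single-iteration slide are exactly unmoved in the input frame)
      re <- gpa_align(array_to_sl(arr))
      arr2 <- sl_to_array(re$aligned)
      for (i in seq_len(N)) {
        tf <- rigid_fit(arr[, , i], arr2[, , i])
        source_poly[[i]] <- sweep(source_poly[[i]] %*% t(tf$rotation), 2,
                                  -tf$translation)
      }
      arr <- arr2
      consensus <- as.matrix(re$consensus[, c("x", "y", "z")])
    }
    Be <- bending_energy_matrix(consensus)
    for (i in seq_len(N)) {
      Y <- arr[, , i]
      e0 <- bending_energy(Be, Y)
      T_ <- tangents(Y)
      M <- (Be * tcrossprod(T_))[sliders, sliders, drop = FALSE]
      g <- rowSums(T_ * (Be %*% Y))[sliders]
      diag(M) <- diag(M) + max(ridge, 1e-12 * mean(abs(diag(M))))
      alpha <- tryCatch(solve(M, -g), error = function(e) {
        if (!ridge_warned) {
          warning("singular sliding system; ridge-stabilized solve",
                  call. = FALSE)
          ridge_warned <<- TRUE
        }
        solve(M + diag(1e-6 * mean(abs(diag(M))), length(sliders)), -g)
      })
      scale_f <- 1
      Ybest <- Y
      for (try in 1:12) {
        step <- numeric(k)
        step[sliders] <- alpha * scale_f
        Yp <- Y + T_ * step
        for (b in unique(topo$border)) {
          rows <- which(topo$border == b)
          Yp[rows, ] <- project_to_polyline(Yp[rows, , drop = FALSE],
                                            source_poly[[i]][rows, ,
                                                             drop = FALSE])
        }
        Yp[is_anchor, ] <- Y[is_anchor, ]
        if (bending_energy(Be, Yp) <= e0 + 1e-12 * max(1, abs(e0))) {
          Ybest <- Yp
          break
        }
        scale_f <- scale_f / 2
      }
      arr[, , i] <- Ybest
      energy_log <- rbind(energy_log,
                          data.frame(subject_id = ids[i], iteration = it,
                                     before = e0,
                                     after = bending_energy(Be, Ybest)))
    }
    consensus <- apply(arr, c(1, 2), mean)
  }
  structure(
    list(aligned = array_to_sl(arr),
         consensus = tibble::tibble(border = topo$border,
                                    ordinal = topo$ordinal,
                                    x = consensus[, 1], y = consensus[, 2],
                                    z = consensus[, 3]),
         energy = tibble::as_tibble(energy_log)),
    class = "slid_semilandmarks"
  )
}
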