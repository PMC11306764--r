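# Thin-plate-spline surface reconstruction of sutures/fontanelles and total
# surface area via triangulation and Heron's formula.
#
# Five patches are reconstructed per subject, each as a TPS height field over
# its base plane: superior (X-Y), left and right lateral (Y-Z), anterior and
# posterior (Z-X). Footprints are meshed with boundary-conforming structured
# meshes: ruled strips between the two edges of a suture, and ear clipping
# plus longest-edge bisection for the fontanelle polygons.

base_planes <- c("XY", "YZ", "ZX")

plane_project <- function(m, plane) {
  switch(plane,
    XY = list(uv = m[, 1:2, drop = FALSE], h = m[, 3]),
    YZ = list(uv = m[, 2:3, drop = FALSE], h = m[, 1]),
    ZX = list(uv = m[, c(3, 1), drop = FALSE], h = m[, 2]),
    stop("unknown base plane: ", plane, call. = FALSE))
}

plane_lift <- function(uv, h, plane) {
  switch(plane,
    XY = cbind(uv[, 1], uv[, 2], h),
    YZ = cbind(h, uv[, 1], uv[, 2]),
    ZX = cbind(uv[, 2], h, uv[, 1]))
}

#' Fit a TPS height-field patch to 3D points
#'
#' Projects the points onto the chosen base plane and fits an interpolating
#' thin-plate spline to the out-of-plane coordinate (see [fit_tps()]).
#'
#' @param points n x 3 matrix (or data frame with `x,y,z`) of patch points.
#' @param base_plane `"XY"`, `"YZ"` or `"ZX"` (height = z, x, y respectively).
#' @param lambda Regularization passed to [fit_tps()] (0 = interpolant).
#' @return A `tps_patch`: the `tps` object plus the base plane.
#' @export
fit_tps_patch <- function(points, base_plane = c("XY", "YZ", "ZX"),
                          lambda = 0) {
  base_plane <- match.arg(base_plane)
  m <- as_point_matrix(points)
  pr <- plane_project(m, base_plane)
  structure(list(tps = fit_tps(pr$uv, pr$h, lambda = lambda),
                 base_plane = base_plane),
            class = "tps_patch")
}

#' @export
predict.tps_patch <- function(object, newdata, ...) {
  predict(object$tps, newdata, ...)
}

new_triangulated_surface <- function(vertices, triangles) {
  structure(list(vertices = vertices, triangles = triangles),
            class = "triangulated_surface")
}

#' @export
print.triangulated_surface <- function(x, ...) {
  cat("<triangulated_surface>:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles, mean edge",
      sprintf("%.3f", mean_edge_length(x)), "mm\n")
  invisible(x)
}

#' Mean 3D edge length of a triangulated surface
#' @param surface A `triangulated_surface`.
#' @return Mean edge length (mm).
#' @export
mean_edge_length <- function(surface) {
  v <- surface$vertices
  tr <- surface$triangles
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2])
  hi <- pmax(e[, 1], e[, 2])
  keep <- !duplicated(lo * (nrow(v) + 1) + hi)
  mean(sqrt(rowSums((v[lo[keep], , drop = FALSE] -
                     v[hi[keep], , drop = FALSE])^2)))
}

grid_triangles <- function(ni, nj) {
  # triangles of an ni x nj structured grid, vertices indexed row-major by i
  i <- rep(seq_len(ni - 1L), nj - 1L)
  j <- rep(seq_len(nj - 1L), each = ni - 1L)
  v00 <- (j - 1L) * ni + i
  v10 <- v00 + 1L
  v01 <- v00 + ni
  v11 <- v01 + 1L
  rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
}

mesh_strip_uv <- function(chain_a, chain_b, target_edge) {
  la <- polyline_length(chain_a)
  lb <- polyline_length(chain_b)
  ni <- max(2L, as.integer(ceiling(max(la, lb) / target_edge)) + 1L)
  A <- resample_polyline(chain_a, ni)
  B <- resample_polyline(chain_b, ni)
  width <- mean(sqrt(rowSums((A - B)^2)))
  nj <- max(2L, as.integer(ceiling(width / target_edge)) + 1L)
  t <- seq(0, 1, length.out = nj)
  verts <- do.call(rbind, lapply(t, function(tt) (1 - tt) * A + tt * B))
  list(vertices = verts, triangles = grid_triangles(ni, nj))
}

# ear-clipping triangulation of a simple polygon (vertex indices)
ear_clip <- function(poly) {
  n <- nrow(poly)
  idx <- seq_len(n)
  # signed area fixes the orientation convention
  sa <- sum(poly[, 1] * poly[c(2:n, 1), 2] - poly[c(2:n, 1), 1] * poly[, 2])
  ccw <- sa > 0
  tris <- matrix(0L, 0, 3)
  guard_ <- 0L
  while (length(idx) > 3 && guard_ < 10L * n) {
    guard_ <- guard_ + 1L
    m <- length(idx)
    prv <- c(m, seq_len(m - 1L))
    nxt <- c(2:m, 1L)
    A <- poly[idx[prv], , drop = FALSE]
    B <- poly[idx, , drop = FALSE]
    C <- poly[idx[nxt], , drop = FALSE]
    crossz <- (B[, 1] - A[, 1]) * (C[, 2] - B[, 2]) -
      (B[, 2] - A[, 2]) * (C[, 1] - B[, 1])
    if (!ccw) crossz <- -crossz
    # rank convex corners by ear quality (area over squared longest side)
    per2 <- pmax(rowSums((A - B)^2), rowSums((B - C)^2), rowSums((A - C)^2))
    quality <- ifelse(crossz > 1e-12, crossz / pmax(per2, 1e-300), -Inf)
    clipped <- FALSE
    for (j in order(quality, decreasing = TRUE)) {
      if (quality[j] <= 0) break
      a <- idx[prv[j]]; b <- idx[j]; c_ <- idx[nxt[j]]
      others <- setdiff(idx, c(a, b, c_))
      if (length(others)) {
        # barycentric point-in-triangle test for the remaining vertices
        P <- poly[others, , drop = FALSE]
        d <- (poly[b, 2] - poly[c_, 2]) * (poly[a, 1] - poly[c_, 1]) +
          (poly[c_, 1] - poly[b, 1]) * (poly[a, 2] - poly[c_, 2])
        l1 <- ((poly[b, 2] - poly[c_, 2]) * (P[, 1] - poly[c_, 1]) +
                 (poly[c_, 1] - poly[b, 1]) * (P[, 2] - poly[c_, 2])) / d
        l2 <- ((poly[c_, 2] - poly[a, 2]) * (P[, 1] - poly[c_, 1]) +
                 (poly[a, 1] - poly[c_, 1]) * (P[, 2] - poly[c_, 2])) / d
        l3 <- 1 - l1 - l2
        if (any(l1 > -1e-12 & l2 > -1e-12 & l3 > -1e-12)) next
      }
      tris <- rbind(tris, c(a, b, c_))
      idx <- idx[idx != b]
      clipped <- TRUE
      break
    }
    if (!clipped) {
      stop("footprint polygon could not be triangulated (self-intersecting?)",
           call. = FALSE)
    }
  }
  rbind(tris, idx)
}

# longest-edge bisection of a triangle list until every edge <= max_edge
refine_triangles <- function(verts, tris, max_edge) {
  # vectorized sweeps: every triangle whose longest edge exceeds the target is
  # bisected at that edge's midpoint (hanging nodes are tolerated: they lie on
  # the neighbour's edge, so the tiling of the footprint is preserved)
  V <- verts
  Tm <- tris
  out <- NULL
  me2 <- max_edge^2
  for (pass in 1:60) {
    P1 <- V[Tm[, 1], , drop = FALSE]
    P2 <- V[Tm[, 2], , drop = FALSE]
    P3 <- V[Tm[, 3], , drop = FALSE]
    E <- cbind(rowSums((P1 - P2)^2), rowSums((P2 - P3)^2),
               rowSums((P3 - P1)^2))
    le <- max.col(E, ties.method = "first")
    emax <- E[cbind(seq_len(nrow(E)), le)]
    done <- emax <= me2
    out <- rbind(out, Tm[done, , drop = FALSE])
    if (all(done)) break
    Tm <- Tm[!done, , drop = FALSE]
    le <- le[!done]
    a <- Tm[cbind(seq_len(nrow(Tm)), le)]
    b <- Tm[cbind(seq_len(nrow(Tm)), le %% 3L + 1L)]
    opp <- Tm[cbind(seq_len(nrow(Tm)), (le + 1L) %% 3L + 1L)]
    mid_idx <- nrow(V) + seq_len(nrow(Tm))
    V <- rbind(V, (V[a, , drop = FALSE] + V[b, , drop = FALSE]) / 2)
    Tm <- rbind(cbind(a, mid_idx, opp), cbind(mid_idx, b, opp))
  }
  if (nrow(Tm) && !all(done)) out <- rbind(out, Tm)
  list(vertices = V, triangles = out)
}

mesh_polygon_uv <- function(boundary, target_edge) {
  # boundary-conforming mesh of a simple polygon: resample the boundary at
  # the target spacing, ear-clip, then refine the ears by longest-edge
  # bisection until every edge is at the target length
  if (sqrt(sum((boundary[1, ] - boundary[nrow(boundary), ])^2)) > 1e-9) {
    boundary <- rbind(boundary, boundary[1, ])
  }
  per <- polyline_length(boundary)
  ns <- max(8L, min(400L, as.integer(ceiling(per / target_edge))))
  B <- resample_polyline(boundary, ns + 1L)[-(ns + 1L), , drop = FALSE]
  base <- ear_clip(B)
  refine_triangles(B, base, 1.8 * target_edge)
}

#' Triangulate a patch footprint and lift it through a TPS
#'
#' Builds a boundary-conforming structured mesh of the footprint in the base
#' plane at a point spacing of about `target_edge`, then lifts each mesh
#' vertex through the TPS height field. Footprints are either ruled strips
#' (a list with `chain_a` and `chain_b`, the two edges, as uv or 3D point
#' matrices) or star-shaped polygons (a list with `boundary`).
#'
#' The planar sampling density is corrected by the region's 3D-to-planar
#' stretch (estimated from its defining curves) so the mean 3D edge length
#' tracks `target_edge`.
#'
#' @param patch A `tps_patch` from [fit_tps_patch()] (or a bare `tps` plus
#'   `plane`).
#' @param region List with either `chain_a`/`chain_b` or `boundary` (2-column
#'   uv matrices; 3-column matrices are projected onto the base plane).
#' @param target_edge Target mean edge length (mm); default 0.3.
#' @return A `triangulated_surface` with 3D `vertices` and `triangles`.
#' @export
triangulate_patch <- function(patch, region, target_edge = 0.3) {
  stopifnot(inherits(patch, "tps_patch"), target_edge > 0)
  proj <- function(m) {
    m <- as_point_matrix(m, cols = colnames(m) %||% c("x", "y", "z"))
    if (ncol(m) == 3) plane_project(m, patch$base_plane)$uv else m
  }
  build <- function(edge) {
    if (!is.null(region$boundary)) {
      mesh_polygon_uv(proj(region$boundary), edge)
    } else if (!is.null(region$chain_a)) {
      mesh_strip_uv(proj(region$chain_a), proj(region$chain_b), edge)
    } else {
      stop("region must provide boundary or chain_a/chain_b", call. = FALSE)
    }
  }
  lift <- function(mesh) {
    h <- predict(patch$tps, mesh$vertices)
    new_triangulated_surface(
      plane_lift(mesh$vertices, h, patch$base_plane), mesh$triangles)
  }
  # estimate the 3D/planar stretch from the region curves (when given in 3D)
  stretch <- 1
  ref <- region$boundary %||% region$chain_a
  if (!is.null(ref) && ncol(as_point_matrix(ref,
                                            colnames(ref) %||%
                                              c("x", "y", "z"))) == 3) {
    m3 <- as_point_matrix(ref, colnames(ref) %||% c("x", "y", "z"))
    stretch <- polyline_length(m3) / max(polyline_length(proj(m3)), 1e-12)
  }
  lift(build(target_edge / min(2, max(1, stretch))))
}

#' Total surface area of a triangulation by Heron's formula
#'
#' Sums `sqrt(s (s-a) (s-b) (s-c))` with `s = (a+b+c)/2` over all triangles.
#' Triangles that are degenerate beyond round-off are excluded with a warning
#' and counted in the `degenerate` attribute.
#'
#' @param surface A `triangulated_surface`.
#' @return Total area (mm^2) with attribute `degenerate`.
#' @export
surface_area_heron <- function(surface) {
  v <- surface$vertices
  tr <- surface$triangles
  a <- sqrt(rowSums((v[tr[, 1], , drop = FALSE] -
                     v[tr[, 2], , drop = FALSE])^2))
  b <- sqrt(rowSums((v[tr[, 2], , drop = FALSE] -
                     v[tr[, 3], , drop = FALSE])^2))
  c_ <- sqrt(rowSums((v[tr[, 3], , drop = FALSE] -
                      v[tr[, 1], , drop = FALSE])^2))
  s <- (a + b + c_) / 2
  val <- s * (s - a) * (s - b) * (s - c_)
  # degenerate when the longest side consumes the semiperimeter (collinear or
  # impossible side lengths beyond round-off)
  degen <- (s - pmax(a, b, c_)) <= 1e-12 * pmax(s, 1e-300)
  if (any(degen)) {
    warning(sum(degen), " degenerate triangle(s) excluded from Heron sum",
            call. = FALSE)
  }
  val[val < 0] <- 0
  structure(sum(sqrt(val[!degen])), degenerate = sum(degen))
}

# ---- patch plan: which semilandmarks feed which of the 5 patches ------------

#' Default patch plan
#'
#' Maps each of the nine parts onto the five reconstruction patches. Split
#' fractions divide a suture strip along its course: the metopic suture's
#' leading (nasion-side) fraction joins the anterior patch; the coronal
#' suture's medial half stays superior and its lateral half joins the lateral
#' patches; the lambdoid's medial half joins the posterior patch.
#'
#' @param metopic_anterior Leading fraction of the metopic strip assigned to
#'   the anterior patch.
#' @param coronal_medial Medial fraction of the coronal strip kept superior.
#' @param lambdoid_medial Medial fraction of the lambdoid strip assigned to
#'   the posterior patch.
#' @return Named list of split fractions.
#' @export
patch_plan <- function(metopic_anterior = 0.35, coronal_medial = 0.5,
                       lambdoid_medial = 0.5) {
  stopifnot(metopic_anterior > 0, metopic_anterior < 1,
            coronal_medial > 0, coronal_medial < 1,
            lambdoid_medial > 0, lambdoid_medial < 1)
  list(metopic_anterior = metopic_anterior, coronal_medial = coronal_medial,
       lambdoid_medial = lambdoid_medial)
}

# ordered boundary loop of a fontanelle footprint (3D points)
fontanelle_loop <- function(sl, partition, part, side) {
  p <- partition$parts
  seg <- function(border, edge, reverse = FALSE, side_sel = NULL) {
    r <- p[p$part == part & p$border == border & p$edge == edge &
             (if (is.null(side_sel)) TRUE else p$side == side_sel), ]
    part_segment(sl, r$border[1], r$start[1], r$end[1], reverse = reverse)
  }
  if (part == "anterior_fontanelle") {
    rbind(seg(1, 1), seg(3, 2), seg(4, 2, reverse = TRUE),
          seg(2, 1, reverse = TRUE))
  } else if (part == "posterior_fontanelle") {
    rbind(seg(3, 1), seg(7, 2), seg(4, 1, reverse = TRUE))
  } else if (part == "sphenoidal_fontanelle") {
    b_front <- if (side == "L") 1L else 2L
    b_par <- if (side == "L") 3L else 4L
    b_temp <- if (side == "L") 5L else 6L
    rbind(seg(b_front, 1, side_sel = side), seg(b_temp, 3, side_sel = side),
          seg(b_par, 2, side_sel = side))
  } else if (part == "mastoid_fontanelle") {
    b_par <- if (side == "L") 3L else 4L
    b_temp <- if (side == "L") 5L else 6L
    rbind(seg(b_par, 1, side_sel = side), seg(b_temp, 2, side_sel = side),
          seg(7, 3, reverse = (side == "R"), side_sel = side))
  } else {
    stop("not a fontanelle part: ", part, call. = FALSE)
  }
}

# opposing edge chains of one suture side, direction-aligned
suture_chains <- function(sl, partition, part, side) {
  p <- partition$parts
  sel <- if (part %in% paired_parts) {
    # midline sutures: one range per edge, the two mirror halves ARE the edges
    p$part == part
  } else {
    p$part == part & (p$side == side | p$side == "M")
  }
  r1 <- p[sel & p$edge == 1, ]
  r2 <- p[sel & p$edge == 2, ]
  A <- part_segment(sl, r1$border[1], r1$start[1], r1$end[1])
  B <- part_segment(sl, r2$border[1], r2$start[1], r2$end[1])
  same <- sum((A[1, ] - B[1, ])^2) + sum((A[nrow(A), ] - B[nrow(B), ])^2)
  flip <- sum((A[1, ] - B[nrow(B), ])^2) + sum((A[nrow(A), ] - B[1, ])^2)
  if (flip < same) B <- B[rev(seq_len(nrow(B))), , drop = FALSE]
  list(chain_a = A, chain_b = B)
}

split_chains <- function(chains, fraction) {
  # split a strip at a fraction of its course; both pieces share the cut line
  n <- max(nrow(chains$chain_a), nrow(chains$chain_b), 3L)
  A <- resample_polyline(chains$chain_a, n)
  B <- resample_polyline(chains$chain_b, n)
  cut <- min(n - 1L, max(2L, as.integer(round(fraction * n))))
  list(
    head = list(chain_a = A[1:cut, , drop = FALSE],
                chain_b = B[1:cut, , drop = FALSE]),
    tail = list(chain_a = A[cut:n, , drop = FALSE],
                chain_b = B[cut:n, , drop = FALSE])
  )
}

patch_pieces <- function(sl, partition, plan = patch_plan()) {
  pieces <- list()
  add <- function(patch, part, piece) {
    pieces[[length(pieces) + 1]] <<- c(list(patch = patch, part = part),
                                       piece)
  }
  met <- suture_chains(sl, partition, "metopic", "M")
  ms <- split_chains(met, plan$metopic_anterior)
  add("anterior", "metopic", ms$head)
  add("superior", "metopic", ms$tail)
  add("superior", "sagittal", suture_chains(sl, partition, "sagittal", "M"))
  add("superior", "anterior_fontanelle",
      list(boundary = fontanelle_loop(sl, partition, "anterior_fontanelle",
                                      "M")))
  add("posterior", "posterior_fontanelle",
      list(boundary = fontanelle_loop(sl, partition, "posterior_fontanelle",
                                      "M")))
  for (side in c("L", "R")) {
    lat <- paste0("lateral_", side)
    cs <- split_chains(suture_chains(sl, partition, "coronal", side),
                       plan$coronal_medial)
    add("superior", "coronal", cs$head)
    add(lat, "coronal", cs$tail)
    ls <- split_chains(suture_chains(sl, partition, "lambdoid", side),
                       plan$lambdoid_medial)
    add("posterior", "lambdoid", ls$head)
    add(lat, "lambdoid", ls$tail)
    add(lat, "squamosal", suture_chains(sl, partition, "squamosal", side))
    add(lat, "sphenoidal_fontanelle",
        list(boundary = fontanelle_loop(sl, partition,
                                        "sphenoidal_fontanelle", side)))
    add(lat, "mastoid_fontanelle",
        list(boundary = fontanelle_loop(sl, partition, "mastoid_fontanelle",
                                        side)))
  }
  pieces
}

patch_plane_of <- function(patch) {
  switch(patch, superior = "XY", lateral_L = "YZ", lateral_R = "YZ",
         anterior = "ZX", posterior = "ZX")
}

#' Total suture/fontanelle surface area of a subject
#'
#' Fits the five TPS patches (superior on X-Y, left/right lateral on Y-Z,
#' anterior/posterior on Z-X), meshes every suture strip and fontanelle
#' footprint at the target edge length, lifts the meshes through their patch's
#' TPS, and sums triangle areas with Heron's formula. Every semilandmark is
#' assigned to exactly one patch, so patch areas sum to the total.
#'
#' @inheritParams suture_length
#' @param target_edge Target mean triangle edge length (mm); default 0.3.
#' @param plan Patch split fractions from [patch_plan()].
#' @return List with `total` (mm^2), `patches` (tibble `patch`, `area`, always
#'   5 rows; a degenerate patch reports `NA` and `partial = TRUE`), `parts`
#'   (per-part areas) and `partial` flag.
#' @export
total_suture_area <- function(sl, partition, target_edge = 0.3,
                              plan = patch_plan()) {
  pieces <- patch_pieces(sl, partition, plan)
  res <- purrr::map_dfr(pieces, function(pc) {
    tibble::tibble(patch = pc$patch, part = pc$part,
                   area = NA_real_, failed = TRUE)
  })
  patch_names <- c("superior", "lateral_L", "lateral_R", "anterior",
                   "posterior")
  for (pt in patch_names) {
    idx <- which(vapply(pieces, function(p) p$patch == pt, logical(1)))
    fit <- tryCatch({
      pts <- do.call(rbind, lapply(pieces[idx], function(p) {
        if (!is.null(p$boundary)) p$boundary else rbind(p$chain_a, p$chain_b)
      }))
      fit_tps_patch(pts, patch_plane_of(pt))
    }, error = function(e) {
      warning("patch ", pt, " degenerate: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(fit)) next
    for (i in idx) {
      area_i <- tryCatch({
        surf <- triangulate_patch(fit, pieces[[i]], target_edge = target_edge)
        as.numeric(surface_area_heron(surf))
      }, error = function(e) {
        warning("piece ", pieces[[i]]$part, " in patch ", pt, " failed: ",
                conditionMessage(e), call. = FALSE)
        NA_real_
      })
      res$area[i] <- area_i
      res$failed[i] <- is.na(area_i)
    }
  }
  patches <- dplyr::summarise(
    dplyr::group_by(res, .data$patch),
    area = if (any(.data$failed)) NA_real_ else sum(.data$area),
    .groups = "drop")
  patches <- dplyr::left_join(tibble::tibble(patch = patch_names), patches,
                              by = "patch")
  parts <- dplyr::summarise(dplyr::group_by(res, .data$part),
                            area = sum(.data$area), .groups = "drop")
  partial <- any(res$failed)
  list(total = if (partial) sum(res$area, na.rm = TRUE) else sum(res$area),
       patches = patches, parts = parts, partial = partial)
}
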