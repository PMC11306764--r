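# Suture length, width, sinuosity index and cranial shape parameters.

suture_parts <- c("metopic", "sagittal", "coronal", "squamosal", "lambdoid")
paired_parts <- c("metopic", "sagittal")

get_part_ranges <- function(partition, part) {
  ranges <- partition$parts[partition$parts$part == part, ]
  if (!nrow(ranges)) stop("unknown part: ", part, call. = FALSE)
  ranges
}

edge_length <- function(sl, ranges) {
  sum(vapply(seq_len(nrow(ranges)), function(i) {
    polyline_length(part_segment(sl, ranges$border[i], ranges$start[i],
                                 ranges$end[i]))
  }, numeric(1)))
}

#' Suture length
#'
#' The length of a suture is the average of the arc lengths of its two bone
#' edges (for the bilateral sutures each edge sums its left and right
#' segments).
#'
#' @param sl Semilandmark tibble of one subject.
#' @param partition A `suture_partition` from [partition_sutures()].
#' @param part Part name (one of the five sutures, or a fontanelle).
#' @return Length in mm.
#' @export
suture_length <- function(sl, partition, part) {
  ranges <- get_part_ranges(partition, part)
  edges <- sort(unique(ranges$edge))
  if (length(edges) < 2) {
    stop("part ", part, " has a single edge; length is undefined",
         call. = FALSE)
  }
  mean(vapply(edges[1:2], function(e) {
    edge_length(sl, ranges[ranges$edge == e, ])
  }, numeric(1)))
}

#' Suture width
#'
#' In `"paired"` mode (midline sutures: metopic, sagittal) the width is the
#' mean distance between corresponding semilandmarks of the two edges; in
#' `"nearest"` mode (all other sutures) it is the mean, over the semilandmarks
#' of one edge, of the shortest distance to the opposite edge. `"auto"` picks
#' paired for the midline sutures and nearest otherwise. A width of 0 is valid
#' (fused suture).
#'
#' @inheritParams suture_length
#' @param mode `"auto"`, `"paired"` or `"nearest"`.
#' @return Width in mm.
#' @export
suture_width <- function(sl, partition, part,
                         mode = c("auto", "paired", "nearest")) {
  mode <- match.arg(mode)
  ranges <- get_part_ranges(partition, part)
  if (mode == "auto") {
    mode <- if (part %in% paired_parts) "paired" else "nearest"
  }
  if (mode == "paired" && !part %in% paired_parts) {
    warning("paired width is only defined for the midline sutures; ",
            "falling back to nearest mode for ", part, call. = FALSE)
    mode <- "nearest"
  }
  e1 <- ranges[ranges$edge == 1, ]
  e2 <- ranges[ranges$edge == 2, ]
  A <- do.call(rbind, lapply(seq_len(nrow(e1)), function(i) {
    part_segment(sl, e1$border[i], e1$start[i], e1$end[i])
  }))
  B <- do.call(rbind, lapply(seq_len(nrow(e2)), function(i) {
    part_segment(sl, e2$border[i], e2$start[i], e2$end[i])
  }))
  if (mode == "paired") {
    if (nrow(A) != nrow(B)) {
      stop("paired width requires equal counts on both edges", call. = FALSE)
    }
    mean(sqrt(rowSums((A - B)^2)))
  } else {
    mean(nearest_distances(A, B))
  }
}

#' Sinuosity index
#'
#' Ratio of a suture edge's arc length to the straight-line distance between
#' its two endpoints, computed per edge segment and averaged over the part's
#' segments; 1 for a straight suture, larger for interdigitated sutures.
#'
#' @inheritParams suture_length
#' @return Dimensionless SI (>= 1 up to round-off).
#' @export
sinuosity_index <- function(sl, partition, part) {
  ranges <- get_part_ranges(partition, part)
  si <- vapply(seq_len(nrow(ranges)), function(i) {
    seg <- part_segment(sl, ranges$border[i], ranges$start[i], ranges$end[i])
    chord <- sqrt(sum((seg[1, ] - seg[nrow(seg), ])^2))
    if (chord <= 1e-12) {
      stop("closed curve has undefined SI (part ", part, ")", call. = FALSE)
    }
    polyline_length(seg) / chord
  }, numeric(1))
  mean(si)
}

#' Cranial length, width and circumference
#'
#' Cranial length L is the distance from glabella to opisthocranion, width W
#' the distance between the two eurions, and circumference C the arc length of
#' the closed axial head contour through glabella and opisthocranion. Without
#' a contour, C is reported as `NA` (never extrapolated from L and W).
#'
#' @param landmarks List with `points` (tibble `landmark`, `x,y,z` including
#'   glabella, opisthocranion, eurionL, eurionR) and optional `axial_contour`.
#' @param contour_tol If the contour passes farther than this (mm) from
#'   glabella or opisthocranion, a warning is issued.
#' @return Tibble with `cranial_length`, `cranial_width`,
#'   `cranial_circumference` (mm).
#' @export
cranial_measurements <- function(landmarks, contour_tol = 2) {
  pts <- landmarks$points
  get <- function(nm) {
    row <- pts[pts$landmark == nm, ]
    if (!nrow(row)) stop("missing landmark: ", nm, call. = FALSE)
    as.numeric(row[1, c("x", "y", "z")])
  }
  g <- get("glabella"); op <- get("opisthocranion")
  L <- sqrt(sum((g - op)^2))
  W <- sqrt(sum((get("eurionL") - get("eurionR"))^2))
  C <- NA_real_
  if (!is.null(landmarks$axial_contour)) {
    ctr <- as_point_matrix(landmarks$axial_contour)
    dg <- min(sqrt(rowSums(sweep(ctr, 2, g)^2)))
    dop <- min(sqrt(rowSums(sweep(ctr, 2, op)^2)))
    if (dg > contour_tol || dop > contour_tol) {
      warning("axial contour passes ", sprintf("%.2f", max(dg, dop)),
              " mm from glabella/opisthocranion", call. = FALSE)
    }
    C <- contour_length(ctr, closed = TRUE)
  }
  tibble::tibble(cranial_length = L, cranial_width = W,
                 cranial_circumference = C)
}

#' Full morphometric record of one subject
#'
#' Combines cranial measurements, per-suture length/width/SI for the five
#' named sutures, the unweighted mean SI, and (optionally) the total
#' thin-plate-spline surface area of all sutures and fontanelles.
#'
#' @inheritParams suture_length
#' @param landmarks Anatomical landmarks (see [cranial_measurements()]), or
#'   `NULL` to skip the cranial columns.
#' @param surface_area Compute `total_surface_area` via [total_suture_area()]?
#' @param target_edge Mesh edge target (mm) passed to [total_suture_area()].
#' @return One-row tibble (a morphometric record).
#' @export
measure_subject <- function(sl, partition, landmarks = NULL,
                            surface_area = TRUE, target_edge = 0.3) {
  rec <- tibble::tibble(subject_id = sl$subject_id[1])
  if (!is.null(landmarks)) {
    rec <- dplyr::bind_cols(rec, cranial_measurements(landmarks))
  } else {
    rec$cranial_length <- NA_real_
    rec$cranial_width <- NA_real_
    rec$cranial_circumference <- NA_real_
  }
  for (p in suture_parts) {
    rec[[paste0(p, "_length")]] <- suture_length(sl, partition, p)
    rec[[paste0(p, "_width")]] <- suture_width(sl, partition, p)
    rec[[paste0(p, "_si")]] <- sinuosity_index(sl, partition, p)
  }
  rec$average_si <- mean(vapply(suture_parts, function(p) {
    rec[[paste0(p, "_si")]]
  }, numeric(1)))
  if (surface_area) {
    area <- total_suture_area(sl, partition, target_edge = target_edge)
    rec$total_surface_area <- area$total
  } else {
    rec$total_surface_area <- NA_real_
  }
  rec
}
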