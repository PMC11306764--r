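# Validators for the core tabular types. Each validator returns its input
# invisibly on success and signals a classed error on violation.

#' Default per-border semilandmark counts
#'
#' Borders 1, 2 and 7 carry 100 semilandmarks, borders 3 and 4 carry 200, and
#' borders 5 and 6 carry 50, for 800 in total.
#' @return Named integer vector of length 7 (names `"1"`..`"7"`).
#' @export
default_counts <- function() {
  stats::setNames(c(100L, 100L, 200L, 200L, 50L, 50L, 100L), as.character(1:7))
}

n_borders <- 7L

#' Validate a border-curve table
#'
#' A border-curve table has one row per traced point with columns `subject_id`,
#' `border` (1-7), `ordinal` (order along the border) and `x`, `y`, `z` in mm.
#' Exactly 7 borders per subject are required, each with at least 2 points, no
#' two consecutive identical points, and all coordinates finite.
#'
#' @param curves Tibble of border points.
#' @return The input, invisibly.
#' @export
validate_border_curves <- function(curves) {
  req <- c("subject_id", "border", "ordinal", "x", "y", "z")
  miss <- setdiff(req, names(curves))
  if (length(miss)) {
    stop("corrupt input: missing columns ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  xyz <- as.matrix(curves[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) {
    stop("corrupt input: non-finite coordinate", call. = FALSE)
  }
  for (sid in unique(curves$subject_id)) {
    sub <- curves[curves$subject_id == sid, ]
    present <- sort(unique(as.integer(sub$border)))
    if (!identical(present, seq_len(n_borders))) {
      stop("incomplete subject: ", sid, " has borders ",
           paste(present, collapse = ","), " (need 1-", n_borders, ")",
           call. = FALSE)
    }
    for (b in present) {
      cb <- sub[sub$border == b, ]
      cb <- cb[order(cb$ordinal), ]
      if (nrow(cb) < 2) {
        stop("degenerate border: border ", b, " of subject ", sid,
             " has fewer than 2 points", call. = FALSE)
      }
      m <- as.matrix(cb[, c("x", "y", "z")])
      if (any(rowSums(abs(diff(m))) == 0)) {
        stop("degenerate border: consecutive identical points on border ", b,
             " of subject ", sid, call. = FALSE)
      }
    }
  }
  invisible(curves)
}

#' Validate a semilandmark table
#'
#' Checks per-border counts against `counts`, contiguous strictly increasing
#' ordinals within each border, and finite coordinates.
#'
#' @param sl Semilandmark tibble (`subject_id`, `border`, `ordinal`, `x,y,z`).
#' @param counts Named per-border counts, as from [default_counts()].
#' @return The input, invisibly.
#' @export
validate_semilandmarks <- function(sl, counts = default_counts()) {
  if (!all(is.finite(as.matrix(sl[, c("x", "y", "z")])))) {
    stop("corrupt input: non-finite coordinate", call. = FALSE)
  }
  for (sid in unique(sl$subject_id)) {
    sub <- sl[sl$subject_id == sid, ]
    if (nrow(sub) != sum(counts)) {
      stop("semilandmark count mismatch for subject ", sid, ": ", nrow(sub),
           " != ", sum(counts), call. = FALSE)
    }
    for (b in as.integer(names(counts))) {
      ords <- sub$ordinal[sub$border == b]
      if (length(ords) != counts[[as.character(b)]]) {
        stop("semilandmark count mismatch on border ", b, " of subject ", sid,
             call. = FALSE)
      }
      if (!identical(as.integer(sort(ords)), seq_along(ords))) {
        stop("ordinals on border ", b, " of subject ", sid,
             " are not contiguous and strictly increasing", call. = FALSE)
      }
    }
  }
  invisible(sl)
}

#' Validate a morphometric record table
#'
#' One row per subject with cranial length/width/circumference, per-suture
#' length, width and sinuosity index, total surface area and average sinuosity
#' index. Lengths, widths and areas must be non-negative and every sinuosity
#' index at least 1 (widths of 0 are allowed: a fused suture has zero width).
#'
#' @param records Morphometric tibble.
#' @return The input, invisibly.
#' @export
validate_morphometrics <- function(records) {
  if (anyDuplicated(records$subject_id)) {
    stop("duplicate subject_id in morphometric records", call. = FALSE)
  }
  si_cols <- grep("_si$|^average_si$", names(records), value = TRUE)
  for (col in si_cols) {
    v <- records[[col]]
    if (any(is.finite(v) & v < 1 - 1e-9)) {
      stop("invalid morphometrics: ", col, " < 1", call. = FALSE)
    }
  }
  num_cols <- setdiff(names(records)[vapply(records, is.numeric, logical(1))],
                      si_cols)
  for (col in num_cols) {
    v <- records[[col]]
    if (any(is.finite(v) & v < 0)) {
      stop("invalid morphometrics: negative ", col, call. = FALSE)
    }
  }
  if (all(c("cranial_length", "cranial_width", "cranial_circumference")
          %in% names(records))) {
    ok <- is.finite(records$cranial_circumference)
    if (any(records$cranial_length[ok] > records$cranial_circumference[ok]) ||
        any(records$cranial_width[ok] > records$cranial_circumference[ok])) {
      stop("invalid morphometrics: cranial chord exceeds circumference",
           call. = FALSE)
    }
  }
  invisible(records)
}

#' Validate anatomical landmarks
#'
#' Requires the alignment triplet (rhinion, fmoR, fmoL) to be non-collinear and
#' the axial contour, if present, to be closed and planar within tolerance.
#'
#' @param lm List with elements `points` (tibble `landmark`, `x`, `y`, `z`) and
#'   optional `axial_contour` (ordered point tibble, closed).
#' @param planar_tol Maximum out-of-plane deviation of the contour (mm).
#' @return The input, invisibly.
#' @export
validate_landmarks <- function(lm, planar_tol = 2) {
  pts <- lm$points
  need <- c("rhinion", "fmoR", "fmoL")
  if (!all(need %in% pts$landmark)) {
    stop("incomplete subject: missing alignment landmark(s)", call. = FALSE)
  }
  tri <- as.matrix(pts[match(need, pts$landmark), c("x", "y", "z")])
  v1 <- tri[2, ] - tri[1, ]
  v2 <- tri[3, ] - tri[1, ]
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  if (sqrt(sum(cr^2)) < 1e-9) {
    stop("alignment triplet is collinear", call. = FALSE)
  }
  if (!is.null(lm$axial_contour)) {
    ctr <- as_point_matrix(lm$axial_contour)
    if (planarity_deviation(ctr) > planar_tol) {
      stop("axial contour is not planar within tolerance", call. = FALSE)
    }
  }
  invisible(lm)
}
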