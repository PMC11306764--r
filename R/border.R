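# Border resampling to semilandmarks and width-series construction.

#' Resample one border polyline to equally spaced points
#'
#' Places `n` points at equal arc-length spacing along the polyline, the first
#' and last coinciding with the curve endpoints; every output point lies on a
#' segment of the input polyline.
#'
#' @param curve Data frame (or matrix) of ordered 3D points with columns
#'   `x`, `y`, `z`.
#' @param n Number of output points (>= 2).
#' @return Tibble with `ordinal`, `x`, `y`, `z`.
#' @examples
#' seg <- tibble::tibble(x = c(0, 10), y = 0, z = 0)
#' resample_border(seg, 5)$x # 0 2.5 5 7.5 10
#' @export
resample_border <- function(curve, n) {
  mat <- as_point_matrix(curve)
  out <- resample_polyline(mat, n)
  tibble::tibble(ordinal = seq_len(n), x = out[, 1], y = out[, 2],
                 z = out[, 3])
}

#' Assemble the fixed-topology semilandmark set of a subject
#'
#' Resamples each of the seven border curves to its configured semilandmark
#' count (defaults 100, 100, 200, 200, 50, 50, 100, i.e. 800 in total) and
#' concatenates them into a border-indexed, ordinal-ordered point table.
#'
#' @param curves Validated border-curve tibble (one subject).
#' @param counts Named per-border counts, as from [default_counts()].
#' @return Semilandmark tibble (`subject_id`, `border`, `ordinal`, `x,y,z`)
#'   with attribute `counts`.
#' @export
assemble_semilandmarks <- function(curves, counts = default_counts()) {
  validate_border_curves(curves)
  if (!identical(sort(as.integer(names(counts))), seq_len(n_borders))) {
    stop("counts must be named for borders 1-", n_borders, call. = FALSE)
  }
  if (length(unique(curves$subject_id)) != 1) {
    stop("assemble_semilandmarks expects a single subject", call. = FALSE)
  }
  sid <- curves$subject_id[1]
  out <- purrr::map_dfr(seq_len(n_borders), function(b) {
    cb <- curves[curves$border == b, ]
    cb <- cb[order(cb$ordinal), ]
    rs <- resample_border(cb, counts[[as.character(b)]])
    tibble::tibble(subject_id = sid, border = b, ordinal = rs$ordinal,
                   x = rs$x, y = rs$y, z = rs$z)
  })
  validate_semilandmarks(out, counts)
  attr(out, "counts") <- counts
  out
}

sl_border_matrix <- function(sl, border) {
  sub <- sl[sl$border == border, ]
  sub <- sub[order(sub$ordinal), ]
  as.matrix(sub[, c("x", "y", "z")])
}

#' Width series between two borders
#'
#' In `"paired"` mode the i-th width is the distance between the i-th
#' semilandmark on each border (both borders must carry the same count); in
#' `"nearest"` mode it is the distance from the i-th semilandmark on
#' `border_a` to the nearest semilandmark on `border_b`.
#'
#' @param sl Semilandmark tibble for one subject.
#' @param border_a,border_b Border indices (1-7).
#' @param mode `"paired"` or `"nearest"`.
#' @return Tibble with `ordinal` and `width` (mm), plus attributes
#'   `source_borders` and `pairing_mode`.
#' @export
width_series <- function(sl, border_a, border_b,
                         mode = c("paired", "nearest")) {
  mode <- match.arg(mode)
  A <- sl_border_matrix(sl, border_a)
  B <- sl_border_matrix(sl, border_b)
  if (mode == "paired") {
    if (nrow(A) != nrow(B)) {
      stop("paired width series requires equal semilandmark counts (",
           nrow(A), " vs ", nrow(B), ")", call. = FALSE)
    }
    w <- sqrt(rowSums((A - B)^2))
  } else {
    w <- nearest_distances(A, B)
  }
  out <- tibble::tibble(ordinal = seq_len(nrow(A)), width = w)
  attr(out, "source_borders") <- c(border_a, border_b)
  attr(out, "pairing_mode") <- mode
  out
}

as_width_vector <- function(widths) {
  w <- if (is.data.frame(widths)) widths$width else as.numeric(widths)
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("width series must be finite and non-negative", call. = FALSE)
  }
  w
}

#' Detect the suture-to-fontanelle junction on a width series
#'
#' Scans the width series from `start` toward its end and collects the
#' candidate indices i at which the width increases sharply:
#' `w[i+1] - w[i] > k` and, under the default `"ratio"` form,
#' `w[i+1] - w[i] > 10 * k * (w[i] - w[i-1])` (the current increment dominates
#' the previous one). The junction is the last candidate. The alternative
#' `"abs"` form uses `w[i+1] - w[i] > 10 * k * abs(w[i] - w[i-1])`; the two
#' coincide on monotone profiles.
#'
#' @param widths Width series (tibble from [width_series()] or numeric vector).
#' @param k Width-change threshold (mm); defaults 0.15 for the metopic and 0.18
#'   for the sagittal scan (see [junction_config()]).
#' @param start First index scanned (>= 2 so that a previous increment exists).
#' @param end Last index scanned; defaults to the end of the series.
#' @param form Comparison strategy for the second clause (see Details).
#' @return The junction index (integer), or `NA_integer_` if no index
#'   satisfies the criterion.
#' @export
detect_fontanelle_junction <- function(widths, k, start = 2L, end = NULL,
                                       form = c("ratio", "abs")) {
  form <- match.arg(form)
  w <- as_width_vector(widths)
  n <- length(w)
  if (n < 3) stop("width series shorter than 3", call. = FALSE)
  stopifnot(k > 0)
  start <- max(2L, as.integer(start))
  end <- min(n - 1L, as.integer(end %||% (n - 1L)))
  if (start > end) return(NA_integer_)
  i <- start:end
  inc <- w[i + 1L] - w[i]
  prev <- w[i] - w[i - 1L]
  if (form == "abs") prev <- abs(prev)
  cand <- i[inc > k & inc > 10 * k * prev]
  if (!length(cand)) return(NA_integer_)
  cand[length(cand)]
}

#' Detect lateral junction points on a width series
#'
#' Finds the indices where the discrete second-order width change exceeds `m`:
#' `(w[i+1] - w[i]) - (w[i] - w[i-1]) > m` (default `"second_diff"` form; the
#' `"abs"` variant thresholds the absolute second difference). Each run of
#' consecutive qualifying indices contributes its last index, so one anatomical
#' junction yields one junction point, ranked by the run's summed second
#' difference (a corner falling between samples splits its slope change over
#' adjacent ordinals).
#'
#' @param widths Width series (tibble or numeric vector), length >= 3.
#' @param m Second-difference threshold (mm); default 0.4.
#' @param start,end Scan range (defaults: the full interior of the series).
#' @param form Comparison strategy (see Details).
#' @return Tibble with `index` and `magnitude` (the second difference at the
#'   detected index), ordered by index; zero rows if none qualify.
#' @export
detect_lateral_junctions <- function(widths, m = 0.4, start = 2L, end = NULL,
                                     form = c("second_diff", "abs")) {
  form <- match.arg(form)
  w <- as_width_vector(widths)
  n <- length(w)
  if (n < 3) stop("width series shorter than 3", call. = FALSE)
  stopifnot(m > 0)
  start <- max(2L, as.integer(start))
  end <- min(n - 1L, as.integer(end %||% (n - 1L)))
  if (start > end) {
    return(tibble::tibble(index = integer(0), magnitude = numeric(0)))
  }
  i <- start:end
  d2 <- (w[i + 1L] - w[i]) - (w[i] - w[i - 1L])
  hit <- if (form == "abs") abs(d2) > m else d2 > m
  idx <- i[hit]
  mag <- d2[hit]
  if (!length(idx)) {
    return(tibble::tibble(index = integer(0), magnitude = numeric(0)))
  }
  # each run of consecutive hits contributes its last index; the run's
  # magnitudes are summed (the corner's slope change may split over samples)
  run_id <- cumsum(c(1L, diff(idx) != 1L))
  tibble::tibble(
    index = as.integer(tapply(idx, run_id, max)),
    magnitude = as.numeric(tapply(mag, run_id, sum)))
}
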