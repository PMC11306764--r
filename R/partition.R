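# Partition of the 800 semilandmarks into 9 named suture/fontanelle parts
# delimited by 32 junction points (JPs).
#
# Border topology (fixed by the border-tracing convention, mirrored L/R):
#   border 1/2: left/right frontal bone edge, starting at the nasion; runs
#     along the metopic suture, around the anterior fontanelle (AF) front
#     edge, down the coronal suture and briefly into the sphenoidal fontanelle.
#   border 3/4: left/right parietal bone edge, starting (and conceptually
#     ending) at the parietal corner point; runs along the sagittal suture,
#     the posterior fontanelle (PF) front edge, the lambdoid suture, the
#     mastoid fontanelle, the squamosal suture, the sphenoidal fontanelle, the
#     coronal suture and finally the AF back edge.
#   border 5/6: left/right temporal bone superior edge, from the sphenoidal
#     to the mastoid fontanelle along the squamosal suture.
#   border 7: occipital bone superior edge, from the left mastoid fontanelle
#     over the left lambdoid suture, the PF back edges and the right lambdoid
#     suture into the right mastoid fontanelle.
#
# JP numbering: JP1/JP2 nasion starts of borders 1/2; JP3/JP4 metopic-AF
# junctions; JP5/JP6 parietal corner starts of borders 3/4; JP7/JP8
# sagittal-PF junctions; JP9-JP32 the lateral junctions in border order
# (2 on border 1, 2 on border 2, 6 on border 3, 6 on border 4, 2 on border 5,
# 2 on border 6, 4 on border 7).

lateral_expected <- c(`1` = 2L, `2` = 2L, `3` = 6L, `4` = 6L, `5` = 2L,
                      `6` = 2L, `7` = 4L)

part_names <- c("metopic", "anterior_fontanelle", "sagittal", "coronal",
                "squamosal", "lambdoid", "posterior_fontanelle",
                "sphenoidal_fontanelle", "mastoid_fontanelle")

#' Junction-detection configuration
#'
#' Thresholds and strategy switches of the junction-point detector. The
#' defaults are the framework's reference values: `k_metopic = 0.15` mm for the
#' metopic-to-anterior-fontanelle junctions (JP3/JP4), `k_sagittal = 0.18` mm
#' for the sagittal-to-posterior-fontanelle junctions (JP7/JP8), and
#' `m_lateral = 0.4` for the 24 lateral junctions (JP9-JP32).
#'
#' `scan_window_frontal` / `scan_window_parietal` bound the midline junction
#' search to a leading fraction of borders 1/2 and 3/4: beyond the fontanelle
#' these borders turn laterally and the inter-border width series no longer
#' measures a suture width. `guard` is the number of ordinals skipped after a
#' midline junction before the lateral scan starts.
#'
#' @param k_metopic,k_sagittal Width-change thresholds (mm), > 0.
#' @param m_lateral Second-difference threshold (mm), > 0.
#' @param scan_window_frontal,scan_window_parietal Leading fraction of the
#'   border scanned for the midline junctions.
#' @param guard Ordinals skipped after JP3/JP7 before the lateral scan.
#' @param eq1_form,eq2_form Strategy switches of the two criteria (see
#'   [detect_fontanelle_junction()] and [detect_lateral_junctions()]).
#' @return A list of class `junction_config`.
#' @export
junction_config <- function(k_metopic = 0.15, k_sagittal = 0.18,
                            m_lateral = 0.4,
                            scan_window_frontal = 0.42,
                            scan_window_parietal = 0.35,
                            guard = 3L,
                            eq1_form = c("ratio", "abs"),
                            eq2_form = c("second_diff", "abs")) {
  stopifnot(k_metopic > 0, k_sagittal > 0, m_lateral > 0,
            scan_window_frontal > 0, scan_window_frontal <= 1,
            scan_window_parietal > 0, scan_window_parietal <= 1, guard >= 1)
  structure(
    list(k_metopic = k_metopic, k_sagittal = k_sagittal,
         m_lateral = m_lateral,
         scan_window_frontal = scan_window_frontal,
         scan_window_parietal = scan_window_parietal,
         guard = as.integer(guard),
         eq1_form = match.arg(eq1_form), eq2_form = match.arg(eq2_form)),
    class = "junction_config"
  )
}

new_suture_partition <- function(junctions, parts) {
  structure(list(junctions = junctions, parts = parts),
            class = "suture_partition")
}

#' @export
print.suture_partition <- function(x, ...) {
  cat("<suture_partition>:", nrow(x$junctions), "junction points,",
      length(unique(x$parts$part)), "parts\n")
  print(dplyr::count(x$parts, .data$part, name = "ranges"), n = Inf)
  invisible(x)
}

# nearest distance from each semilandmark of one border to all other borders
union_width_series <- function(sl, border) {
  A <- sl_border_matrix(sl, border)
  B <- as.matrix(sl[sl$border != border, c("x", "y", "z")])
  nearest_distances(A, B)
}

detect_laterals_on_border <- function(sl, border, cfg, start) {
  w <- union_width_series(sl, border)
  hits <- detect_lateral_junctions(w, m = cfg$m_lateral,
                                   start = max(start, 1L + cfg$guard),
                                   end = length(w) - cfg$guard,
                                   form = cfg$eq2_form)
  expected <- lateral_expected[[as.character(border)]]
  if (nrow(hits) < expected) {
    stop("partition failure: expected ", expected,
         " lateral junctions on border ", border, ", found ", nrow(hits),
         call. = FALSE)
  }
  if (nrow(hits) > expected) {
    warning("border ", border, ": ", nrow(hits), " lateral junction ",
            "candidates, keeping the ", expected, " strongest", call. = FALSE)
    hits <- hits[order(-hits$magnitude)[seq_len(expected)], ]
    hits <- hits[order(hits$index), ]
  }
  hits$index
}

#' Partition the semilandmarks into sutures and fontanelles
#'
#' Detects the 32 junction points of one subject and assembles the nine named
#' parts (metopic, sagittal, coronal, squamosal and lambdoid sutures; anterior,
#' posterior, sphenoidal and mastoid fontanelles) as 1-based inclusive ordinal
#' ranges on the relevant borders. JP1/JP2 and JP5/JP6 are the fixed first
#' ordinals of borders 1/2 and 3/4; JP3/JP4 and JP7/JP8 are found on the paired
#' midline width series with `k_metopic` / `k_sagittal`; JP9-JP32 are found on
#' each border's nearest-distance-to-other-borders series with `m_lateral`.
#'
#' @param sl Semilandmark tibble of one subject.
#' @param cfg A [junction_config()].
#' @return A `suture_partition`: list with tibbles `junctions`
#'   (`jp`, `border`, `ordinal`) and `parts`
#'   (`part`, `border`, `start`, `end`, `edge`, `side`), where `edge` (1 or 2)
#'   labels the two opposing bone edges of a suture part and `side` is
#'   `"L"`, `"R"` or `"M"`.
#' @export
partition_sutures <- function(sl, cfg = junction_config()) {
  counts <- vapply(as.character(1:7), function(b) {
    sum(sl$border == as.integer(b))
  }, integer(1))
  validate_semilandmarks(sl, counts)

  w12 <- width_series(sl, 1, 2, mode = "paired")
  jp3 <- detect_fontanelle_junction(
    w12, k = cfg$k_metopic, start = 2L,
    end = floor(cfg$scan_window_frontal * counts[["1"]]), form = cfg$eq1_form)
  if (is.na(jp3)) stop("partition failure: JP3", call. = FALSE)

  w34 <- width_series(sl, 3, 4, mode = "paired")
  jp7 <- detect_fontanelle_junction(
    w34, k = cfg$k_sagittal, start = 2L,
    end = floor(cfg$scan_window_parietal * counts[["3"]]), form = cfg$eq1_form)
  if (is.na(jp7)) stop("partition failure: JP7", call. = FALSE)

  lat <- list(
    `1` = detect_laterals_on_border(sl, 1, cfg, start = jp3 + cfg$guard),
    `2` = detect_laterals_on_border(sl, 2, cfg, start = jp3 + cfg$guard),
    `3` = detect_laterals_on_border(sl, 3, cfg, start = jp7 + cfg$guard),
    `4` = detect_laterals_on_border(sl, 4, cfg, start = jp7 + cfg$guard),
    `5` = detect_laterals_on_border(sl, 5, cfg, start = 2L),
    `6` = detect_laterals_on_border(sl, 6, cfg, start = 2L),
    `7` = detect_laterals_on_border(sl, 7, cfg, start = 2L)
  )

  junctions <- tibble::tibble(
    jp = paste0("JP", 1:32),
    border = c(1L, 2L, 1L, 2L, 3L, 4L, 3L, 4L,
               rep(1L, 2), rep(2L, 2), rep(3L, 6), rep(4L, 6),
               rep(5L, 2), rep(6L, 2), rep(7L, 4)),
    ordinal = as.integer(c(1L, 1L, jp3, jp3, 1L, 1L, jp7, jp7,
                           lat[["1"]], lat[["2"]], lat[["3"]], lat[["4"]],
                           lat[["5"]], lat[["6"]], lat[["7"]]))
  )

  a  <- lat[["1"]]; a2 <- lat[["2"]]   # frontal: AF end, coronal end
  l  <- lat[["3"]]; l2 <- lat[["4"]]   # parietal: 6 junctions in border order
  s  <- lat[["5"]]; s2 <- lat[["6"]]   # temporal: squamosal start/end
  o  <- lat[["7"]]                     # occipital: 4 junctions
  c1 <- counts[["1"]]; c3 <- counts[["3"]]; c5 <- counts[["5"]]
  c7 <- counts[["7"]]

  rng <- function(part, border, start, end, edge, side) {
    tibble::tibble(part = part, border = as.integer(border),
                   start = as.integer(start), end = as.integer(end),
                   edge = as.integer(edge), side = side)
  }
  parts <- dplyr::bind_rows(
    rng("metopic", 1, 1, jp3, 1, "L"),
    rng("metopic", 2, 1, jp3, 2, "R"),
    rng("anterior_fontanelle", 1, jp3, a[1], 1, "L"),
    rng("anterior_fontanelle", 2, jp3, a2[1], 1, "R"),
    rng("anterior_fontanelle", 3, l[6], c3, 2, "L"),
    rng("anterior_fontanelle", 4, l2[6], c3, 2, "R"),
    rng("sagittal", 3, 1, jp7, 1, "L"),
    rng("sagittal", 4, 1, jp7, 2, "R"),
    rng("coronal", 1, a[1], a[2], 1, "L"),
    rng("coronal", 2, a2[1], a2[2], 1, "R"),
    rng("coronal", 3, l[5], l[6], 2, "L"),
    rng("coronal", 4, l2[5], l2[6], 2, "R"),
    rng("squamosal", 3, l[3], l[4], 1, "L"),
    rng("squamosal", 4, l2[3], l2[4], 1, "R"),
    rng("squamosal", 5, s[1], s[2], 2, "L"),
    rng("squamosal", 6, s2[1], s2[2], 2, "R"),
    rng("lambdoid", 3, l[1], l[2], 1, "L"),
    rng("lambdoid", 4, l2[1], l2[2], 1, "R"),
    rng("lambdoid", 7, o[1], o[2], 2, "L"),
    rng("lambdoid", 7, o[3], o[4], 2, "R"),
    rng("posterior_fontanelle", 3, jp7, l[1], 1, "L"),
    rng("posterior_fontanelle", 4, jp7, l2[1], 1, "R"),
    rng("posterior_fontanelle", 7, o[2], o[3], 2, "M"),
    rng("sphenoidal_fontanelle", 1, a[2], c1, 1, "L"),
    rng("sphenoidal_fontanelle", 2, a2[2], c1, 1, "R"),
    rng("sphenoidal_fontanelle", 3, l[4], l[5], 2, "L"),
    rng("sphenoidal_fontanelle", 4, l2[4], l2[5], 2, "R"),
    rng("sphenoidal_fontanelle", 5, 1, s[1], 3, "L"),
    rng("sphenoidal_fontanelle", 6, 1, s2[1], 3, "R"),
    rng("mastoid_fontanelle", 3, l[2], l[3], 1, "L"),
    rng("mastoid_fontanelle", 4, l2[2], l2[3], 1, "R"),
    rng("mastoid_fontanelle", 5, s[2], c5, 2, "L"),
    rng("mastoid_fontanelle", 6, s2[2], c5, 2, "R"),
    rng("mastoid_fontanelle", 7, 1, o[1], 3, "L"),
    rng("mastoid_fontanelle", 7, o[4], c7, 3, "R")
  )
  bad <- parts$start >= parts$end
  if (any(bad)) {
    stop("partition failure: empty range for part ",
         paste(unique(parts$part[bad]), collapse = ", "), call. = FALSE)
  }
  new_suture_partition(junctions, parts)
}

#' Extract the ordered point matrix of one part range
#' @noRd
part_segment <- function(sl, border, start, end, reverse = FALSE) {
  m <- sl_border_matrix(sl, border)[start:end, , drop = FALSE]
  if (reverse) m[rev(seq_len(nrow(m))), , drop = FALSE] else m
}
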