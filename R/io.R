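# Readers and writers for border curves, landmarks and result tables.
#
# Internal coordinate frame ("RAS-like"): X = left -> right, Y = posterior ->
# anterior, Z = inferior -> superior, millimetres everywhere. Slicer Markups
# FCSV files declare their frame (LPS or RAS) in the header; LPS coordinates
# are converted on read by negating x and y. The frame tag is carried as the
# `coordinate_frame` attribute, never silently assumed.

internal_frame <- "RAS"

#' Read traced border curves
#'
#' Reads a per-subject set of seven ordered border polylines from plain CSV
#' (columns `subject_id`, `border`, `ordinal`, `x`, `y`, `z`), Slicer Markups
#' FCSV (one point per row, border and ordinal encoded in the point label as
#' `b<border>-<ordinal>`), or a JSON mirror of the CSV schema. Coordinates are
#' converted to the package frame (X left to right, Y posterior to anterior,
#' Z inferior to superior; mm) and validated.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"`, `"fcsv"` or `"json"`.
#' @param subject_id Subject id to use when the format does not carry one
#'   (FCSV); defaults to the file name.
#' @return A validated border-curve tibble, ordered by border then ordinal,
#'   with attribute `coordinate_frame`.
#' @seealso [write_border_curves()], [validate_border_curves()]
#' @export
read_border_curves <- function(path, format = c("auto", "csv", "fcsv", "json"),
                               subject_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", fcsv = "fcsv", json = "json",
                     stop("cannot infer format of ", path, call. = FALSE))
  }
  curves <- switch(format,
    # base read.csv: its strtod parser is correctly rounded, giving bitwise
    # round trips of the 17-digit coordinate serialization
    csv = tibble::as_tibble(utils::read.csv(path)),
    json = tibble::as_tibble(jsonlite::fromJSON(path)),
    fcsv = read_fcsv_points(path, subject_id %||% basename(path))
  )
  curves <- tibble::as_tibble(curves)
  curves$border <- as.integer(curves$border)
  curves$ordinal <- as.integer(curves$ordinal)
  for (cl in c("x", "y", "z")) curves[[cl]] <- as.numeric(curves[[cl]])
  curves <- dplyr::arrange(curves, .data$subject_id, .data$border,
                           .data$ordinal)
  validate_border_curves(curves)
  attr(curves, "coordinate_frame") <- internal_frame
  curves
}

read_fcsv_points <- function(path, subject_id) {
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  frame <- "LPS"
  cs <- grep("CoordinateSystem", header, value = TRUE)
  if (length(cs)) {
    frame <- if (grepl("RAS|= *1", cs[1])) "RAS" else "LPS"
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(body)) stop("corrupt input: empty FCSV", call. = FALSE)
  df <- utils::read.csv(text = body, header = FALSE,
                        stringsAsFactors = FALSE)
  # Slicer markups fcsv: id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,node
  lab <- as.character(df[[12]])
  m <- regmatches(lab, regexec("^b([0-9]+)-([0-9]+)$", lab))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) {
    stop("corrupt input: FCSV label not of form b<border>-<ordinal>",
         call. = FALSE)
  }
  out <- tibble::tibble(
    subject_id = subject_id,
    border = as.integer(vapply(m, `[`, character(1), 2)),
    ordinal = as.integer(vapply(m, `[`, character(1), 3)),
    x = as.numeric(df[[2]]), y = as.numeric(df[[3]]), z = as.numeric(df[[4]])
  )
  if (frame == "LPS") {
    out$x <- -out$x
    out$y <- -out$y
  }
  out
}

#' Write border curves
#'
#' Writes the CSV, FCSV or JSON representation read by [read_border_curves()].
#' Coordinates are serialized at full double precision so that a read/write
#' round trip is bitwise exact. FCSV output declares `CoordinateSystem = LPS`
#' (Slicer's default dialect) and converts from the internal frame.
#'
#' @param curves Border-curve tibble.
#' @param path Output path.
#' @param format `"csv"`, `"fcsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_border_curves <- function(curves, path,
                                format = c("csv", "fcsv", "json")) {
  format <- match.arg(format)
  validate_border_curves(curves)
  full <- curves
  # serialize coordinates at 17 significant digits for bitwise round trips
  for (cl in c("x", "y", "z")) full[[cl]] <- format_full(curves[[cl]])
  if (format == "csv") {
    readr::write_csv(full, path)
  } else if (format == "json") {
    jsonlite::write_json(full, path, digits = NA, auto_unbox = TRUE)
  } else {
    if (length(unique(curves$subject_id)) != 1) {
      stop("FCSV holds one subject per file", call. = FALSE)
    }
    rows <- sprintf(
      "p%d,%s,%s,%s,0,0,0,1,1,1,0,b%d-%d,,",
      seq_len(nrow(curves)),
      format_full(-curves$x), format_full(-curves$y), format_full(curves$z),
      curves$border, curves$ordinal
    )
    writeLines(c(
      "# Markups fiducial file version = 4.11",
      "# CoordinateSystem = LPS",
      "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID",
      rows
    ), path)
  }
  invisible(path)
}

#' Write and read morphometric record tables
#'
#' One row per subject, stable column order, full-precision CSV so that
#' `read_morphometrics(write_morphometrics(x))` returns equal records. Records
#' are validated (duplicate subjects and sinuosity indices below 1 are errors)
#' before writing.
#'
#' @param records Morphometric tibble.
#' @param path Output CSV path.
#' @return `path` invisibly (writer); the record tibble (reader).
#' @export
write_morphometrics <- function(records, path) {
  validate_morphometrics(records)
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_morphometrics
#' @export
read_morphometrics <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Serialize a suture partition to JSON
#'
#' @param partition A `suture_partition` (see [partition_sutures()]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  jsonlite::write_json(
    list(junctions = partition$junctions, parts = partition$parts),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  raw <- jsonlite::fromJSON(path)
  new_suture_partition(tibble::as_tibble(raw$junctions),
                       tibble::as_tibble(raw$parts))
}

#' Export a triangulated surface as Wavefront OBJ
#'
#' Plain-text mesh export of a reconstructed suture/fontanelle patch, for QC in
#' any mesh viewer.
#'
#' @param surface A `triangulated_surface` (see [triangulate_patch()]).
#' @param path Output `.obj` path.
#' @return `path`, invisibly.
#' @export
write_surface_obj <- function(surface, path) {
  v <- surface$vertices
  f <- surface$triangles
  writeLines(c(
    sprintf("v %s %s %s", format_full(v[, 1]), format_full(v[, 2]),
            format_full(v[, 3])),
    sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])
  ), path)
  invisible(path)
}
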