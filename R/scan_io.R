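# On-disk artifacts: PLY/STL scans, tooth-label sidecars, rigid-transform
# JSON, cohort manifests. Units are millimetres everywhere, on disk and in
# memory; angles are serialized in degrees only inside result tables, never
# radians. Readers reject malformed input rather than repairing it.

TIMEPOINTS <- c("T1", "T2", "ClinT2")

#' A labelled dental-cast point cloud
#'
#' The unit every pipeline stage consumes: an N x 3 point cloud in mm with
#' one FDI tooth number per point. Label 0 is reserved for non-tooth points
#' (gingiva, cast base) so they can be carried but ignored.
#'
#' @param points N x 3 numeric matrix, mm; must be finite, N >= 1.
#' @param labels Integer vector of length N of FDI two-digit tooth numbers
#'   (0 = unassigned).
#' @param patient_id Character scalar.
#' @param timepoint One of `"T1"`, `"T2"`, `"ClinT2"`.
#' @return Object of class `labeled_scan`.
#' @export
labeled_scan <- function(points, labels = integer(nrow(points)),
                         patient_id = "", timepoint = "T1") {
  points <- as_point_matrix(points)
  cm_assert(nrow(points) >= 1L, "scan must contain at least one point",
            "validation_error")
  cm_assert(all(is.finite(points)), "scan coordinates must be finite",
            "validation_error")
  labels <- as.integer(labels)
  cm_assert(length(labels) == nrow(points) && !anyNA(labels),
            "labels must be one integer per point", "integrity_error")
  cm_assert(is.character(patient_id) && length(patient_id) == 1L,
            "patient_id must be a character scalar", "validation_error")
  cm_assert(timepoint %in% TIMEPOINTS,
            "timepoint must be one of T1, T2, ClinT2", "validation_error")
  structure(list(points = points, labels = labels, patient_id = patient_id,
                 timepoint = timepoint),
            class = "labeled_scan")
}

#' @export
print.labeled_scan <- function(x, ...) {
  teeth <- sort(unique(x$labels[x$labels > 0L]))
  cat(sprintf("<labeled_scan> %s/%s: %d points, %d teeth (FDI %s)\n",
              x$patient_id, x$timepoint, nrow(x$points), length(teeth),
              paste(teeth, collapse = " ")))
  invisible(x)
}

#' Points belonging to one or more teeth
#'
#' @param scan A [labeled_scan()].
#' @param ids FDI tooth numbers.
#' @return Matrix of the matching points.
#' @export
tooth_points <- function(scan, ids) {
  cm_assert(inherits(scan, "labeled_scan"), "scan must be a labeled_scan",
            "config_error")
  missing_ids <- setdiff(ids, scan$labels)
  if (length(missing_ids) > 0L)
    cm_stop(sprintf("tooth id(s) %s not present in scan",
                    paste(missing_ids, collapse = ", ")), "lookup_error")
  scan$points[scan$labels %in% ids, , drop = FALSE]
}

#' FDI tooth numbers present in a scan
#' @param scan A [labeled_scan()].
#' @return Sorted integer vector (label 0 excluded).
#' @export
scan_teeth <- function(scan) sort(unique(scan$labels[scan$labels > 0L]))

# ---------------------------------------------------------------- PLY ----

ply_header <- function(n, format) {
  c("ply",
    sprintf("format %s 1.0", format),
    "comment castmove dental cast scan, coordinates in mm",
    sprintf("element vertex %d", n),
    "property double x",
    "property double y",
    "property double z",
    "end_header")
}

write_ply <- function(points, path, format = c("binary_little_endian", "ascii")) {
  format <- match.arg(format)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(ply_header(nrow(points), format), con, sep = "\n")
  if (format == "ascii") {
    writeLines(sprintf("%.17g %.17g %.17g",
                       points[, 1], points[, 2], points[, 3]), con, sep = "\n")
  } else {
    writeBin(as.vector(t(points)), con, size = 8L, endian = "little")
  }
  invisible(path)
}

read_ply <- function(path) {
  if (!file.exists(path))
    cm_stop(sprintf("file not found: %s", path), "io_error")
  raw <- readBin(path, "raw", file.size(path))
  # locate end_header in the (always-ASCII) header region
  idx <- grepRaw("end_header", raw, fixed = TRUE)
  if (length(idx) == 0L)
    cm_stop(sprintf("PLY parse error in %s: no end_header found", path),
            "parse_error")
  idx <- idx[1]
  body_start <- idx + nchar("end_header")
  if (body_start <= length(raw) && raw[body_start] == charToRaw("\r"))
    body_start <- body_start + 1L
  if (body_start > length(raw) || raw[body_start] != charToRaw("\n"))
    cm_stop(sprintf("PLY parse error in %s: end_header not newline-terminated",
                    path), "parse_error")
  header <- strsplit(rawToChar(raw[seq_len(idx - 1L)]), "\r?\n")[[1]]
  body <- raw[seq.int(body_start + 1L, length.out = length(raw) - body_start)]

  if (length(header) < 1L || header[1] != "ply")
    cm_stop(sprintf("PLY parse error in %s, line 1: missing 'ply' magic", path),
            "parse_error")
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1L)
    cm_stop(sprintf("PLY parse error in %s: expected one format line", path),
            "parse_error")
  fmt <- strsplit(fmt_line, " +")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    cm_stop(sprintf("PLY parse error in %s: unsupported format '%s'", path, fmt),
            "parse_error")
  el_lines <- grep("^element ", header)
  if (length(el_lines) != 1L ||
      !grepl("^element vertex [0-9]+$", header[el_lines]))
    cm_stop(sprintf(
      "PLY parse error in %s, line %d: exactly one 'element vertex N' supported",
      path, if (length(el_lines)) el_lines[1] else 0L), "parse_error")
  n <- as.integer(sub("^element vertex ", "", header[el_lines]))
  props <- header[grep("^property ", header)]
  want <- paste("property", rep(c("double", "float"), each = 3),
                c("x", "y", "z"))
  if (!(identical(props, want[1:3]) || identical(props, want[4:6])))
    cm_stop(sprintf(
      "PLY parse error in %s: vertex properties must be exactly x, y, z (float or double)",
      path), "parse_error")
  size <- if (grepl("double", props[1])) 8L else 4L

  if (fmt == "ascii") {
    txt <- rawToChar(body)
    vals <- suppressWarnings(scan(text = txt, what = double(), quiet = TRUE))
    if (length(vals) != 3L * n)
      cm_stop(sprintf(
        "PLY parse error in %s: expected %d coordinate values, found %d",
        path, 3L * n, length(vals)), "parse_error")
  } else {
    if (length(body) < 3L * n * size)
      cm_stop(sprintf(
        "PLY parse error in %s: binary body truncated at byte offset %d (need %d)",
        path, length(body), 3L * n * size), "parse_error")
    vals <- readBin(body, "double", n = 3L * n, size = size, endian = "little")
  }
  pts <- matrix(vals, ncol = 3L, byrow = TRUE)
  bad <- which(!is.finite(pts))
  if (length(bad) > 0L) {
    rec <- ((bad[1] - 1L) %% nrow(pts)) + 1L
    cm_stop(sprintf(
      "PLY parse error in %s: non-finite coordinate in vertex record %d",
      path, rec), "parse_error")
  }
  pts
}

# ---------------------------------------------------------------- STL ----

# Binary STL: 80-byte header, uint32 triangle count, then 50 bytes per
# triangle (normal + 3 vertices as float32, 2-byte attribute). Vertices are
# deduplicated within 1e-9 mm, keeping first-appearance order.
read_stl <- function(path) {
  if (!file.exists(path))
    cm_stop(sprintf("file not found: %s", path), "io_error")
  sz <- file.size(path)
  if (sz < 84)
    cm_stop(sprintf("STL parse error in %s: file shorter than 84-byte preamble",
                    path), "parse_error")
  con <- file(path, "rb")
  on.exit(close(con))
  head5 <- readBin(con, "raw", 5L)
  seek(con, 0)
  if (identical(rawToChar(head5), "solid") && !grepl("\\0",
      rawToChar(readBin(con, "raw", min(sz, 512L)))))
    cm_stop(sprintf("STL parse error in %s: ASCII STL is not supported", path),
            "parse_error")
  seek(con, 80)
  n_tri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (sz != 84 + 50 * n_tri)
    cm_stop(sprintf(
      "STL parse error in %s: size %d inconsistent with %d triangles",
      path, sz, n_tri), "parse_error")
  verts <- matrix(NA_real_, 3L * n_tri, 3L)
  for (i in seq_len(n_tri)) {
    vals <- readBin(con, "double", 12L, size = 4L, endian = "little")
    readBin(con, "raw", 2L)
    verts[(3L * i - 2L):(3L * i), ] <- matrix(vals[4:12], 3L, 3L, byrow = TRUE)
  }
  if (any(!is.finite(verts)))
    cm_stop(sprintf("STL parse error in %s: non-finite vertex coordinate", path),
            "parse_error")
  key <- paste(round(verts[, 1] / 1e-9), round(verts[, 2] / 1e-9),
               round(verts[, 3] / 1e-9))
  verts[!duplicated(key), , drop = FALSE]
}

# ------------------------------------------------------------- labels ----

write_labels <- function(labels, path) {
  write.csv(data.frame(point_index = seq_along(labels),
                       tooth_id_FDI = as.integer(labels)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_labels <- function(path, n_points) {
  if (!file.exists(path))
    cm_stop(sprintf("file not found: %s", path), "io_error")
  df <- read.csv(path)
  if (!identical(names(df), c("point_index", "tooth_id_FDI")))
    cm_stop(sprintf(
      "label file %s must have columns point_index,tooth_id_FDI", path),
      "parse_error")
  if (nrow(df) != n_points)
    cm_stop(sprintf(
      "label/point count mismatch: %d labels in %s but %d points in scan",
      nrow(df), path, n_points), "integrity_error")
  if (!identical(sort(df$point_index), seq_len(n_points)))
    cm_stop(sprintf("label file %s: point_index must cover 1..N exactly", path),
            "integrity_error")
  as.integer(df$tooth_id_FDI[order(df$point_index)])
}

# --------------------------------------------------------- public I/O ----

#' Read a labelled scan from disk
#'
#' Reads a point cloud from PLY (ASCII or binary little-endian) or binary
#' STL (vertices deduplicated within 1e-9 mm) plus a CSV label sidecar with
#' columns `point_index,tooth_id_FDI` (1-based indices).
#'
#' @param path Scan file (`.ply` or `.stl`).
#' @param label_path Label sidecar CSV; `NULL` labels every point 0.
#' @param patient_id,timepoint Metadata stored on the returned scan.
#' @return A [labeled_scan()].
#' @export
read_scan <- function(path, label_path = NULL, patient_id = "",
                      timepoint = "T1") {
  ext <- tolower(tools::file_ext(path))
  pts <- switch(ext,
    ply = read_ply(path),
    stl = read_stl(path),
    cm_stop(sprintf("unrecognized scan format '.%s' (PLY or STL supported)",
                    ext), "parse_error"))
  labels <- if (is.null(label_path)) integer(nrow(pts))
            else read_labels(label_path, nrow(pts))
  labeled_scan(pts, labels, patient_id = patient_id, timepoint = timepoint)
}

#' Write a labelled scan to disk
#'
#' Writes the point cloud as PLY (`binary_little_endian` by default, or
#' `ascii`) with double-precision coordinates in mm, and the labels as a
#' CSV sidecar. `write_scan` followed by [read_scan()] is the identity.
#'
#' @param scan A [labeled_scan()].
#' @param path Output PLY path.
#' @param label_path Output CSV path; `NULL` skips the sidecar.
#' @param format PLY dialect.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path, label_path = NULL,
                       format = c("binary_little_endian", "ascii")) {
  cm_assert(inherits(scan, "labeled_scan"), "scan must be a labeled_scan",
            "config_error")
  ok <- tryCatch({write_ply(scan$points, path, match.arg(format)); TRUE},
                 error = function(e) e)
  if (!isTRUE(ok))
    cm_stop(sprintf("cannot write scan to %s: %s", path,
                    conditionMessage(ok)), "io_error")
  if (!is.null(label_path)) write_labels(scan$labels, label_path)
  invisible(path)
}

# ---------------------------------------------------------- transforms ----

#' Read and write rigid transforms as JSON
#'
#' Transforms are serialized as 4x4 row-major homogeneous matrices in mm
#' with last row (0, 0, 0, 1). On read, the rotation block is checked for
#' orthonormality (max |R'R - I| < 1e-6) and a determinant of +1;
#' reflections and non-rigid matrices are rejected.
#'
#' @param transform A [rigid_transform()].
#' @param path JSON file path.
#' @return `read_transform_json` returns a [rigid_transform()];
#'   `write_transform_json` returns `path` invisibly.
#' @export
write_transform_json <- function(transform, path) {
  m <- rbind(cbind(transform$R, transform$t), c(0, 0, 0, 1))
  jsonlite::write_json(list(matrix_4x4_row_major = as.vector(t(m))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  if (!file.exists(path))
    cm_stop(sprintf("file not found: %s", path), "io_error")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- obj$matrix_4x4_row_major
  if (is.null(v) || length(v) != 16L || !is.numeric(v))
    cm_stop(sprintf("%s: expected 16-element matrix_4x4_row_major", path),
            "parse_error")
  m <- matrix(v, 4L, 4L, byrow = TRUE)
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-12)
    cm_stop(sprintf("%s: last homogeneous row must be (0,0,0,1)", path),
            "validation_error")
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) >= 1e-6)
    cm_stop(sprintf("%s: rotation block is not orthonormal", path),
            "validation_error")
  if (det(R) < 0)
    cm_stop(sprintf("%s: rotation block is a reflection (det = -1)", path),
            "validation_error")
  # re-orthonormalize the float round-off before the strict constructor
  sv <- svd(R)
  rigid_transform(sv$u %*% t(sv$v), m[1:3, 4])
}

# ------------------------------------------------------------ manifest ----

MANIFEST_COLUMNS <- c("patient_id", "group", "subgroup", "moved_tooth_id",
                      "planned_Tx", "planned_Ty", "planned_Tz",
                      "planned_Rx", "planned_Ry", "planned_Rz",
                      "planned_total", "staging_per_aligner", "n_aligners",
                      "compliance_hours_per_day", "true_efficacy")

GROUPS <- c("torque", "derotation", "distalization")
SUBGROUPS <- c("attachment", "none", "power_ridge")

validate_manifest <- function(df) {
  miss <- setdiff(MANIFEST_COLUMNS, names(df))
  if (length(miss) > 0L)
    cm_stop(sprintf("manifest is missing column(s): %s",
                    paste(miss, collapse = ", ")), "integrity_error")
  cm_assert(all(df$group %in% GROUPS),
            sprintf("manifest group values must be one of: %s",
                    paste(GROUPS, collapse = ", ")), "validation_error")
  cm_assert(all(df$subgroup %in% SUBGROUPS),
            sprintf("manifest subgroup values must be one of: %s",
                    paste(SUBGROUPS, collapse = ", ")), "validation_error")
  cm_assert(all(df$compliance_hours_per_day > 0 &
                  df$compliance_hours_per_day <= 24),
            "compliance_hours_per_day must lie in (0, 24]", "validation_error")
  df
}

#' Read and write a cohort manifest
#'
#' One row per analyzed tooth movement: patient, movement group
#' (torque / derotation / distalization), subgroup (attachment / none /
#' power_ridge), the moved FDI tooth, the six planned movement components,
#' the planned primary magnitude, staging per aligner, aligner count,
#' compliance and (for synthetic cohorts) the drawn true efficacy.
#'
#' @param manifest Data frame with the manifest columns.
#' @param path CSV path.
#' @return `read_manifest` returns the validated data frame.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  write.csv(manifest[, MANIFEST_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    cm_stop(sprintf("file not found: %s", path), "io_error")
  validate_manifest(read.csv(path, stringsAsFactors = FALSE))
}
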