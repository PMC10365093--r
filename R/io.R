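## File formats: pose logs (CSV with unit quaternions), scan schedules
## (JSON), centroid tables (TSV), calibration transforms (JSON) and the
## metrics/comparison reports (TSV/JSON).  Quaternion storage makes
## rigidity enforceable at parse time; all writers emit a provenance
## header and all round trips are lossless at 1e-9.

POSE_LOG_HEADER <- c("time_s", "qw", "qx", "qy", "qz",
                     "tx_mm", "ty_mm", "tz_mm")

fmt12 <- function(x) formatC(x, digits = 12, format = "g")

provenance_lines <- function(seed = NULL) {
  v <- as.character(utils::packageVersion("headmotion"))
  c(sprintf("# headmotion %s", v),
    if (!is.null(seed)) sprintf("# seed: %s", format(seed)))
}

#' Read a pose log
#'
#' Pose logs are UTF-8 CSV files with header
#' \code{time_s,qw,qx,qy,qz,tx_mm,ty_mm,tz_mm}: one scalar-first unit
#' quaternion and translation (mm) per time stamp, plus an optional
#' \code{# frame: <tag>} comment line.  Quaternions off unit norm by up
#' to 1e-3 are renormalized; beyond that the row is rejected (the log is
#' not a rigid pose stream).
#'
#' @param path file path.
#' @param frame frame tag to assume when the file carries none.
#' @param nominal_rate nominal sampling rate stored on the trace (Hz);
#'   default inferred from the median sampling interval.
#' @return A \code{\link{pose_trace}}.
#' @export
read_pose_log <- function(path, frame = NULL, nominal_rate = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  cmt <- grep("^#", lines, value = TRUE)
  fr <- sub("^# *frame: *", "", grep("^# *frame:", cmt, value = TRUE))
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) < 2L) stop("pose log has no data rows")
  if (!identical(trimws(strsplit(body[1], ",")[[1]]), POSE_LOG_HEADER))
    stop("pose log header must be: ", paste(POSE_LOG_HEADER, collapse = ","))
  df <- utils::read.csv(text = body, header = TRUE)
  if (any(!vapply(df, is.numeric, TRUE)) || anyNA(df))
    stop("malformed pose log row(s): non-numeric or missing fields")
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad))
    stop("times must be strictly increasing; first violation at data row ",
         bad[1] + 1L)
  q <- as.matrix(df[, c("qw", "qx", "qy", "qz")])
  norms <- sqrt(rowSums(q^2))
  off <- which(abs(norms - 1) > 1e-3)
  if (length(off))
    stop("quaternion norm deviates from 1 by more than 1e-3 at data row ",
         off[1], " (|q| = ", format(norms[off[1]]), ")")
  q <- q / norms
  frame <- if (length(fr)) fr[1] else frame %||% "tracker"
  if (is.null(nominal_rate))
    nominal_rate <- 1 / stats::median(diff(df$time_s))
  pose_trace(df$time_s, quat_to_rotarray(q),
             as.matrix(df[, c("tx_mm", "ty_mm", "tz_mm")]),
             frame = frame, nominal_rate = nominal_rate, validate = FALSE)
}

#' Write a pose log
#'
#' @param trace a \code{\link{pose_trace}}.
#' @param path output file path.
#' @param seed optional seed recorded in the provenance header.
#' @return \code{path}, invisibly.
#' @export
write_pose_log <- function(trace, path, seed = NULL) {
  stopifnot(inherits(trace, "pose_trace"))
  n <- length(trace$times)
  q <- t(vapply(seq_len(n), function(i) rotmat_to_quat(trace$rot[, , i]),
                numeric(4)))
  rows <- paste(fmt12(trace$times), fmt12(q[, 1]), fmt12(q[, 2]),
                fmt12(q[, 3]), fmt12(q[, 4]), fmt12(trace$trans[, 1]),
                fmt12(trace$trans[, 2]), fmt12(trace$trans[, 3]), sep = ",")
  writeLines(c(provenance_lines(seed),
               sprintf("# frame: %s", trace$frame),
               paste(POSE_LOG_HEADER, collapse = ","), rows), path)
  invisible(path)
}

#' Read a pose log in the 16-column matrix dialect
#'
#' Interoperability reader for logs that store the full 4x4 transform
#' row-major (columns \code{time_s,m00,...,m33}).  The upper-left 3x3
#' block is projected onto the nearest rotation; deviations above 1e-6
#' trigger a warning (the stream was not exactly rigid).
#'
#' @param path file path.
#' @param frame,nominal_rate as in \code{\link{read_pose_log}}.
#' @return A \code{\link{pose_trace}}.
#' @export
read_pose_log_matrix <- function(path, frame = "tracker",
                                 nominal_rate = NULL) {
  df <- utils::read.csv(path, comment.char = "#")
  if (ncol(df) != 17L)
    stop("matrix-dialect pose log needs 17 columns (time_s + 16 row-major)")
  if (anyNA(df)) stop("malformed pose log row(s)")
  n <- nrow(df)
  M <- as.matrix(df[, -1])
  rot <- array(0, c(3, 3, n))
  maxdev <- 0
  for (i in seq_len(n)) {
    m <- matrix(M[i, ], 4, 4, byrow = TRUE)
    R <- m[1:3, 1:3]
    dev <- max(abs(crossprod(R) - diag(3)))
    maxdev <- max(maxdev, dev)
    rot[, , i] <- if (dev > 1e-12) nearest_rotation(R) else R
  }
  if (maxdev > 1e-6)
    warning(sprintf(
      "rotation blocks deviate from orthonormality by up to %.3g; projected",
      maxdev))
  trans <- cbind(M[, 4], M[, 8], M[, 12])
  if (is.null(nominal_rate))
    nominal_rate <- 1 / stats::median(diff(df[[1]]))
  pose_trace(df[[1]], rot, trans, frame = frame,
             nominal_rate = nominal_rate, validate = FALSE)
}

#' Read and write scan schedules (JSON)
#'
#' Schedules are JSON objects with a \code{windows} array (fields
#' \code{label}, \code{start}, \code{end}, \code{modality}) and a
#' \code{reference_label}.  Validation (window ordering, known
#' modalities, non-overlapping MR windows) happens in
#' \code{\link{scan_schedule}}.
#'
#' @param path file path.
#' @return A \code{\link{scan_schedule}}.
#' @export
read_schedule <- function(path) {
  js <- jsonlite::fromJSON(path)
  if (is.null(js$windows)) stop("schedule JSON needs a 'windows' array")
  scan_schedule(js$windows, js$reference_label %||% "MPRAGE")
}

#' @rdname read_schedule
#' @param schedule a \code{\link{scan_schedule}} to serialize.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "scan_schedule"))
  jsonlite::write_json(
    list(windows = schedule$windows,
         reference_label = schedule$reference_label),
    path, auto_unbox = TRUE, digits = 12, pretty = TRUE)
  invisible(path)
}

#' Read and write region-centroid tables (TSV)
#'
#' Tab-separated with header \code{label hemisphere x_mm y_mm z_mm},
#' coordinates in RAS mm, as exported from a segmentation tool.
#'
#' @param path file path.
#' @return A \code{\link{region_centroids}} table.
#' @export
read_centroids <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("label", "hemisphere", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("centroid table needs columns: ", paste(need, collapse = ", "))
  region_centroids(df$label, df$hemisphere, df$x_mm, df$y_mm, df$z_mm)
}

#' @rdname read_centroids
#' @param centroids a \code{\link{region_centroids}} table.
#' @export
write_centroids <- function(centroids, path) {
  stopifnot(inherits(centroids, "region_centroids"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(), con)
  utils::write.table(as.data.frame(centroids), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write a cross-calibration transform (JSON)
#'
#' Stored as a scalar-first unit quaternion plus translation, so the
#' transform is rigid by construction when read back.
#'
#' @param path file path.
#' @return A \code{\link{rigid_transform}}.
#' @export
read_calibration <- function(path) {
  js <- jsonlite::fromJSON(path)
  q <- as.numeric(js$quaternion)
  if (length(q) != 4L || abs(sqrt(sum(q^2)) - 1) > 1e-3)
    stop("calibration quaternion missing or off unit norm")
  q <- q / sqrt(sum(q^2))
  rigid_transform(quat_to_rotarray(matrix(q, 1))[, , 1],
                  as.numeric(js$translation_mm))
}

#' @rdname read_calibration
#' @param transform a \code{\link{rigid_transform}}.
#' @export
write_calibration <- function(transform, path) {
  stopifnot(inherits(transform, "rigid_transform"))
  jsonlite::write_json(
    list(quaternion = rotmat_to_quat(transform$R),
         translation_mm = transform$t),
    path, digits = 12, pretty = TRUE)
  invisible(path)
}

#' Write an analysis report
#'
#' Serializes a metrics / axis / region / comparison table as TSV (with
#' a provenance comment header) or JSON (fixed key order, 12 significant
#' digits), chosen by file extension.
#'
#' @param table a data frame (e.g. \code{cohort_motion()$metrics} or a
#'   \code{\link{cohort_comparisons}} table).
#' @param path output path ending in \code{.tsv} or \code{.json}.
#' @param seed optional seed recorded in the provenance header.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(table, path, seed = NULL) {
  table <- as.data.frame(table)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(provenance = list(
             tool = paste("headmotion",
                          as.character(utils::packageVersion("headmotion"))),
             seed = seed),
           rows = table),
      path, auto_unbox = TRUE, digits = 12, pretty = TRUE, na = "null")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(provenance_lines(seed), con)
    utils::write.table(table, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
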