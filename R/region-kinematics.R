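#' Brain-region centroid tables
#'
#' Region-level kinematics consume a table of region centroids in scanner
#' RAS coordinates (mm), as exported from any segmentation tool.  The
#' canonical set is 8 cortical and 8 subcortical bilateral regions.
#'
#' @param label character vector of unique region labels.
#' @param hemisphere \code{"left"} or \code{"right"} per region.
#' @param x,y,z RAS coordinates, mm.
#' @return A data frame of class \code{"region_centroids"} with columns
#'   \code{label}, \code{hemisphere}, \code{x_mm}, \code{y_mm},
#'   \code{z_mm}.
#' @export
region_centroids <- function(label, hemisphere, x, y, z) {
  if (anyDuplicated(label)) stop("region labels must be unique")
  if (any(!hemisphere %in% c("left", "right")))
    stop("hemisphere must be 'left' or 'right'")
  if (!all(is.finite(c(x, y, z)))) stop("non-finite centroid coordinates")
  structure(data.frame(label = as.character(label),
                       hemisphere = as.character(hemisphere),
                       x_mm = as.numeric(x), y_mm = as.numeric(y),
                       z_mm = as.numeric(z)),
            class = c("region_centroids", "data.frame"))
}

#' Default synthetic region-centroid table
#'
#' The 16 canonical bilateral regions (hippocampus, caudate, amygdala,
#' putamen, lateral occipital, inferior temporal, precentral, medial
#' orbitofrontal) with synthetic placeholder coordinates at roughly
#' anatomically plausible RAS positions.  These are stand-in coordinates
#' for testing and simulation, not measurements from any subject.
#'
#' @return A \code{\link{region_centroids}} table with 16 rows.
#' @export
default_region_centroids <- function() {
  base <- data.frame(
    region = c("Hippocampus", "Caudate", "Amygdala", "Putamen",
               "Lateral-Occipital", "Inferior-Temporal", "Precentral",
               "Medial-Orbitofrontal"),
    x = c(28, 13, 24, 26, 32, 50, 38, 7),
    y = c(-22, 12, -4, 2, -86, -30, -12, 36),
    z = c(-14, 12, -20, 2, 6, -26, 52, -14))
  out <- do.call(rbind, lapply(c("Left", "Right"), function(h) {
    data.frame(label = paste0(h, "-", base$region),
               hemisphere = tolower(h),
               x = if (h == "Left") -base$x else base$x,
               y = base$y, z = base$z)
  }))
  region_centroids(out$label, out$hemisphere, out$x, out$y, out$z)
}

#' Propagate head motion to region centroids
#'
#' Applies every reference-relative transform to each region centroid and
#' returns the signed displacement vector
#' \code{Delta(t) = R_t c + t_t - c} (mm) per region and time point.
#' Pure translations move every region identically; rotations displace a
#' region in proportion to its distance from the rotation axis.
#'
#' @param rel_trace a reference-relative \code{pose_trace} in the RAS
#'   frame.
#' @param centroids a \code{\link{region_centroids}} table (RAS mm).
#' @return An object of class \code{"region_displacements"}: a named list
#'   of n x 3 matrices (columns dx, dy, dz in mm), one per region, with
#'   the sample times as attribute \code{times}.
#' @export
propagate <- function(rel_trace, centroids) {
  stopifnot(inherits(rel_trace, "pose_trace"),
            inherits(centroids, "region_centroids"))
  if (!identical(rel_trace$frame, "RAS"))
    stop("trace must be in the RAS frame to match centroid coordinates ",
         "(apply change_frame with the cross-calibration transform first)")
  out <- lapply(seq_len(nrow(centroids)), function(i) {
    p <- c(centroids$x_mm[i], centroids$y_mm[i], centroids$z_mm[i])
    pos <- rotarray_apply(rel_trace$rot, rel_trace$trans, p)
    delta <- pos - matrix(p, nrow(pos), 3, byrow = TRUE)
    colnames(delta) <- c("dx", "dy", "dz")
    delta
  })
  names(out) <- centroids$label
  structure(out, class = "region_displacements",
            times = rel_trace$times,
            nominal_rate = rel_trace$nominal_rate)
}

#' @export
print.region_displacements <- function(x, ...) {
  cat(sprintf("Region displacements: %d regions x %d time points\n",
              length(x), length(attr(x, "times"))))
  invisible(x)
}

#' Per-axis displacement summaries by region
#'
#' For each region and axis, the median over time of the absolute per-axis
#' displacement component (mm); signed medians are emitted alongside for
#' directionality.
#'
#' @param displacements a \code{\link{propagate}} result.
#' @return A data frame of class \code{"region_axis_summary"}: one row per
#'   region x axis with \code{median_abs_disp_mm} and
#'   \code{median_signed_disp_mm}.
#' @export
region_axis_summary <- function(displacements) {
  stopifnot(inherits(displacements, "region_displacements"))
  out <- do.call(rbind, lapply(names(displacements), function(lab) {
    d <- displacements[[lab]]
    data.frame(label = lab, axis = c("x", "y", "z"),
               median_abs_disp_mm = apply(abs(d), 2, stats::median),
               median_signed_disp_mm = apply(d, 2, stats::median))
  }))
  rownames(out) <- NULL
  structure(out, class = c("region_axis_summary", "data.frame"))
}

#' Displacement metrics per region
#'
#' Feeds the Euclidean norm of each region's displacement vectors through
#' \code{\link{motion_summary}}, yielding the four motion metrics per
#' region.
#'
#' @param displacements a \code{\link{propagate}} result.
#' @param threshold_mm motion-free threshold, mm.
#' @return A data frame, one row per region, with the
#'   \code{patient_metrics} columns plus \code{label}.
#' @export
region_metrics <- function(displacements, threshold_mm = 2.0) {
  stopifnot(inherits(displacements, "region_displacements"))
  times <- attr(displacements, "times")
  rate <- attr(displacements, "nominal_rate")
  out <- do.call(rbind, lapply(names(displacements), function(lab) {
    d <- displacements[[lab]]
    ser <- structure(
      data.frame(time = times, displacement = sqrt(rowSums(d^2))),
      class = c("displacement_series", "data.frame"),
      point_label = lab, nominal_rate = rate, referenced = TRUE)
    m <- motion_summary(ser, threshold_mm)
    cbind(label = lab, as.data.frame(m))
  }))
  rownames(out) <- NULL
  out
}
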