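#' Displacement of a tracked point over time
#'
#' For a reference-relative trace, the displacement at time t is the
#' Euclidean distance (mm) between the point's position under the pose at
#' t and its reference position:
#' \code{d(t) = || R_t p + t_t - p ||}.  The tracked point is typically
#' the facial point-cloud centroid (close to the nose bridge) or a brain
#' region centroid.
#'
#' @param rel_trace a reference-relative \code{pose_trace} (contains an
#'   identity sample at the reference time).  If no sample is the
#'   identity the series is computed anyway and flagged via the
#'   \code{referenced} attribute (with a warning).
#' @param point numeric 3-vector, mm, in the trace's frame.
#' @param point_label label stored with the series.
#' @return A data frame of class \code{"displacement_series"} with columns
#'   \code{time} (s) and \code{displacement} (mm), the point label and the
#'   nominal sampling rate as attributes.
#' @export
displacement_series <- function(rel_trace, point,
                                point_label = "centroid") {
  stopifnot(inherits(rel_trace, "pose_trace"))
  point <- as.numeric(point)
  if (length(point) != 3L || !all(is.finite(point)))
    stop("point must be a finite 3-vector")
  pos <- rotarray_apply(rel_trace$rot, rel_trace$trans, point)
  d <- sqrt((pos[, 1] - point[1])^2 + (pos[, 2] - point[2])^2 +
              (pos[, 3] - point[3])^2)
  referenced <- any(d < 1e-9)
  if (!referenced)
    warning("trace does not contain an identity (reference) sample; ",
            "displacements are not relative to a reference pose")
  structure(data.frame(time = rel_trace$times, displacement = d),
            class = c("displacement_series", "data.frame"),
            point_label = point_label,
            nominal_rate = rel_trace$nominal_rate,
            referenced = referenced)
}

#' Summary metrics of a displacement series
#'
#' Computes the four per-patient motion metrics: mean, median and maximum
#' displacement (mm) and the motion-free fraction -- the fraction of scan
#' time during which displacement stays strictly below the threshold
#' (default 2 mm, a standard motion-thresholding value).
#'
#' Because masking to acquisition windows leaves unevenly spaced samples,
#' the motion-free fraction is time-weighted: each sample is weighted by
#' the gap to the next sample, capped at twice the nominal sampling
#' interval so that untracked gaps between windows carry no evidence.
#' Under uniform sampling this reduces to the plain sample count.
#'
#' @param series a \code{\link{displacement_series}}.
#' @param threshold_mm motion-free threshold, mm (strict inequality
#'   \code{d < threshold}).
#' @return An object of class \code{"patient_metrics"}: a one-row data
#'   frame with \code{n_samples}, \code{mean_disp_mm},
#'   \code{median_disp_mm}, \code{max_disp_mm}, \code{motion_free_frac}
#'   and \code{threshold_mm}.
#' @examples
#' tr <- pose_trace(0:3, array(diag(3), c(3, 3, 4)),
#'                  cbind(0, 0, c(0, 1, 3, 3)), nominal_rate = 1)
#' motion_summary(displacement_series(tr, c(0, 0, 0)))
#' @export
motion_summary <- function(series, threshold_mm = 2.0) {
  stopifnot(inherits(series, "displacement_series"))
  d <- series$displacement
  if (length(d) == 0L) stop("empty displacement series")
  w <- sample_weights(series$time, attr(series, "nominal_rate"))
  out <- data.frame(n_samples = length(d),
                    mean_disp_mm = mean(d),
                    median_disp_mm = stats::median(d),
                    max_disp_mm = max(d),
                    motion_free_frac = sum(w[d < threshold_mm]) / sum(w),
                    threshold_mm = threshold_mm)
  structure(out, class = c("patient_metrics", "data.frame"),
            point_label = attr(series, "point_label"))
}

# time weights: following inter-sample gap, capped at 2x the nominal
# interval; the last sample gets one nominal interval.
sample_weights <- function(times, nominal_rate) {
  dt <- if (is.null(nominal_rate) || !is.finite(nominal_rate)) {
    stats::median(diff(times))
  } else 1 / nominal_rate
  if (length(times) == 1L) return(1)
  gaps <- c(diff(times), dt)
  pmin(gaps, 2 * dt)
}

#' @export
print.patient_metrics <- function(x, ...) {
  cat(sprintf(
    "Motion metrics (%s): mean %.3f / median %.3f / max %.3f mm; motion-free %.1f%% (< %g mm)\n",
    attr(x, "point_label") %||% "point", x$mean_disp_mm, x$median_disp_mm,
    x$max_disp_mm, 100 * x$motion_free_frac, x$threshold_mm))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-axis component summaries of a trace
#'
#' Decomposes every sample of a reference-relative trace into the six
#' motion parameters and summarizes each translation (mm) and rotation
#' (deg) component per axis: the summary of absolute values (magnitude of
#' motion along/about the axis) and of signed values (net direction, e.g.
#' drift out of the scanner bore shows as negative z translation).
#'
#' @param rel_trace a reference-relative \code{pose_trace}.
#' @param stat summary statistic over time, \code{"mean"} (default) or
#'   \code{"median"}.
#' @return A data frame of class \code{"axis_summary"} with columns
#'   \code{channel} (\code{translation}/\code{rotation}), \code{axis},
#'   \code{mean_abs} and \code{mean_signed} (mm or deg).
#' @export
axis_summaries <- function(rel_trace, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  f <- if (stat == "mean") mean else stats::median
  mp <- motion_params(rel_trace)
  comp <- list(translation = mp[c("t_x", "t_y", "t_z")],
               rotation = mp[c("r_x", "r_y", "r_z")])
  out <- do.call(rbind, lapply(names(comp), function(ch) {
    v <- comp[[ch]]
    data.frame(channel = ch, axis = c("x", "y", "z"),
               mean_abs = vapply(v, function(col) f(abs(col)), 0),
               mean_signed = vapply(v, f, 0))
  }))
  rownames(out) <- NULL
  structure(out, class = c("axis_summary", "data.frame"), stat = stat)
}
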