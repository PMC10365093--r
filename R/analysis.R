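#' Per-patient motion analysis
#'
#' The main per-patient entry point: runs the full quantification chain
#' on one pose trace.  The trace is (optionally) moved into the scanner
#' RAS frame with a cross-calibration transform, masked to the MR
#' acquisition windows, re-referenced to the temporal midpoint of the
#' reference sequence, and summarized into displacement metrics for the
#' tracked point, per-axis translation/rotation components, and
#' (optionally) region-level displacements.
#'
#' @param trace a \code{\link{pose_trace}}.
#' @param schedule a \code{\link{scan_schedule}}.
#' @param point tracked point for patient-level metrics, RAS mm.  The
#'   default (0, 100, -20) stands in for the facial point-cloud centroid
#'   near the nose bridge (an anterior-inferior point).
#' @param threshold_mm motion-free threshold, mm.
#' @param calibration optional cross-calibration
#'   \code{\link{rigid_transform}} applied (by conjugation) when the
#'   trace is not yet in RAS.
#' @param centroids optional \code{\link{region_centroids}}; when given,
#'   region-level displacements and metrics are computed as well.
#' @param stat time-summary statistic for axis components
#'   (\code{"mean"} or \code{"median"}).
#' @param keep_series keep the displacement series and the
#'   reference-relative trace in the result (needed for plotting).
#' @return An object of class \code{"patient_motion"} with components
#'   \code{metrics} (\code{patient_metrics}), \code{axes}
#'   (\code{axis_summary}), \code{region_axes}, \code{region_metrics}
#'   (when centroids are given), \code{reference_time}, \code{n_samples}
#'   and optionally \code{series}.
#' @examples
#' sim <- simulate_trace(awake_profile(seed = 7), default_schedule(),
#'                       rate_hz = 2)
#' fit <- patient_motion(sim$trace, default_schedule())
#' fit
#' @export
patient_motion <- function(trace, schedule,
                           point = c(0, 100, -20), threshold_mm = 2.0,
                           calibration = NULL, centroids = NULL,
                           stat = "mean", keep_series = FALSE) {
  stopifnot(inherits(trace, "pose_trace"), inherits(schedule, "scan_schedule"))
  if (!is.null(calibration) && !identical(trace$frame, "RAS"))
    trace <- change_frame(trace, calibration, to = "RAS")
  masked <- mask_to_windows(trace, schedule, "MR")
  t_ref <- select_reference_time(masked, schedule)
  rel <- relative_to_reference(masked, t_ref)
  series <- displacement_series(rel, point)
  out <- list(metrics = motion_summary(series, threshold_mm),
              axes = axis_summaries(rel, stat),
              reference_time = t_ref,
              n_samples = length(rel$times),
              point = point)
  if (!is.null(centroids)) {
    disp <- propagate(rel, centroids)
    out$region_axes <- region_axis_summary(disp)
    out$region_metrics <- region_metrics(disp, threshold_mm)
  }
  if (keep_series) {
    out$series <- series
    out$rel_trace <- rel
  }
  structure(out, class = "patient_motion")
}

#' @export
print.patient_motion <- function(x, ...) {
  cat(sprintf("Head-motion analysis: %d MR samples, reference at %.1f s\n",
              x$n_samples, x$reference_time))
  print(x$metrics)
  invisible(x)
}

#' @export
summary.patient_motion <- function(object, ...) {
  print(object)
  cat("\nPer-axis components (", attr(object$axes, "stat"),
      " over time):\n", sep = "")
  print(as.data.frame(object$axes), row.names = FALSE)
  if (!is.null(object$region_metrics)) {
    cat("\nRegion metrics (first rows):\n")
    print(utils::head(object$region_metrics, 4), row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.patient_motion <- function(x, ...) {
  if (is.null(x$series))
    stop("re-run patient_motion() with keep_series = TRUE to plot")
  plot(x$series$time, x$series$displacement, type = "l",
       xlab = "time (s)", ylab = "displacement (mm)",
       main = "Displacement relative to reference", ...)
  graphics::abline(h = x$metrics$threshold_mm, lty = 2, col = "grey40")
  graphics::abline(v = x$reference_time, lty = 3, col = "steelblue")
  invisible(x)
}

#' Cohort-level motion tables
#'
#' Runs \code{\link{patient_motion}} for every patient of a (simulated
#' or assembled) cohort and stacks the results into the long tables
#' consumed by \code{\link{cohort_comparisons}}.
#'
#' @param cohort a \code{\link{make_cohort}} result, or any list whose
#'   elements have \code{patient_id}, \code{group} and \code{trace}.
#' @param schedule a \code{\link{scan_schedule}} (defaults to the
#'   cohort's own schedule when present).
#' @param ... passed to \code{\link{patient_motion}}.
#' @return An object of class \code{"cohort_motion"}: a list with
#'   \code{metrics} (one row per patient), \code{axes} (patient x channel
#'   x axis) and, when centroids were given, \code{regions} (patient x
#'   region x axis).
#' @export
cohort_motion <- function(cohort, schedule = attr(cohort, "schedule"), ...) {
  if (is.null(schedule)) stop("a scan schedule is required")
  res <- lapply(cohort, function(p) {
    fit <- patient_motion(p$trace, schedule, ...)
    met <- cbind(patient_id = p$patient_id, group = p$group,
                 point_label = attr(fit$metrics, "point_label") %||% "centroid",
                 as.data.frame(fit$metrics))
    axes <- cbind(patient_id = p$patient_id, group = p$group,
                  as.data.frame(fit$axes))
    regs <- if (!is.null(fit$region_axes))
      cbind(patient_id = p$patient_id, group = p$group,
            as.data.frame(fit$region_axes))
    list(met = met, axes = axes, regs = regs)
  })
  out <- list(metrics = do.call(rbind, lapply(res, `[[`, "met")),
              axes = do.call(rbind, lapply(res, `[[`, "axes")))
  regs <- lapply(res, `[[`, "regs")
  if (!is.null(regs[[1]])) out$regions <- do.call(rbind, regs)
  structure(out, class = "cohort_motion")
}

#' @export
print.cohort_motion <- function(x, ...) {
  cat(sprintf("Cohort motion tables: %d patients (%s)\n",
              nrow(x$metrics),
              paste(sprintf("%s n=%d", names(table(x$metrics$group)),
                            as.integer(table(x$metrics$group))),
                    collapse = ", ")))
  for (g in unique(x$metrics$group)) {
    cs <- cohort_summary(x$metrics$mean_disp_mm[x$metrics$group == g])
    cat(sprintf("  %s mean displacement: %.2f ± %.2f mm (median ± SD)\n",
                g, cs$median, cs$sd))
  }
  invisible(x)
}
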