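#' Pose traces
#'
#' A pose trace is a time-ordered stream of rigid-body transforms of the
#' head relative to a tracker or scanner frame, as produced by a markerless
#' tracking device at roughly 30 Hz.  Rotations are held as a 3x3xn array
#' and translations as an n x 3 matrix (mm); times are seconds from
#' session start and strictly increasing.
#'
#' @param times numeric vector of sample times, seconds, strictly
#'   increasing.
#' @param rotations 3x3xn array of rotation matrices, or a list of 3x3
#'   matrices.
#' @param translations n x 3 matrix of translations (mm).
#' @param frame frame tag, one of \code{"tracker"} or \code{"RAS"}.
#' @param nominal_rate nominal sampling rate in Hz (used only to weight
#'   motion-free time over uneven gaps).
#' @param validate check rotation orthonormality on every sample (on by
#'   default; the simulator constructs rotations from unit quaternions and
#'   skips the per-sample check).
#' @return An object of class \code{"pose_trace"}.
#' @export
pose_trace <- function(times, rotations, translations, frame = "tracker",
                       nominal_rate = 30, validate = TRUE) {
  times <- as.numeric(times)
  n <- length(times)
  if (n < 1L) stop("a pose trace needs at least one sample")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (is.list(rotations))
    rotations <- array(unlist(rotations), c(3, 3, n))
  translations <- matrix(as.numeric(translations), ncol = 3)
  if (!identical(dim(rotations), c(3L, 3L, n)) && !all(dim(rotations) == c(3, 3, n)))
    stop("rotations must be 3x3x", n)
  if (nrow(translations) != n)
    stop("translations must have one row per sample")
  frame <- match.arg(frame, c("tracker", "RAS"))
  if (validate) {
    for (i in seq_len(n)) assert_rotation(rotations[, , i])
  }
  structure(list(times = times, rot = rotations, trans = translations,
                 frame = frame, nominal_rate = nominal_rate),
            class = "pose_trace")
}

#' @export
length.pose_trace <- function(x) length(x$times)

#' Extract one sample of a pose trace as a rigid transform
#' @param trace a \code{pose_trace}.
#' @param i sample index.
#' @return A \code{rigid_transform}.
#' @export
trace_transform <- function(trace, i) {
  rigid_transform(trace$rot[, , i], trace$trans[i, ])
}

# subset a trace by sample index, preserving metadata
trace_subset <- function(trace, idx) {
  structure(list(times = trace$times[idx],
                 rot = trace$rot[, , idx, drop = FALSE],
                 trans = trace$trans[idx, , drop = FALSE],
                 frame = trace$frame, nominal_rate = trace$nominal_rate),
            class = "pose_trace")
}

#' @export
print.pose_trace <- function(x, ...) {
  cat(sprintf("Pose trace: %d samples, %.1f-%.1f s, frame '%s', ~%g Hz\n",
              length(x$times), min(x$times), max(x$times), x$frame,
              x$nominal_rate))
  invisible(x)
}

#' Scan schedules
#'
#' The acquisition timeline of an examination: labelled windows with start
#' and end times (seconds) and a modality (\code{MR}, \code{PET} or
#' \code{dead}).  Motion analysis is restricted to the MR windows; the
#' reference pose is taken at the temporal midpoint of the window named by
#' \code{reference_label} (the structural sequence whose centre of k-space
#' is most motion-sensitive).
#'
#' @param windows data frame with columns \code{label}, \code{start},
#'   \code{end} (s) and \code{modality}.
#' @param reference_label label of the reference sequence window.
#' @return An object of class \code{"scan_schedule"}.
#' @export
scan_schedule <- function(windows, reference_label = "MPRAGE") {
  windows <- as.data.frame(windows, stringsAsFactors = FALSE)
  need <- c("label", "start", "end", "modality")
  if (!all(need %in% names(windows)))
    stop("schedule windows need columns: ", paste(need, collapse = ", "))
  if (any(!windows$modality %in% c("MR", "PET", "dead")))
    stop("unknown modality; must be MR, PET or dead")
  if (any(windows$end <= windows$start))
    stop("every window needs start < end")
  mr <- windows[windows$modality == "MR", , drop = FALSE]
  if (nrow(mr) > 1L) {
    o <- order(mr$start)
    if (any(mr$start[o][-1] < mr$end[o][-nrow(mr)]))
      stop("MR windows must not overlap")
  }
  structure(list(windows = windows, reference_label = reference_label),
            class = "scan_schedule")
}

#' @export
print.scan_schedule <- function(x, ...) {
  cat(sprintf("Scan schedule: %d windows (%d MR), reference '%s'\n",
              nrow(x$windows), sum(x$windows$modality == "MR"),
              x$reference_label))
  print(x$windows, row.names = FALSE)
  invisible(x)
}

#' Mask a pose trace to scheduled acquisition windows
#'
#' Retains the samples whose time falls inside any window of the requested
#' modality (closed intervals), in original order.  Motion recorded during
#' dead time or other modalities is discarded before computing metrics.
#'
#' @param trace a \code{pose_trace}.
#' @param schedule a \code{scan_schedule}.
#' @param modality which windows to keep (default \code{"MR"}).
#' @return The masked \code{pose_trace}.
#' @export
mask_to_windows <- function(trace, schedule, modality = "MR") {
  stopifnot(inherits(trace, "pose_trace"), inherits(schedule, "scan_schedule"))
  w <- schedule$windows[schedule$windows$modality == modality, , drop = FALSE]
  if (nrow(w) == 0L)
    stop("schedule has no windows of modality '", modality, "'")
  keep <- rep(FALSE, length(trace$times))
  for (i in seq_len(nrow(w)))
    keep <- keep | (trace$times >= w$start[i] & trace$times <= w$end[i])
  if (!any(keep)) stop("no samples in selected windows")
  trace_subset(trace, which(keep))
}

#' Select the reference time of a trace
#'
#' Returns the trace timestamp nearest the temporal midpoint
#' \code{(start + end) / 2} of the schedule's reference window (ties go to
#' the earlier sample).  The midpoint of the structural sequence is used
#' because it corresponds to the acquisition of the centre of k-space.
#'
#' @param trace a \code{pose_trace}.
#' @param schedule a \code{scan_schedule} whose \code{reference_label}
#'   names one of its windows.
#' @return Reference time in seconds.
#' @export
select_reference_time <- function(trace, schedule) {
  stopifnot(inherits(trace, "pose_trace"), inherits(schedule, "scan_schedule"))
  w <- schedule$windows[schedule$windows$label == schedule$reference_label, ,
                        drop = FALSE]
  if (nrow(w) == 0L)
    stop("reference window '", schedule$reference_label,
         "' not found in schedule")
  mid <- (w$start[1] + w$end[1]) / 2
  trace$times[nearest_sample(trace$times, mid)]
}

# index of the sample nearest t; ties resolved to the earlier sample
nearest_sample <- function(times, t) {
  d <- abs(times - t)
  which(d <= min(d))[1]
}

#' Re-reference a pose trace
#'
#' Expresses every pose relative to the pose at the reference time: each
#' output transform is \code{T_t o T_ref^-1}, i.e. the motion of the head
#' in the fixed scanner frame since the reference instant.  The sample
#' nearest \code{t_ref} maps to the identity exactly, so displacement at
#' the reference time is zero by construction.  Re-referencing an already
#' referenced trace at the same instant is the identity.
#'
#' @param trace a \code{pose_trace}.
#' @param t_ref reference time (s), within the trace's time span; usually
#'   from \code{\link{select_reference_time}}.
#' @return The reference-relative \code{pose_trace}.
#' @export
relative_to_reference <- function(trace, t_ref) {
  stopifnot(inherits(trace, "pose_trace"))
  if (length(trace$times) == 0L) stop("empty trace")
  if (t_ref < min(trace$times) || t_ref > max(trace$times))
    stop("t_ref outside the trace time span")
  i0 <- nearest_sample(trace$times, t_ref)
  Rref <- trace$rot[, , i0]
  tref <- trace$trans[i0, ]
  Q <- t(Rref)                        # Rref^-1
  Rrel <- rotarray_multiply_fixed(trace$rot, Q, "right")
  # t_rel = t_t - Rrel %*% tref
  trel <- trace$trans - rotarray_apply(Rrel, matrix(0, nrow(trace$trans), 3),
                                       tref)
  Rrel[, , i0] <- diag(3)
  trel[i0, ] <- 0
  structure(list(times = trace$times, rot = Rrel, trans = trel,
                 frame = trace$frame, nominal_rate = trace$nominal_rate,
                 reference_time = trace$times[i0]),
            class = "pose_trace")
}

#' Move a pose trace into another coordinate frame
#'
#' Applies a fixed cross-calibration transform \code{C} (e.g. tracker to
#' scanner RAS) by conjugation: each pose becomes
#' \code{C o T o C^-1}, which is the same physical motion expressed in the
#' new frame.  Displacement metrics are invariant under this operation.
#'
#' @param trace a \code{pose_trace}.
#' @param C the cross-calibration \code{rigid_transform} mapping the
#'   current frame into \code{to}.
#' @param to target frame tag (default \code{"RAS"}).
#' @return The re-framed \code{pose_trace}.
#' @export
change_frame <- function(trace, C, to = "RAS") {
  stopifnot(inherits(trace, "pose_trace"), inherits(C, "rigid_transform"))
  to <- match.arg(to, c("tracker", "RAS"))
  if (identical(trace$frame, to))
    stop("trace is already in frame '", to, "'")
  Rc <- C$R; tc <- C$t
  Rp <- rotarray_multiply_fixed(
    rotarray_multiply_fixed(trace$rot, t(Rc), "right"), Rc, "left")
  # t' = Rc t + tc - R' tc
  zero <- matrix(0, nrow(trace$trans), 3)
  tp <- quat_fixed_rotate(Rc, trace$trans) +
    matrix(tc, nrow(trace$trans), 3, byrow = TRUE) -
    rotarray_apply(Rp, zero, tc)
  out <- trace
  out$rot <- Rp
  out$trans <- tp
  out$frame <- to
  out
}

# rotate all rows of v (n x 3) by one fixed rotation matrix
quat_fixed_rotate <- function(R, v) v %*% t(R)

#' Decompose every sample of a trace into motion parameters
#'
#' @param x a \code{pose_trace} (usually reference-relative).
#' @param ... unused.
#' @return A data frame with one row per sample: \code{time}, translations
#'   \code{t_x, t_y, t_z} (mm), Tait-Bryan angles \code{r_x, r_y, r_z}
#'   (deg, factorization \code{Rz Ry Rx}) and \code{gimbal_lock}.
#' @export
motion_params.pose_trace <- function(x, ...) {
  ang <- rotarray_to_zyx_angles(x$rot)
  data.frame(time = x$times,
             t_x = x$trans[, 1], t_y = x$trans[, 2], t_z = x$trans[, 3],
             r_x = ang[, 1], r_y = ang[, 2], r_z = ang[, 3],
             gimbal_lock = attr(ang, "gimbal_lock"))
}
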