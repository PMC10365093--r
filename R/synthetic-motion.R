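#' Synthetic motion profiles
#'
#' A motion profile parameterizes the four stochastic processes the
#' generator superimposes to emulate paediatric head motion during a
#' scan session:
#' \describe{
#'   \item{drift}{slow, deterministic translation, predominantly along
#'     -z (out of the scanner bore); linear or saturating in time;}
#'   \item{nodding}{transient rotation pulses about the left-right (x)
#'     axis at Poisson onsets (raised-cosine shape);}
#'   \item{spikes}{brief, large translation pulses in a random direction
#'     (e.g. a sudden jerk), also Poisson;}
#'   \item{jitter}{AR(1) sensor/physiological noise on all six motion
#'     parameters.}
#' }
#' Event amplitudes are drawn from lognormal distributions matching the
#' stated mean and sd (guaranteeing positivity).
#'
#' @param drift_rate length-3 numeric, mm/min along x, y, z (default
#'   direction -z).
#' @param drift_shape \code{"linear"} or \code{"saturating"}.
#' @param drift_tau_min time constant (minutes) of the saturating drift.
#' @param nod_rate nodding events per minute.
#' @param nod_amplitude_deg,nod_amplitude_sd_deg mean and sd of the nod
#'   amplitude (degrees about x).
#' @param nod_duration_s duration of one nod pulse, seconds.
#' @param spike_rate displacement spikes per minute.
#' @param spike_amplitude_mm,spike_amplitude_sd_mm mean and sd of spike
#'   amplitude, mm.
#' @param spike_duration_s duration of one spike pulse, seconds.
#' @param jitter_sd_trans_mm,jitter_sd_rot_deg stationary sd of the AR(1)
#'   jitter on translations (mm) and rotations (deg).
#' @param jitter_ar1 AR(1) coefficient in [0, 1).
#' @param seed integer RNG seed for the trace.
#' @return An object of class \code{"motion_profile"} (a list).
#' @export
motion_profile <- function(drift_rate = c(0, 0, 0),
                           drift_shape = c("linear", "saturating"),
                           drift_tau_min = 20,
                           nod_rate = 0,
                           nod_amplitude_deg = 0.5,
                           nod_amplitude_sd_deg = 0.3,
                           nod_duration_s = 3,
                           spike_rate = 0,
                           spike_amplitude_mm = 2,
                           spike_amplitude_sd_mm = 1,
                           spike_duration_s = 2,
                           jitter_sd_trans_mm = 0,
                           jitter_sd_rot_deg = 0,
                           jitter_ar1 = 0.9,
                           seed = 1L) {
  drift_shape <- match.arg(drift_shape)
  stopifnot(length(drift_rate) == 3L,
            nod_rate >= 0, spike_rate >= 0,
            nod_amplitude_sd_deg >= 0, spike_amplitude_sd_mm >= 0,
            jitter_sd_trans_mm >= 0, jitter_sd_rot_deg >= 0,
            jitter_ar1 >= 0, jitter_ar1 < 1,
            drift_tau_min > 0, nod_duration_s > 0, spike_duration_s > 0)
  structure(as.list(environment()), class = "motion_profile")
}

#' Default cohort profiles
#'
#' Calibration defaults for the two study conditions: anaesthetised
#' patients (\code{ga_profile}) show slow saturating drift and almost no
#' events; awake patients (\code{awake_profile}) show faster linear
#' drift plus nodding and displacement spikes.  These are simulation
#' calibration choices, not measurements.
#'
#' @param seed RNG seed stored in the profile.
#' @return A \code{\link{motion_profile}}.
#' @export
ga_profile <- function(seed = 1L) {
  motion_profile(drift_rate = c(0, 0, -0.05), drift_shape = "saturating",
                 drift_tau_min = 20, nod_rate = 0,
                 spike_rate = 0.02, spike_amplitude_mm = 2,
                 spike_amplitude_sd_mm = 1,
                 jitter_sd_trans_mm = 0.02, jitter_sd_rot_deg = 0.01,
                 seed = seed)
}

#' @rdname ga_profile
#' @export
awake_profile <- function(seed = 1L) {
  motion_profile(drift_rate = c(0, 0, -0.08), drift_shape = "linear",
                 nod_rate = 0.5, nod_amplitude_deg = 0.5,
                 nod_amplitude_sd_deg = 0.3,
                 spike_rate = 0.2, spike_amplitude_mm = 2,
                 spike_amplitude_sd_mm = 1,
                 jitter_sd_trans_mm = 0.05, jitter_sd_rot_deg = 0.03,
                 seed = seed)
}

#' Default synthetic scan schedule
#'
#' Five MR sequence windows with standard structural-protocol durations
#' (MPRAGE 266 s, STIR 174 s, transversal FLAIR 272 s, coronal FLAIR
#' 164 s, Blade 122 s; 998 s of MR time in total), interleaved with PET
#' and dead-time gaps so that the wall time from the start of the first
#' to the end of the last MR sequence is 41.7 min.  The MPRAGE window is
#' flagged as the reference sequence.
#'
#' @return A \code{\link{scan_schedule}}.
#' @export
default_schedule <- function() {
  mr_labels <- c("MPRAGE", "STIR", "FLAIR-tra", "FLAIR-cor", "BLADE")
  mr_dur <- c(266, 174, 272, 164, 122)
  wall <- 41.7 * 60
  gap <- (wall - sum(mr_dur)) / 4
  start <- cumsum(c(0, utils::head(mr_dur, -1) + gap))
  win <- data.frame(label = mr_labels, start = start,
                    end = start + mr_dur, modality = "MR")
  gaps <- data.frame(label = paste0("gap", 1:4),
                     start = win$end[1:4], end = win$start[2:5],
                     modality = c("PET", "dead", "PET", "dead"))
  scan_schedule(rbind(win, gaps), reference_label = "MPRAGE")
}

# lognormal meanlog/sdlog matching a target mean m > 0 and sd s >= 0
lnorm_params <- function(m, s) {
  if (m <= 0) return(NULL)
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

rlnorm_ms <- function(n, m, s) {
  p <- lnorm_params(m, s)
  if (is.null(p)) return(rep(0, n))
  stats::rlnorm(n, p$meanlog, p$sdlog)
}

# raised-cosine pulse of unit peak on [onset, onset + duration]
pulse_shape <- function(times, onset, duration) {
  u <- (times - onset) / duration
  ifelse(u >= 0 & u <= 1, 0.5 * (1 - cos(2 * pi * u)), 0)
}

#' Simulate a pose trace
#'
#' Generates one patient's head-motion trace over the full session span
#' of a schedule.  The pose at time t composes the four processes in the
#' fixed order drift, nod, spike, jitter
#' (\code{T = T_drift o T_nod o T_spike o T_jitter}); rotations are
#' composed through unit quaternions so every generated transform is
#' rigid by construction.  The generator is fully reproducible from the
#' profile's seed.
#'
#' @param profile a \code{\link{motion_profile}}.
#' @param schedule a \code{\link{scan_schedule}} defining the session
#'   span.
#' @param rate_hz sampling rate (default 30, the tracking device's
#'   nominal rate).
#' @param frame frame tag given to the generated trace (default
#'   \code{"RAS"}).
#' @return A list with elements \code{trace} (a \code{pose_trace}) and
#'   \code{truth} (ground truth: the event log, the per-sample drift and
#'   the profile used).
#' @export
simulate_trace <- function(profile, schedule, rate_hz = 30,
                           frame = "RAS") {
  stopifnot(inherits(profile, "motion_profile"),
            inherits(schedule, "scan_schedule"))
  session_end <- max(schedule$windows$end)
  if (session_end <= 0) stop("schedule has no positive duration")
  set.seed(as.integer(profile$seed))
  times <- seq(0, session_end, by = 1 / rate_hz)
  n <- length(times)
  dur_min <- session_end / 60

  ## drift (deterministic translation)
  shape <- switch(profile$drift_shape,
                  linear = times / 60,
                  saturating = profile$drift_tau_min *
                    (1 - exp(-times / (60 * profile$drift_tau_min))))
  drift <- outer(shape, profile$drift_rate)

  ## nodding rotation pulses about x
  events <- data.frame(type = character(0), onset = numeric(0),
                       duration = numeric(0), amplitude = numeric(0))
  theta <- numeric(n)
  n_nod <- stats::rpois(1, profile$nod_rate * dur_min)
  if (n_nod > 0) {
    onset <- stats::runif(n_nod, 0, max(session_end - profile$nod_duration_s, 0))
    amp <- rlnorm_ms(n_nod, profile$nod_amplitude_deg,
                     profile$nod_amplitude_sd_deg)
    for (k in seq_len(n_nod))
      theta <- theta + amp[k] * pulse_shape(times, onset[k],
                                            profile$nod_duration_s)
    events <- rbind(events, data.frame(type = "nod", onset = onset,
                                       duration = profile$nod_duration_s,
                                       amplitude = amp))
  }

  ## translation spikes in random directions
  spike <- matrix(0, n, 3)
  n_spk <- stats::rpois(1, profile$spike_rate * dur_min)
  if (n_spk > 0) {
    onset <- stats::runif(n_spk, 0, max(session_end - profile$spike_duration_s, 0))
    amp <- rlnorm_ms(n_spk, profile$spike_amplitude_mm,
                     profile$spike_amplitude_sd_mm)
    dir <- matrix(stats::rnorm(3 * n_spk), n_spk, 3)
    dir <- dir / sqrt(rowSums(dir^2))
    for (k in seq_len(n_spk))
      spike <- spike + outer(pulse_shape(times, onset[k],
                                         profile$spike_duration_s),
                             amp[k] * dir[k, ])
    events <- rbind(events, data.frame(type = "spike", onset = onset,
                                       duration = profile$spike_duration_s,
                                       amplitude = amp))
  }

  ## AR(1) jitter on all six parameters (stationary sd as configured)
  ar1_series <- function(sd) {
    if (sd == 0) return(numeric(n))
    phi <- profile$jitter_ar1
    e <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
    as.numeric(stats::filter(e, phi, method = "recursive",
                             init = stats::rnorm(1, 0, sd)))
  }
  jit_t <- cbind(ar1_series(profile$jitter_sd_trans_mm),
                 ar1_series(profile$jitter_sd_trans_mm),
                 ar1_series(profile$jitter_sd_trans_mm))
  jit_r <- cbind(ar1_series(profile$jitter_sd_rot_deg),
                 ar1_series(profile$jitter_sd_rot_deg),
                 ar1_series(profile$jitter_sd_rot_deg)) * pi / 180

  ## compose: R = R_nod R_jit ; t = drift + R_nod (spike + jit_t)
  q_nod <- quat_about_axis(c(1, 0, 0), theta * pi / 180)
  q_jit <- quat_multiply(
    quat_multiply(quat_about_axis(c(0, 0, 1), jit_r[, 3]),
                  quat_about_axis(c(0, 1, 0), jit_r[, 2])),
    quat_about_axis(c(1, 0, 0), jit_r[, 1]))
  q <- quat_normalize(quat_multiply(q_nod, q_jit))
  trans <- drift + quat_rotate(q_nod, spike + jit_t)

  trace <- pose_trace(times, quat_to_rotarray(q), trans, frame = frame,
                      nominal_rate = rate_hz, validate = FALSE)
  truth <- list(events = events, drift = drift, profile = profile)
  list(trace = trace, truth = truth)
}

#' Simulate a two-group cohort
#'
#' Generates per-patient traces for an anaesthetised ("GA") and an awake
#' group.  Per-patient seeds and profile parameters are derived
#' deterministically from \code{master_seed}: each rate/amplitude/jitter
#' parameter is scaled by a patient-specific lognormal factor
#' (\code{sdlog = population_sdlog}) around the group default, modelling
#' between-patient variability.
#'
#' @param n_ga,n_awake group sizes (defaults 18 and 43, a typical
#'   clinical imbalance).
#' @param ga,awake the group \code{\link{motion_profile}}s.
#' @param master_seed integer master seed; the same seed reproduces the
#'   cohort exactly.
#' @param schedule scan schedule shared by all patients.
#' @param rate_hz sampling rate for all traces.
#' @param population_sdlog lognormal sdlog of between-patient parameter
#'   variation (0 disables it).
#' @return A list of class \code{"simulated_cohort"}; each element has
#'   \code{patient_id}, \code{group}, \code{trace} and \code{truth}.
#' @export
make_cohort <- function(n_ga = 18, n_awake = 43,
                        ga = ga_profile(), awake = awake_profile(),
                        master_seed = 1L, schedule = default_schedule(),
                        rate_hz = 30, population_sdlog = 0.4) {
  stopifnot(n_ga >= 1, n_awake >= 1)
  n <- n_ga + n_awake
  set.seed(as.integer(master_seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  scale_pars <- c("nod_rate", "nod_amplitude_deg", "spike_rate",
                  "spike_amplitude_mm", "jitter_sd_trans_mm",
                  "jitter_sd_rot_deg")
  factors <- matrix(stats::rlnorm(n * (length(scale_pars) + 1), 0,
                                  population_sdlog),
                    n, length(scale_pars) + 1)
  group <- rep(c("GA", "awake"), c(n_ga, n_awake))
  out <- lapply(seq_len(n), function(i) {
    prof <- if (group[i] == "GA") ga else awake
    prof$drift_rate <- prof$drift_rate * factors[i, 1]
    for (j in seq_along(scale_pars))
      prof[[scale_pars[j]]] <- prof[[scale_pars[j]]] * factors[i, j + 1]
    prof$seed <- seeds[i]
    sim <- simulate_trace(prof, schedule, rate_hz = rate_hz)
    list(patient_id = sprintf("P%03d", i), group = group[i],
         trace = sim$trace, truth = sim$truth)
  })
  structure(out, class = "simulated_cohort", schedule = schedule,
            master_seed = master_seed)
}

#' @export
print.simulated_cohort <- function(x, ...) {
  g <- vapply(x, `[[`, "", "group")
  cat(sprintf("Simulated cohort: %d patients (%d GA, %d awake), master seed %s\n",
              length(x), sum(g == "GA"), sum(g == "awake"),
              format(attr(x, "master_seed"))))
  invisible(x)
}
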