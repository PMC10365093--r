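# Shared generators for tests.  All randomness is drawn from the caller's
# RNG stream; tests set their own seeds.

# random small-motion rigid transform (|angles| <= max_deg, |t| <= max_mm)
random_rigid <- function(max_deg = 15, max_mm = 10) {
  rt_from_params(t_x = runif(1, -max_mm, max_mm),
                 t_y = runif(1, -max_mm, max_mm),
                 t_z = runif(1, -max_mm, max_mm),
                 r_x = runif(1, -max_deg, max_deg),
                 r_y = runif(1, -max_deg, max_deg),
                 r_z = runif(1, -max_deg, max_deg))
}

# pose trace from a list of rigid transforms
trace_from_transforms <- function(transforms, times = NULL,
                                  frame = "tracker", nominal_rate = 1) {
  n <- length(transforms)
  if (is.null(times)) times <- seq_len(n) - 1
  rot <- array(0, c(3, 3, n))
  trans <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    rot[, , i] <- transforms[[i]]$R
    trans[i, ] <- transforms[[i]]$t
  }
  pose_trace(times, rot, trans, frame = frame, nominal_rate = nominal_rate)
}

# random smooth trace: a random walk of small rigid increments
random_trace <- function(n = 50, step_deg = 0.5, step_mm = 0.3,
                         frame = "tracker", nominal_rate = 1) {
  cur <- random_rigid(5, 3)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cur <- rt_compose(random_rigid(step_deg, step_mm), cur)
    out[[i]] <- cur
  }
  trace_from_transforms(out, frame = frame, nominal_rate = nominal_rate)
}

# identity trace of length n
identity_trace <- function(n, times = seq_len(n) - 1, frame = "RAS",
                           nominal_rate = 1) {
  trace_from_transforms(replicate(n, rt_identity(), simplify = FALSE),
                        times = times, frame = frame,
                        nominal_rate = nominal_rate)
}

# trace whose i-th pose is a pure translation given by rows of tmat
translation_trace <- function(tmat, times = seq_len(nrow(tmat)) - 1,
                              frame = "RAS", nominal_rate = 1) {
  trace_from_transforms(
    lapply(seq_len(nrow(tmat)),
           function(i) rt_translate(tmat[i, 1], tmat[i, 2], tmat[i, 3])),
    times = times, frame = frame, nominal_rate = nominal_rate)
}

frob <- function(A, B) max(abs(A - B))

rt_equal <- function(A, B, tol = 1e-9) {
  frob(A$R, B$R) <= tol && max(abs(A$t - B$t)) <= tol
}

# one-MR-window schedule [0, dur] for closed-form drift checks
single_window_schedule <- function(dur = 600, label = "MPRAGE") {
  scan_schedule(data.frame(label = label, start = 0, end = dur,
                           modality = "MR"),
                reference_label = label)
}

# brute-force exact two-sided Mann-Whitney p by enumeration of all
# C(nx+ny, nx) group assignments (independent oracle; no ties assumed)
enumerate_mw <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  u_all <- apply(combos, 2, function(idx)
    sum(r[idx]) - nx * (nx + 1) / 2)
  # two-sided: double the smaller tail (the null distribution of U is
  # symmetric about nx*ny/2), capped at 1
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  list(u = u_obs, p = min(1, p))
}
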