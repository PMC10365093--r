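test_that("the default schedule has the protocol durations", {
  sch <- default_schedule()
  w <- sch$windows
  mpr <- w[w$label == "MPRAGE", ]
  expect_equal(mpr$end - mpr$start, 266)
  expect_equal(sum(w$end[w$modality == "MR"] - w$start[w$modality == "MR"]),
               998)
  expect_equal(max(w$end), 41.7 * 60)
  expect_equal(sch$reference_label, "MPRAGE")
})

test_that("a zero profile generates an identity trace", {
  sim <- simulate_trace(motion_profile(seed = 3), default_schedule(),
                        rate_hz = 2)
  expect_lt(max(abs(sim$trace$trans)), 1e-15)
  expect_lt(max(abs(sweep(sim$trace$rot, c(1, 2), diag(3)))), 1e-15)
  expect_equal(nrow(sim$truth$events), 0)
})

test_that("generated transforms are rigid by construction", {
  sim <- simulate_trace(awake_profile(seed = 4), default_schedule(),
                        rate_hz = 2)
  n <- length(sim$trace$times)
  for (i in seq(1, n, length.out = 50)) {
    R <- sim$trace$rot[, , round(i)]
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
})

test_that("drift-only traces reproduce the closed-form mean displacement", {
  r <- 0.1                      # mm/min
  prof <- motion_profile(drift_rate = c(0, 0, -r), seed = 5)
  sch <- single_window_schedule(600)
  sim <- simulate_trace(prof, sch, rate_hz = 30)
  rel <- relative_to_reference(sim$trace,
                               select_reference_time(sim$trace, sch))
  m <- motion_summary(displacement_series(rel, c(0, 0, 0)))
  expect_equal(m$mean_disp_mm, r / 60 * 600 / 4, tolerance = 2e-2)
})

test_that("nod pulses appear only as x rotation with the drawn amplitude", {
  prof <- motion_profile(nod_rate = 0.05, nod_amplitude_deg = 1.2,
                         nod_amplitude_sd_deg = 0.4, seed = 2)
  sim <- simulate_trace(prof, default_schedule(), rate_hz = 10)
  ev <- sim$truth$events
  expect_gte(nrow(ev), 1)
  mp <- motion_params(sim$trace)
  expect_equal(max(abs(mp$r_y)), 0, tolerance = 1e-9)
  expect_equal(max(abs(mp$r_z)), 0, tolerance = 1e-9)
  # sampled peak equals the ground-truth pulse evaluated on the grid
  times <- sim$trace$times
  pred <- rep(0, length(times))
  for (k in seq_len(nrow(ev)))
    pred <- pred + ev$amplitude[k] *
      headmotion:::pulse_shape(times, ev$onset[k], ev$duration[k])
  expect_equal(max(abs(mp$r_x)), max(pred), tolerance = 1e-6)
  # and the grid peak is within pulse curvature of the true amplitude
  expect_equal(max(abs(mp$r_x)), max(ev$amplitude), tolerance = 1e-2)
})

test_that("simulation is reproducible from its seed", {
  a <- simulate_trace(awake_profile(seed = 9), default_schedule(), 2)
  b <- simulate_trace(awake_profile(seed = 9), default_schedule(), 2)
  expect_identical(a$trace$trans, b$trace$trans)
  expect_identical(a$trace$rot, b$trace$rot)
  expect_identical(a$truth$events, b$truth$events)
  c1 <- make_cohort(n_ga = 2, n_awake = 2, master_seed = 77, rate_hz = 2)
  c2 <- make_cohort(n_ga = 2, n_awake = 2, master_seed = 77, rate_hz = 2)
  for (i in 1:4) {
    expect_identical(c1[[i]]$trace$trans, c2[[i]]$trace$trans)
    expect_identical(c1[[i]]$trace$rot, c2[[i]]$trace$rot)
  }
})

test_that("the drift slope is recoverable from decomposed traces", {
  # default-jitter awake noise level, drift only
  prof <- motion_profile(drift_rate = c(0, 0, -0.08),
                         jitter_sd_trans_mm = 0.05,
                         jitter_sd_rot_deg = 0.03, seed = 31)
  sch <- default_schedule()
  sim <- simulate_trace(prof, sch, rate_hz = 5)
  masked <- mask_to_windows(sim$trace, sch)
  rel <- relative_to_reference(masked, select_reference_time(masked, sch))
  mp <- motion_params(rel)
  slope <- unname(stats::coef(stats::lm(t_z ~ time, mp))[2]) * 60
  expect_equal(slope, -0.08, tolerance = 0.05)
})

test_that("nod event counts stay within Poisson bounds of the rate", {
  prof <- motion_profile(nod_rate = 1, nod_amplitude_deg = 1,
                         nod_amplitude_sd_deg = 0.2, seed = 41)
  sim <- simulate_trace(prof, default_schedule(), rate_hz = 10)
  mp <- motion_params(sim$trace)
  # count upward crossings of half the mean amplitude
  above <- abs(mp$r_x) > 0.5
  crossings <- sum(diff(as.integer(above)) == 1)
  lambda <- 1 * 41.7
  expect_gte(crossings, qpois(0.025, lambda))
  expect_lte(crossings, qpois(0.975, lambda))
})

test_that("default cohorts separate in the expected direction", {
  for (s in 1:5) {
    co <- make_cohort(n_ga = 6, n_awake = 6, master_seed = s, rate_hz = 1)
    cm <- cohort_motion(co)
    med <- tapply(cm$metrics$mean_disp_mm, cm$metrics$group, median)
    expect_gt(med[["awake"]], med[["GA"]])
  }
})

test_that("zero-motion cohorts yield degenerate, non-significant comparisons", {
  quiet <- motion_profile(seed = 1)
  co <- make_cohort(n_ga = 4, n_awake = 4, ga = quiet, awake = quiet,
                    master_seed = 3, rate_hz = 1, population_sdlog = 0)
  cm <- cohort_motion(co)
  cmp <- cohort_comparisons(cm$metrics, cm$axes)
  expect_false(any(cmp$passed_fdr))
  expect_true(all(cmp$p_value == 1))
})
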