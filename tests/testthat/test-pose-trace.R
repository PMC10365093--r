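test_that("trace construction validates times and shapes", {
  expect_error(pose_trace(c(0, 1, 1), array(diag(3), c(3, 3, 3)),
                          matrix(0, 3, 3)), "strictly increasing")
  expect_error(pose_trace(numeric(0), array(0, c(3, 3, 0)),
                          matrix(0, 0, 3)), "at least one sample")
  tr <- identity_trace(3)
  expect_s3_class(tr, "pose_trace")
  expect_length(tr, 3)
})

test_that("masking keeps exactly the samples inside matching windows", {
  tr <- identity_trace(3, times = c(0, 10, 20))
  sched <- scan_schedule(data.frame(label = "A", start = 5, end = 15,
                                    modality = "MR"), "A")
  expect_equal(mask_to_windows(tr, sched)$times, 10)

  tr2 <- identity_trace(3, times = c(2, 7, 12))
  sched2 <- scan_schedule(data.frame(label = c("A", "B"),
                                     start = c(0, 10), end = c(5, 15),
                                     modality = "MR"), "A")
  expect_equal(mask_to_windows(tr2, sched2)$times, c(2, 12))

  # all samples inside one window -> unchanged
  sched3 <- scan_schedule(data.frame(label = "A", start = 0, end = 30,
                                     modality = "MR"), "A")
  expect_equal(mask_to_windows(tr, sched3)$times, tr$times)

  # boundary samples are kept (closed intervals)
  tr4 <- identity_trace(2, times = c(5, 15))
  expect_equal(mask_to_windows(tr4, sched)$times, c(5, 15))

  sched_pet <- scan_schedule(data.frame(label = "P", start = 100, end = 200,
                                        modality = "PET"), "P")
  expect_error(mask_to_windows(tr, sched_pet, "MR"), "no windows")
  sched_far <- scan_schedule(data.frame(label = "A", start = 100, end = 200,
                                        modality = "MR"), "A")
  expect_error(mask_to_windows(tr, sched_far), "no samples")
})

test_that("reference time is the sample nearest the window midpoint", {
  tr <- identity_trace(367, times = 0:366)
  sched <- scan_schedule(data.frame(label = "MPRAGE", start = 100, end = 366,
                                    modality = "MR"), "MPRAGE")
  expect_equal(select_reference_time(tr, sched), 233)

  # single-sample trace
  tr1 <- identity_trace(1, times = 42)
  expect_equal(select_reference_time(tr1, sched), 42)

  # midpoint equidistant between two samples -> earlier sample
  tr2 <- identity_trace(2, times = c(232.5, 233.5))
  expect_equal(select_reference_time(tr2, sched), 232.5)

  sched_other <- scan_schedule(data.frame(label = "X", start = 0, end = 10,
                                          modality = "MR"), "MISSING")
  expect_error(select_reference_time(tr, sched_other), "not found")
})

test_that("re-referencing maps the reference sample to identity", {
  set.seed(5)
  tr <- random_trace(30)
  rel <- relative_to_reference(tr, tr$times[12])
  expect_lt(frob(rel$rot[, , 12], diag(3)), 1e-12)
  expect_equal(unname(rel$trans[12, ]), c(0, 0, 0))

  # constant trace -> all identity
  T0 <- random_rigid()
  const <- trace_from_transforms(replicate(10, T0, simplify = FALSE))
  relc <- relative_to_reference(const, 4)
  for (i in 1:10) {
    expect_lt(frob(relc$rot[, , i], diag(3)), 1e-9)
    expect_lt(max(abs(relc$trans[i, ])), 1e-9)
  }

  # reference pose = identity -> output equals input
  tr_id_ref <- trace_from_transforms(list(rt_identity(),
                                          rt_translate(1, 2, 3)))
  rel2 <- relative_to_reference(tr_id_ref, 0)
  expect_equal(rel2$trans, tr_id_ref$trans)
  expect_equal(rel2$rot, tr_id_ref$rot)

  # two-sample hand example
  tr3 <- trace_from_transforms(list(rt_translate(1, 0, 0),
                                    rt_translate(3, 0, 0)))
  rel3 <- relative_to_reference(tr3, 0)
  expect_true(rt_equal(trace_transform(rel3, 1), rt_identity()))
  expect_true(rt_equal(trace_transform(rel3, 2), rt_translate(2, 0, 0)))

  expect_error(relative_to_reference(tr, 1e6), "time span")
})

test_that("re-referencing is idempotent at the same reference time", {
  set.seed(6)
  tr <- random_trace(25)
  rel1 <- relative_to_reference(tr, tr$times[8])
  rel2 <- relative_to_reference(rel1, tr$times[8])
  expect_lt(max(abs(rel1$rot - rel2$rot)), 1e-12)
  expect_lt(max(abs(rel1$trans - rel2$trans)), 1e-12)
})

test_that("frame conjugation transforms poses and tags correctly", {
  set.seed(7)
  tr <- random_trace(10, frame = "tracker")

  # C = identity: poses unchanged, tag updated
  tr_id <- change_frame(tr, rt_identity(), "RAS")
  expect_equal(tr_id$rot, tr$rot)
  expect_equal(tr_id$trans, tr$trans)
  expect_equal(tr_id$frame, "RAS")
  expect_error(change_frame(tr_id, rt_identity(), "RAS"), "already in frame")

  # pure translation conjugates to translate(Rc v)
  C <- random_rigid(60, 40)
  v <- c(1.5, -2, 0.7)
  trv <- trace_from_transforms(list(rt_translate(v[1], v[2], v[3])),
                               frame = "tracker")
  out <- change_frame(trv, C, "RAS")
  expect_true(rt_equal(trace_transform(out, 1),
                       rigid_transform(diag(3), as.numeric(C$R %*% v)),
                       1e-9))
})

test_that("displacements are invariant under a change of frame", {
  set.seed(8)
  for (rep in 1:20) {
    tr <- random_trace(40, frame = "tracker")
    C <- random_rigid(90, 100)
    p <- rnorm(3, 0, 60)
    rel <- relative_to_reference(tr, tr$times[5])
    d1 <- displacement_series(rel, p)$displacement
    rel_new <- change_frame(rel, C, "RAS")
    d2 <- displacement_series(rel_new, rt_apply(C, p))$displacement
    expect_equal(d1, d2, tolerance = 1e-9)
  }
})

test_that("trace decomposition agrees with per-sample decomposition", {
  set.seed(9)
  tr <- random_trace(20)
  mp <- motion_params(tr)
  for (i in c(1, 7, 20)) {
    single <- motion_params(trace_transform(tr, i))
    expect_equal(unname(unlist(mp[i, c("t_x", "t_y", "t_z",
                                       "r_x", "r_y", "r_z")])),
                 unname(unlist(single[1, 1:6])), tolerance = 1e-9)
  }
})
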