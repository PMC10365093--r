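test_that("Mann-Whitney U matches the hand-enumerated example", {
  cmp <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(cmp$u_stat, 0)
  expect_equal(cmp$p_value, 1 / 3)
  expect_equal(cmp$method, "exact")
})

test_that("identical samples give p = 1 with a degenerate flag", {
  cmp <- mann_whitney_u(rep(2, 5), rep(2, 7))
  expect_equal(cmp$p_value, 1)
  expect_true(cmp$degenerate)
})

test_that("swapping the samples reflects U and keeps p", {
  set.seed(51)
  for (rep in 1:20) {
    x <- rnorm(5); y <- rnorm(7)
    a <- mann_whitney_u(x, y)
    b <- mann_whitney_u(y, x)
    expect_equal(b$u_stat, a$n_x * a$n_y - a$u_stat)
    expect_equal(b$p_value, a$p_value)
  }
})

test_that("exact p agrees with brute-force enumeration on small samples", {
  set.seed(52)
  for (rep in 1:40) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- rnorm(nx); y <- rnorm(ny)
    cmp <- mann_whitney_u(x, y)
    oracle <- enumerate_mw(x, y)
    expect_equal(cmp$u_stat, oracle$u)
    expect_equal(cmp$p_value, oracle$p, tolerance = 1e-12)
  }
})

test_that("ties or large samples switch to the corrected approximation", {
  cmp <- mann_whitney_u(c(1, 2, 2), c(2, 3, 4))
  expect_equal(cmp$method, "normal-approx")
  set.seed(53)
  big <- mann_whitney_u(rnorm(25), rnorm(25))   # 625 > 400
  expect_equal(big$method, "normal-approx")
  expect_true(big$p_value >= 0 && big$p_value <= 1)
})

test_that("BH step-up matches the hand-derived example", {
  fc <- fdr_correct(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(fc$reject))                # thresholds 0.0125..0.05

  expect_true(fdr_correct(0.04, 0.05)$reject)
  expect_false(any(fdr_correct(rep(1, 10), 0.05)$reject))

  # a p-value above its step-up threshold blocks only itself
  fc2 <- fdr_correct(c(0.01, 0.2, 0.9), alpha = 0.05)
  expect_equal(fc2$reject, c(TRUE, FALSE, FALSE))

  empty <- fdr_correct(numeric(0))
  expect_length(empty$reject, 0)
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH rejections are monotone in alpha", {
  set.seed(54)
  for (rep in 1:50) {
    p <- runif(sample(3:20, 1))^sample(1:3, 1)
    n_rej <- vapply(seq(0.01, 0.2, by = 0.01),
                    function(a) sum(fdr_correct(p, a)$reject), 0L)
    expect_true(all(diff(n_rej) >= 0))
  }
})

test_that("the normality check separates normal from bimodal samples", {
  expect_error(normality_check(c(1, 2)), "at least 3")
  z <- normality_check(rep(5, 10))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))

  set.seed(55)
  ok <- vapply(1:100, function(i) normality_check(rnorm(200)) > 0.05, TRUE)
  expect_gte(mean(ok), 0.9)

  bimodal <- c(rep(0, 50), rep(10, 50)) + rnorm(100, 0, 0.01)
  expect_lt(as.numeric(normality_check(bimodal)), 0.01)
})

test_that("cohort summaries report median and n-1 standard deviation", {
  s1 <- cohort_summary(2)
  expect_equal(c(s1$median, s1$sd, s1$n), c(2, 0, 1))
  expect_false(attr(s1, "sd_defined"))

  s3 <- cohort_summary(c(1, 2, 3))
  expect_equal(c(s3$median, s3$sd), c(2, 1))

  # median is a rank statistic: a rank-symmetric outlier pair is inert
  base <- c(1, 2, 3, 4, 5)
  expect_equal(cohort_summary(c(base, -1e6, 1e6))$median,
               cohort_summary(base)$median)
})

test_that("comparison families are built and corrected independently", {
  set.seed(56)
  n1 <- 8; n2 <- 10
  met <- data.frame(
    patient_id = sprintf("P%02d", 1:(n1 + n2)),
    group = rep(c("GA", "awake"), c(n1, n2)),
    mean_disp_mm = c(rnorm(n1, 1, 0.1), rnorm(n2, 3, 0.3)),
    median_disp_mm = c(rnorm(n1, 1, 0.1), rnorm(n2, 3, 0.3)),
    max_disp_mm = c(rnorm(n1, 2, 0.2), rnorm(n2, 6, 0.5)),
    motion_free_frac = c(runif(n1, 0.9, 1), runif(n2, 0.4, 0.6)))
  axes <- expand.grid(patient_id = met$patient_id,
                      channel = c("translation", "rotation"),
                      axis = c("x", "y", "z"),
                      stringsAsFactors = FALSE)
  axes$group <- met$group[match(axes$patient_id, met$patient_id)]
  axes$mean_abs <- runif(nrow(axes))
  cmp <- cohort_comparisons(met, axes)
  expect_s3_class(cmp, "motion_comparisons")
  expect_equal(sum(cmp$family == "metrics"), 4)
  expect_equal(sum(cmp$family == "axes_GA"), 6)
  expect_equal(sum(cmp$family == "axes_awake"), 6)
  expect_true(all(cmp$passed_fdr[cmp$family == "metrics"]))
  expect_true(all(cmp$u_stat >= 0 & cmp$u_stat <= cmp$n_x * cmp$n_y))
  # within-family BH agrees with a direct call
  for (fam in unique(cmp$family)) {
    sub <- cmp[cmp$family == fam, ]
    expect_equal(sub$passed_fdr, fdr_correct(sub$p_value, 0.05)$reject)
  }

  met1 <- met[met$group == "GA", ]
  expect_error(cohort_comparisons(met1), "two groups")
})

test_that("a single-test family reduces FDR to the plain alpha threshold", {
  expect_true(fdr_correct(0.049, 0.05)$reject)
  expect_false(fdr_correct(0.051, 0.05)$reject)
})
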