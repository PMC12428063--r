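test_that("default cohort reproduces the published replicate structure", {
  ch <- generate_cohort(cohort_spec(), seed = 3)
  expect_equal(nrow(ch), 27L)  # 9 + 6 + 7 + 5
  expect_equal(as.integer(table(ch$group_cm)), c(9L, 6L, 7L, 5L))
  expect_true(all(ch$volume_cm3 > 0))
  expect_true(all(ch$time_s > 0))
})

test_that("zero-SD specification collapses to the group means", {
  g <- reference_groups()
  g$volume_sd_cm3 <- 0
  g$time_sd_s <- 0
  ch <- generate_cohort(cohort_spec(g), seed = 1)
  expect_equal(ch$volume_cm3[ch$group_cm == 1.5], rep(12.83, 7))
  expect_equal(ch$time_s[ch$group_cm == 0.5], rep(473, 9))
})

test_that("cohort generation is seed-deterministic", {
  a <- generate_cohort(cohort_spec(), seed = 99)
  b <- generate_cohort(cohort_spec(), seed = 99)
  d <- generate_cohort(cohort_spec(), seed = 100)
  expect_identical(a, b)
  expect_false(identical(a, d))
})

test_that("truncation never emits non-positive draws and shifts the mean up", {
  g <- data.frame(group_cm = 1, n = 4000L, time_mean_s = 100, time_sd_s = 10,
                  volume_mean_cm3 = 2, volume_sd_cm3 = 3)
  ch <- generate_cohort(cohort_spec(g), seed = 5)
  expect_true(all(ch$volume_cm3 > 0))
  expect_gt(mean(ch$volume_cm3), 2)  # mass below zero folded upward
  bad <- g; bad$volume_mean_cm3 <- -20; bad$volume_sd_cm3 <- 1
  expect_error(cohort_spec(bad), "infeasible truncation")
})

test_that("large cohorts recover the specified group means", {
  g <- reference_groups()
  g$n <- rep(10000L, 4)
  ch <- generate_cohort(cohort_spec(g), seed = 2)
  m <- mean(ch$volume_cm3[ch$group_cm == 1.5])
  expect_equal(m, 12.83, tolerance = 0.01)  # truncation at -4.9 sd: negligible
})

test_that("zero-SD recovery returns identical per-replicate thresholds", {
  g <- reference_groups()
  g$volume_sd_cm3 <- 0
  rec <- recovery_experiment(cohort_spec(g), toy_curve_set(), seed = 1)
  for (grp in g$group_cm) {
    th <- rec$replicates$threshold_V_per_cm[rec$replicates$group_cm == grp]
    expect_lt(max(th) - min(th), 1e-9)
  }
  expect_equal(rec$per_group$bias, rep(0, 4), tolerance = 1e-9)
})

test_that("recovered thresholds track the spec means with sampling noise", {
  curves <- toy_curve_set()
  rec <- recovery_experiment(cohort_spec(), curves, seed = 8)
  # the analytic curve inverts to e = 1000 (s / v)^(2/3); group means within
  # a few standard errors of the implied thresholds
  for (i in 1:4) {
    imp <- rec$per_group$implied_threshold[i]
    se <- rec$per_group$threshold_sd[i] / sqrt(rec$per_group$n[i])
    expect_lt(abs(rec$per_group$bias[i]), 4 * se + 15)
  }
  # threshold dispersion grows with the specified volume dispersion
  tight <- reference_groups(); tight$volume_sd_cm3 <- tight$volume_sd_cm3 / 10
  rec_tight <- recovery_experiment(cohort_spec(tight), curves, seed = 8)
  expect_true(all(rec_tight$per_group$threshold_sd <
                    rec$per_group$threshold_sd))
})

test_that("missing curves are reported by group", {
  expect_error(recovery_experiment(cohort_spec(), toy_curve_set()[1:2]),
               "every group")
})
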