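test_that("threshold matching inverts the volume-field curve", {
  fx <- sphere_fixture()
  curve <- volume_field_curve(fx$field)
  # exact grid hit returns the grid level
  v600 <- curve$volume_cm3[curve$e_set_V_per_cm == 600]
  expect_equal(as.numeric(calibrate_threshold(curve, v600)), 600)
  # round trip across the grid: < 10 V/cm interpolated, exact grid-nearest
  for (e in c(250, 430, 600, 1000, 1550)) {
    v <- volume_above_field(fx$field, e)
    expect_lt(abs(as.numeric(calibrate_threshold(curve, v)) - e), 10)
    expect_equal(as.numeric(calibrate_threshold(curve, v, mode = "grid")),
                 e)
  }
  # closed-form benchmark: 1.95 cm^3 corresponds to about 1000 V/cm
  th <- as.numeric(calibrate_threshold(curve, 1.95))
  expect_equal(th, 1000, tolerance = 0.02)
})

test_that("volumes outside the curve range are flagged and clamped", {
  fx <- sphere_fixture()
  curve <- volume_field_curve(fx$field)
  big <- calibrate_threshold(curve, max(curve$volume_cm3) * 2)
  expect_true(attr(big, "out_of_range"))
  expect_equal(as.numeric(big), 200)
  tiny <- calibrate_threshold(curve, min(curve$volume_cm3) / 2)
  expect_true(attr(tiny, "out_of_range"))
  expect_equal(as.numeric(tiny), 2000)
})

test_that("predicted ablation from the spherical benchmark is spherical", {
  fx <- sphere_fixture()
  ab <- predict_ablation(fx$field, 1000)
  expect_equal(ab$sphericity, 1, tolerance = 0.02)
  expect_equal(ab$volume_cm3, volume_above_field(fx$field, 1000),
               tolerance = 1e-12)
  expect_false(ab$empty)
  # beyond the maximum field: empty region flagged
  none <- predict_ablation(fx$field, 10 * max(fx$field$E_node))
  expect_true(none$empty)
  expect_equal(none$volume_cm3, 0)
})

test_that("predicted length spans at least the exposed electrode", {
  fx <- needle_fixture()
  th <- 700
  ab <- predict_ablation(fx$field, th)
  expect_gte(ab$length_cm, fx$geometry$applicator$exposure_length)
  expect_gt(ab$sphericity, 1)  # needle ablations elongate along the axis
})

test_that("Welch test reproduces hand-computed and reference results", {
  # identical groups
  same <- welch_t_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # published group summaries: 1.5 cm vs 2.0 cm ablation volumes
  w <- welch_t_summary(12.83, 2.61, 7, 7.64, 2.50, 5)
  expect_equal(w$t, 3.481, tolerance = 1e-3)
  expect_equal(w$df, 9.01, tolerance = 1e-2)
  expect_equal(w$p, 0.0069, tolerance = 0.01)
  expect_lt(w$p, 0.05)
  # location invariance
  set.seed(11)
  a <- rnorm(8); b <- rnorm(6, 1)
  expect_equal(welch_t_test(a + 100, b + 100)$t, welch_t_test(a, b)$t,
               tolerance = 1e-12)
})

test_that("Welch implementation agrees with stats::t.test to 1e-12", {
  set.seed(42)
  for (i in 1:20) {
    a <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2), sd = runif(1, .1, 3))
    b <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2), sd = runif(1, .1, 3))
    ref <- stats::t.test(a, b)
    w <- welch_t_test(a, b)
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(w$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate Welch inputs are rejected", {
  expect_error(welch_t_test(c(1), c(1, 2)))
  expect_error(welch_t_summary(5, 0, 4, 5, 0, 4), "zero variance")
})

test_that("linear trend fit matches lm and handles degenerate x", {
  fit <- linear_trend(c(1, 2, 3), c(2, 4, 6))
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 2)
  expect_error(linear_trend(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("group summary reports n, mean and sample SD per group", {
  m <- data.frame(group_cm = c(1, 1, 1, 2),
                  volume_cm3 = c(2, 4, 6, 5),
                  time_s = c(10, 10, 10, 8))
  s <- group_summary(m)
  expect_equal(s$n, c(3L, 1L))
  expect_equal(s$volume_cm3_mean, c(4, 5))
  expect_equal(s$volume_cm3_sd, c(2, 0))
  expect_equal(s$time_s_sd[1], 0)
  expect_error(group_summary(data.frame(volume_cm3 = 1)))
})
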