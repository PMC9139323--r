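test_that("a perfectly flat course is non-significant, duration = horizon", {
  course <- simulate_stability_course(baseline = 100, drift_per_day = 0,
                                      cv = 0, timepoints = 0:8, seed = 1)
  fit <- fit_stability_regression(course)
  expect_equal(fit$slope, 0, tolerance = 1e-12)
  expect_equal(fit$slope_p_value, 1)
  dur <- stability_duration(fit)
  expect_equal(dur$duration_days, 8)
  expect_identical(dur$duration_branch, "non_significant")
})

test_that("a noiseless drifting course crosses at the exact line crossing", {
  # -2%/day of baseline: the point line hits the -10% limit at t = 5; with
  # zero noise the confidence band equals the line
  course <- simulate_stability_course(baseline = 100, drift_per_day = -2,
                                      cv = 0, timepoints = 0:8, seed = 2)
  fit <- fit_stability_regression(course)
  expect_equal(fit$slope_p_value, 0)
  dur <- stability_duration(fit)
  expect_equal(dur$duration_days, 5, tolerance = 2e-3)
  expect_identical(dur$duration_branch, "crossing")

  # positive drift mirrors: +2.5%/day hits +10% at t = 4
  up <- simulate_stability_course(baseline = 80, drift_per_day = 2,
                                  cv = 0, timepoints = 0:8, seed = 3)
  dur_up <- stability_duration(fit_stability_regression(up))
  expect_equal(dur_up$duration_days, 4, tolerance = 2e-3)
})

test_that("noisy courses match the independent grid-scan band oracle", {
  for (seed in c(4, 9, 23)) {
    course <- simulate_stability_course(baseline = 100, drift_per_day = -1.6,
                                        cv = 1, timepoints = 0:8, reps = 3,
                                        seed = seed)
    fit <- fit_stability_regression(course)
    dur <- stability_duration(fit)
    ok <- course[course$status == "ok", ]
    oracle <- stability_crossing_oracle(ok$timepoint_days, ok$value,
                                        fit$baseline_mean, horizon = 8)
    if (fit$slope_p_value < 0.05) {
      expect_equal(dur$duration_days, oracle, tolerance = 2e-3)
    } else {
      expect_equal(dur$duration_days, 8)
    }
  }
})

test_that("the slope is covered by its own 95% CI at close to nominal rate", {
  hits <- 0
  for (i in 1:400) {
    course <- simulate_stability_course(baseline = 100, drift_per_day = -1,
                                        cv = 1, timepoints = 0:8, reps = 3,
                                        seed = 1000 + i)
    fit <- fit_stability_regression(course)
    ci <- stats::confint(fit$lm)["timepoint_days", ]
    hits <- hits + (ci[1] <= -1 && -1 <= ci[2])
  }
  expect_gte(hits / 400, 0.93)
})

test_that("duration is monotone in drift limit and drift magnitude", {
  course <- simulate_stability_course(baseline = 100, drift_per_day = -2,
                                      cv = 0.5, timepoints = 0:8, seed = 6)
  fit <- fit_stability_regression(course)
  d5 <- stability_duration(fit, drift_limit = 5)$duration_days
  d10 <- stability_duration(fit, drift_limit = 10)$duration_days
  d15 <- stability_duration(fit, drift_limit = 15)$duration_days
  expect_true(d5 <= d10 && d10 <= d15)

  slow <- simulate_stability_course(baseline = 100, drift_per_day = -1.5,
                                    cv = 0, timepoints = 0:8, seed = 7)
  fast <- simulate_stability_course(baseline = 100, drift_per_day = -3,
                                    cv = 0, timepoints = 0:8, seed = 7)
  expect_lt(stability_duration(fit_stability_regression(fast))$duration_days,
            stability_duration(fit_stability_regression(slow))$duration_days)
  expect_error(stability_duration(fit, drift_limit = 0), "> 0")
})

test_that("acceptance preconditions are enforced", {
  short <- simulate_stability_course(timepoints = c(0, 1), cv = 1, seed = 8)
  expect_error(fit_stability_regression(short), "at least 2 further")
  course <- simulate_stability_course(timepoints = 0:8, reps = 3, cv = 1,
                                      seed = 9)
  lost <- seq_len(4)                       # 4/27 ~ 15% missing
  course$status[lost] <- "no_result"
  course$value[lost] <- NA_real_
  expect_error(fit_stability_regression(course), "allowance")
})

test_that("the per-condition summary takes the minimum over donors", {
  data <- rbind(
    simulate_stability_course(baseline = 100, drift_per_day = 0, cv = 0.5,
                              timepoints = 0:8, seed = 10, pool_id = "D1"),
    simulate_stability_course(baseline = 100, drift_per_day = -2.5, cv = 0.3,
                              timepoints = 0:8, seed = 11, pool_id = "D2"))
  summ <- stability_summary(data)
  expect_equal(nrow(summ$per_donor), 2)
  expect_equal(summ$overall_duration,
               min(summ$per_donor$duration_days))
  expect_lt(summ$overall_duration, 8)
})
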