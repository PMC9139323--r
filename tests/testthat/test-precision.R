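test_that("constant data yields exactly zero CVs", {
  d <- simulate_precision_study(true_mean = 80,
                                spec = variance_spec(0, 0, 0), seed = 1)
  est <- estimate_components(d)
  expect_equal(est$grand_mean, 80)
  expect_equal(est$cv_repeatability, 0)
  expect_equal(est$cv_between_run, 0)
  expect_equal(est$cv_between_day, 0)
  expect_equal(est$cv_within_laboratory, 0)
})

test_that("components match the hand-computed nested ANOVA on a toy set", {
  # 2 days x 2 runs x 2 replicates, values chosen to spread every stratum
  grid <- expand.grid(replicate = 1:2, run = 1:2, day = 1:2)
  vals <- c(10, 12, 15, 17, 20, 22, 30, 34)
  d <- measurements("P1", "a", vals, day = grid$day, run = grid$run,
                    replicate = grid$replicate)
  est <- estimate_components(d)
  oracle <- anova_oracle_single(d)
  expect_equal(est$grand_mean, oracle$grand_mean, tolerance = 1e-12)
  expect_equal(est$cv_repeatability,
               100 * sqrt(oracle$var_rep) / oracle$grand_mean,
               tolerance = 1e-10)
  expect_equal(est$cv_between_run,
               100 * sqrt(oracle$var_run) / oracle$grand_mean,
               tolerance = 1e-10)
  expect_equal(est$cv_between_day,
               100 * sqrt(oracle$var_day) / oracle$grand_mean,
               tolerance = 1e-10)
})

test_that("components match the oracle on full-size simulated studies", {
  for (seed in c(7, 19)) {
    d <- sim_single_site(80, c(3, 1.5, 2), seed = seed)
    est <- estimate_components(d)
    oracle <- anova_oracle_single(d)
    expect_equal(est$cv_repeatability,
                 100 * sqrt(oracle$var_rep) / oracle$grand_mean,
                 tolerance = 1e-10)
    expect_equal(est$cv_between_day,
                 100 * sqrt(oracle$var_day) / oracle$grand_mean,
                 tolerance = 1e-10)
  }
})

test_that("negative component estimates are truncated to zero", {
  # between-day truly zero: day-mean spread below the replicate noise makes
  # MS_day < MS_run often; force it deterministically with a crafted table
  grid <- expand.grid(replicate = 1:3, run = 1:2, day = 1:2)
  # identical day means; runs differ strongly within day
  vals <- ifelse(grid$run == 1, 70, 90) + grid$replicate * 0.1
  d <- measurements("P1", "a", vals, day = grid$day, run = grid$run,
                    replicate = grid$replicate)
  est <- estimate_components(d)
  expect_equal(est$cv_between_day, 0)
  expect_gt(est$cv_between_run, 0)
})

test_that("multi-site mode reports site and reproducibility, no run", {
  design <- study_design("precision_multi",
                         list(site = 3, day = 5, replicate = 6))
  d <- simulate_precision_study(design, true_mean = 85,
                                spec = variance_spec(3, 0, 2, 2), seed = 12)
  expect_equal(nrow(d), 90)
  est <- estimate_components(d, mode = "multi")
  expect_true(is.na(est$cv_between_run))
  expect_false(is.na(est$cv_between_site))
  expect_equal(est$cv_within_laboratory,
               aggregate_cv(c(est$cv_repeatability, est$cv_between_day)),
               tolerance = 1e-12)
  expect_equal(est$cv_reproducibility,
               aggregate_cv(c(est$cv_within_laboratory, est$cv_between_site)),
               tolerance = 1e-12)
})

test_that("the quadratic within-laboratory identity holds for single site", {
  d <- sim_single_site(60, c(3, 1.5, 2), seed = 5)
  est <- estimate_components(d)
  expect_equal(est$cv_within_laboratory^2,
               est$cv_repeatability^2 + est$cv_between_run^2 +
                 est$cv_between_day^2,
               tolerance = 1e-10)
})

test_that("estimates are invariant under a positive rescaling of values", {
  d <- sim_single_site(60, c(3, 1.5, 2), seed = 9)
  d2 <- d
  d2$value <- d2$value * 17.3
  a <- estimate_components(d)
  b <- estimate_components(d2)
  for (col in c("cv_repeatability", "cv_between_run", "cv_between_day",
                "cv_within_laboratory")) {
    expect_equal(a[[col]], b[[col]], tolerance = 1e-10)
  }
  expect_equal(b$grand_mean, a$grand_mean * 17.3, tolerance = 1e-10)
})

test_that("a single-level factor is rejected with the factor named", {
  grid <- expand.grid(replicate = 1:3, run = 1:2)
  d <- measurements("P1", "a", 70 + seq_len(6), day = 1L, run = grid$run,
                    replicate = grid$replicate)
  expect_error(estimate_components(d), "'day'")
})

test_that("aggregate_cv is root-sum-of-squares with input validation", {
  expect_equal(round(aggregate_cv(c(2.8, 1.3, 2.4)), 1), 3.9)
  expect_equal(round(aggregate_cv(c(2.8, 2.1)), 1), 3.5)
  expect_equal(aggregate_cv(c(0, 0, 0)), 0)
  expect_error(aggregate_cv(c(2, -1)), ">= 0")
})
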