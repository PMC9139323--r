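test_that("an exact line is recovered with non-significant curvature terms", {
  s <- simulate_linearity_series(low = 10, high = 110, n_levels = 11,
                                 reps = 3, curvature = 0, cv = 0, seed = 1)
  s$value <- 2 * s$assigned + 1
  h <- fit_polynomial_hierarchy(s)
  expect_equal(unname(h$fits$order1$coefficients), c(1, 2), tolerance = 1e-9)
  expect_lt(abs(h$fits$order2$coefficients["b2"]), 1e-10)
  expect_lt(abs(h$fits$order3$coefficients["b3"]), 1e-10)
})

test_that("a pure quadratic is fit exactly and flagged as significant", {
  df <- data.frame(assigned = rep(1:6, each = 2))
  df$value <- df$assigned^2 + rep(c(-0.01, 0.01), 6)  # tiny symmetric noise
  h <- fit_polynomial_hierarchy(df)
  expect_equal(unname(h$fits$order2$coefficients), c(0, 0, 1),
               tolerance = 1e-2)
  expect_lt(h$nonlinear_p_values["b2"], 1e-8)
})

test_that("coefficients match the normal-equations solver on random series", {
  set.seed(20)
  for (rep in 1:5) {
    x <- rep(seq(5, 50, length.out = 7), each = 2)
    y <- 3 + 0.5 * x + 0.01 * x^2 + stats::rnorm(length(x), 0, 0.5)
    h <- fit_polynomial_hierarchy(data.frame(assigned = x, value = y))
    for (ord in 1:3) {
      expect_equal(unname(h$fits[[paste0("order", ord)]]$coefficients),
                   polyfit_oracle(x, y, ord), tolerance = 1e-8)
    }
  }
})

test_that("an 11-level exact line passes with r = 1 and no degree", {
  s <- simulate_linearity_series(low = 20, high = 870, curvature = 0, cv = 0,
                                 seed = 2)
  v <- assess_linearity(s)
  expect_true(v$pass_flag)
  expect_equal(v$pearson_r, 1)
  expect_true(is.na(v$degree_of_nonlinearity))
  expect_equal(v$lol, 870)
})

test_that("a constructed 12% curvature fails on degree of non-linearity", {
  # choose curvature so the deviation of the quadratic from the OLS line,
  # relative to the line, reaches ~12% (computed by the independent solver)
  low <- 50; high <- 150; n_levels <- 11
  assigned <- rep(seq(low, high, length.out = n_levels), each = 3)
  target <- function(curv) {
    value <- assigned + curv * (assigned - 100)^2
    lin <- polyfit_oracle(assigned, value, 1)
    quad <- polyfit_oracle(assigned, value, 2)
    xs <- unique(assigned)
    linp <- lin[1] + lin[2] * xs
    quadp <- quad[1] + quad[2] * xs + quad[3] * xs^2
    max(abs(quadp - linp) / abs(linp)) * 100
  }
  curv <- stats::uniroot(function(c) target(c) - 12, c(0, 1),
                         tol = 1e-12)$root
  s <- simulate_linearity_series(low = low, high = high, n_levels = n_levels,
                                 reps = 3, curvature = curv, cv = 0, seed = 3)
  v <- assess_linearity(s)
  expect_false(v$pass_flag)
  expect_gt(v$degree_of_nonlinearity, 10)
  expect_equal(v$degree_of_nonlinearity, 12, tolerance = 1e-6)
  expect_true(any(grepl("non-linearity", v$reasons)))
})

test_that("fewer than 5 valid levels fails citing the minimum", {
  s <- simulate_linearity_series(low = 10, high = 110, n_levels = 11,
                                 reps = 3, cv = 0, seed = 4)
  drop <- s$level > 3
  s$status[drop] <- "no_result"
  s$value[drop] <- NA_real_
  expect_error(assess_linearity(s), "5 distinct levels")
})

test_that("a noisy level violating the CV bound is reported", {
  s <- simulate_linearity_series(low = 10, high = 110, cv = 0, seed = 5)
  lvl0 <- s$level == 0
  s$value[lvl0] <- c(5, 10, 18)            # CV ~ 59% at level 0
  v <- assess_linearity(s)
  expect_true(any(grepl("CV", v$reasons)))
  expect_false(v$per_level$pass[1])
  # LoL excludes the failing level but keeps the passing stretch
  expect_equal(v$lol, 110)
})

test_that("the verdict is invariant under a change of concentration units", {
  s <- simulate_linearity_series(low = 20, high = 870, curvature = 1e-5,
                                 cv = 2, seed = 6)
  s2 <- s
  s2$assigned <- s2$assigned / 1000        # umol/L -> mmol/L
  s2$value <- s2$value / 1000
  v1 <- assess_linearity(s)
  v2 <- assess_linearity(s2)
  expect_equal(v1$pass_flag, v2$pass_flag)
  expect_equal(v1$pearson_r, v2$pearson_r, tolerance = 1e-12)
  expect_equal(v1$degree_of_nonlinearity, v2$degree_of_nonlinearity,
               tolerance = 1e-6)
  expect_equal(v2$lol * 1000, v1$lol, tolerance = 1e-9)
})
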