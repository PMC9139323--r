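test_that("LoB parametric and nonparametric paths match closed forms", {
  # Gaussian closed form: 10 + 1.645... * 2
  x <- c(stats::qnorm(seq(0.02, 0.98, length.out = 40), 10, 2))
  x <- x - mean(x) + 10
  x <- (x - mean(x)) / stats::sd(x) * 2 + 10   # exact sample mean 10, sd 2
  est <- estimate_lob(x, method = "parametric")
  expect_equal(est$lob, 10 + stats::qnorm(0.95) * 2, tolerance = 1e-12)

  # nonparametric rank position for 20 blanks: 0.5 + 20 * 0.95 = 19.5
  set.seed(4)
  y <- sort(stats::rlnorm(20))
  est2 <- estimate_lob(y, method = "nonparametric")
  expect_equal(est2$lob, mean(y[19:20]), tolerance = 1e-12)

  # brute-force percentile oracle on larger panels at several alphas
  set.seed(5)
  z <- stats::rgamma(45, 2, 1)
  for (alpha in c(0.01, 0.05, 0.10)) {
    pos <- min(0.5 + 45 * (1 - alpha), 45)   # clamped at the top order stat
    s <- sort(z)
    lo <- floor(pos)
    expected <- if (lo == 45) s[45]
                else s[lo] + (pos - lo) * (s[lo + 1] - s[lo])
    expect_equal(estimate_lob(z, alpha = alpha,
                              method = "nonparametric")$lob,
                 expected, tolerance = 1e-12)
  }
})

test_that("LoB handles degenerate and undersized panels", {
  expect_equal(estimate_lob(rep(0, 25), method = "parametric")$lob, 0)
  expect_equal(estimate_lob(rep(0, 25), method = "nonparametric")$lob, 0)
  expect_equal(estimate_lob(rep(0, 25), method = "auto")$lob, 0)
  expect_error(estimate_lob(stats::rnorm(19, 10)), "at least 20")
})

test_that("auto LoB method switches on a normality gate", {
  set.seed(11)
  gaussian <- stats::rnorm(60, 10, 1)
  skewed <- stats::rlnorm(60, 0, 1.5)
  expect_identical(estimate_lob(gaussian)$method, "parametric")
  expect_identical(estimate_lob(skewed)$method, "nonparametric")
})

test_that("Cochran's C statistic and verdict behave as defined", {
  r <- cochran_c_test(c(1, 1, 1, 1), df_per_group = 10)
  expect_equal(r$statistic, 0.25)
  expect_true(r$pass_flag)
  r2 <- cochran_c_test(c(99, 0.4, 0.3, 0.3), df_per_group = 10)
  expect_gt(r2$statistic, 0.9)
  expect_false(r2$pass_flag)
  expect_error(cochran_c_test(c(0, 0, 0), df_per_group = 5), "degenerate")
  expect_error(cochran_c_test(c(1), df_per_group = 5), "2 groups")
  expect_error(cochran_c_test(c(1, -1), df_per_group = 5), ">= 0")
})

test_that("Cochran critical value matches the simulated null distribution", {
  k <- 4; df <- 10
  set.seed(101)
  v <- matrix(stats::rchisq(k * 20000, df) / df, ncol = k)
  stat <- apply(v, 1, function(row) max(row) / sum(row))
  empirical <- unname(stats::quantile(stat, 0.95, type = 7))
  closed <- cochran_c_test(c(1, 1, 1, 1), df_per_group = df)$critical_value
  expect_lt(abs(empirical - closed), 0.01)   # Monte-Carlo error at n = 20000
})

test_that("classical LoD equals the hand-computed pooled-SD formula", {
  panels <- simulate_detection_panels(n_blank_pools = 0, n_low_pools = 4,
                                      low_means = c(20, 25, 30, 40),
                                      low_cv = 0, seed = 3)
  # add homogeneous additive noise so Cochran passes
  set.seed(31)
  panels$value <- panels$value + stats::rnorm(nrow(panels), 0, 1.5)
  lob <- 14
  est <- estimate_lod(panels, lob)
  expect_identical(est$method, "classical")
  pools <- split(panels$value, panels$pool_id)
  ns <- lengths(pools)
  f <- sum(ns) - length(pools)
  sd_pooled <- sqrt(sum(vapply(pools, function(p) sum((p - mean(p))^2),
                               numeric(1))) / f)
  c_p <- stats::qnorm(0.95) / (1 - 1 / (4 * f))
  expect_equal(est$lod, lob + c_p * sd_pooled, tolerance = 1e-12)
  expect_gte(est$lod, lob)

  # zero within-pool SD collapses LoD onto LoB
  quiet <- simulate_detection_panels(n_blank_pools = 0, low_cv = 0, seed = 4)
  expect_equal(estimate_lod(quiet, lob = 14, method = "classical")$lod, 14)
})

test_that("variant LoD equals the exhaustive exceedance scan", {
  # heterogeneous pools: multiplicative noise makes SD grow with the mean
  panels <- simulate_detection_panels(n_blank_pools = 0, n_low_pools = 4,
                                      low_means = c(18, 24, 32, 60),
                                      low_cv = 18, seed = 6)
  lob <- 20
  est <- estimate_lod(panels, lob)
  expect_identical(est$method, "nonparametric_variant")
  pools <- split(panels$value, panels$pool_id)
  means <- vapply(pools, mean, numeric(1))
  frac <- vapply(pools, function(p) mean(p > lob), numeric(1))
  expect_equal(est$lod, min(means[frac >= 0.95]), tolerance = 1e-12)

  expect_error(estimate_lod(panels, lob = 1000,
                            method = "nonparametric_variant"),
               "not reached")
})

test_that("LoQ applies the CV rule per lot and the max rule across lots", {
  # three pools x 2 days x 3 reps in one lot, with known CVs via construction
  mk_pool <- function(pid, mean_val, spread, lot) {
    vals <- mean_val + spread * c(-1, 0, 1, -1, 0, 1)
    measurements(pool_id = pid, analyte = "a", value = vals,
                 day = rep(1:2, each = 3), replicate = rep(1:3, 2), lot = lot)
  }
  # sd of c(-1,0,1)*s around mean m gives CV ~ 100*s*0.894/m (n-1 denom)
  lotA <- rbind(mk_pool("p20", 20, 6, "A"),    # CV ~ 27% -> over threshold
                mk_pool("p30", 30, 5, "A"),    # CV ~ 15%
                mk_pool("p40", 40, 4, "A"))    # CV ~  9%
  est <- estimate_loq(lotA)
  expect_equal(est$loq, 30)

  lotB <- rbind(mk_pool("p20", 20, 2, "B"),    # CV ~  9% -> lowest passes
                mk_pool("p30", 30, 5, "B"),
                mk_pool("p40", 40, 4, "B"))
  both <- rbind(lotA, lotB)
  est2 <- estimate_loq(both)
  expect_equal(unname(est2$per_lot_loq), c(30, 20))
  expect_equal(est2$loq, 30)               # max over lots

  # adding a lot can never lower the overall LoQ
  expect_gte(est2$loq, estimate_loq(lotB)$loq)

  # every pool over threshold in a lot -> error naming the lot
  bad <- rbind(mk_pool("p20", 20, 8, "C"), mk_pool("p30", 30, 12, "C"))
  expect_error(estimate_loq(bad), "'C'")
})

test_that("detection_limits flags ordering violations instead of reordering", {
  ok <- detection_limits("valine", lob = 20, lod = 26, loq = 30, lol = 1255)
  expect_true(ok$consistent)
  bad <- detection_limits("x", lob = 30, lod = 26, loq = 30)
  expect_false(bad$consistent)
  expect_match(bad$flags[1], "LoB > LoD")
  expect_equal(bad$lob, 30)                # values left untouched
})

test_that("nonparametric LoB ignores pool identity (pooling property)", {
  p <- simulate_detection_panels(n_low_pools = 0, seed = 8)
  relabeled <- p
  relabeled$pool_id <- "B_all"
  expect_equal(estimate_lob(p, method = "nonparametric")$lob,
               estimate_lob(relabeled, method = "nonparametric")$lob)
})
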