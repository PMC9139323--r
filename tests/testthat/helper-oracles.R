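# Independent oracles used to cross-check the estimators. Each is a
# deliberately plain, loop-based implementation kept separate from the
# package code paths it verifies.

# Exhaustive pairwise-slope Passing-Bablok oracle (shifted-median rule).
pb_oracle <- function(x, y) {
  n <- length(x)
  S <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]; dy <- y[j] - y[i]
      if (dx == 0) {
        if (dy != 0) S <- c(S, sign(dy) * Inf)
      } else {
        S <- c(S, dy / dx)
      }
    }
  }
  S <- S[S != -1]
  S <- sort(S)
  N <- length(S)
  K <- sum(S < -1)
  slope <- if (N %% 2 == 1) S[(N + 1) / 2 + K]
           else mean(S[c(N / 2 + K, N / 2 + 1 + K)])
  list(slope = slope, intercept = stats::median(y - slope * x), N = N, K = K)
}

# Polynomial least squares by explicit normal equations.
polyfit_oracle <- function(x, y, order) {
  X <- outer(x, 0:order, `^`)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# Hand-written balanced nested ANOVA (day > run > replicate), returning the
# variance components from explicit sums of squares.
anova_oracle_single <- function(df) {
  days <- sort(unique(df$day))
  grand <- mean(df$value)
  n <- nrow(df)
  ss_day <- 0; ss_run <- 0; ss_err <- 0
  n_runs <- 0
  for (d in days) {
    dd <- df[df$day == d, ]
    ss_day <- ss_day + nrow(dd) * (mean(dd$value) - grand)^2
    for (r in sort(unique(dd$run))) {
      dr <- dd[dd$run == r, ]
      n_runs <- n_runs + 1
      ss_run <- ss_run + nrow(dr) * (mean(dr$value) - mean(dd$value))^2
      ss_err <- ss_err + sum((dr$value - mean(dr$value))^2)
    }
  }
  D <- length(days)
  ms_day <- ss_day / (D - 1)
  ms_run <- ss_run / (n_runs - D)
  ms_err <- ss_err / (n - n_runs)
  n_rep <- n / n_runs
  n_per_day <- n / D
  list(var_rep = ms_err,
       var_run = max(0, (ms_run - ms_err) / n_rep),
       var_day = max(0, (ms_day - ms_run) / n_per_day),
       grand_mean = grand)
}

# One-sided confidence bound of a simple linear regression mean, from first
# principles (no predict()), and the fine-grid scan for its drift-limit
# crossing.
stability_crossing_oracle <- function(t_obs, y_obs, baseline_mean, horizon,
                                      drift_limit = 10, alpha = 0.05,
                                      step = 1e-3) {
  n <- length(t_obs)
  tb <- mean(t_obs)
  sxx <- sum((t_obs - tb)^2)
  b <- sum((t_obs - tb) * (y_obs - mean(y_obs))) / sxx
  a <- mean(y_obs) - b * tb
  res <- y_obs - (a + b * t_obs)
  s <- sqrt(sum(res^2) / (n - 2))
  tq <- stats::qt(1 - alpha, n - 2)
  upper <- b > 0
  limit <- baseline_mean * (1 + (if (upper) 1 else -1) * drift_limit / 100)
  grid <- seq(0, horizon, by = step)
  se <- s * sqrt(1 / n + (grid - tb)^2 / sxx)
  bound <- (a + b * grid) + (if (upper) tq else -tq) * se
  hit <- if (upper) which(bound >= limit) else which(bound <= limit)
  if (length(hit) == 0) horizon else grid[hit[1]]
}

# Balanced precision-study table builder used by several tests.
sim_single_site <- function(true_mean, cvs, seed, pool_id = "P1") {
  simulate_precision_study(
    study_design("precision_single", list(day = 20, run = 2, replicate = 3)),
    true_mean = true_mean,
    spec = variance_spec(cvs[1], cvs[2], cvs[3]),
    seed = seed, pool_id = pool_id)
}
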