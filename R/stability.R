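# Sample stability (EP25-A style): per-donor ordinary least-squares
# regression of the measurand on storage time, and the drift-limit rule -
# the stability duration is where the one-sided 95% pointwise confidence
# bound of the regression mean crosses the allowed drift limit (+/-10% of the
# baseline mean), or the study horizon when the slope is not significant or
# no crossing occurs within the tested period.

#' Fit the per-donor stability regression
#'
#' Ordinary least squares of value on `timepoint_days` over all replicates of
#' one donor x condition course. The baseline mean is computed from the day-0
#' replicates only (drift limits are anchored to it, not to the regression
#' intercept). A perfectly flat noiseless course has zero residual variance;
#' its slope test is treated as non-significant.
#'
#' @param course measurement `data.frame` for one donor and condition, with
#'   `timepoint_days` set; must contain day 0 plus at least 2 further distinct
#'   timepoints among the ok results.
#' @param max_missing tolerated missing fraction for the course (default 0.10).
#' @return list of class `"stability_fit"`: `donor`, `baseline_mean`, `slope`,
#'   `intercept`, `slope_p_value`, `n_timepoints`, `horizon` (max tested
#'   timepoint), `lm` (the fitted model).
#' @examples
#' course <- simulate_stability_course(baseline = 100, drift_per_day = -1,
#'                                     cv = 1, seed = 3)
#' fit_stability_regression(course)
#' @export
fit_stability_regression <- function(course, max_missing = 0.10) {
  df <- validate_measurements(as.data.frame(course))
  if (all(is.na(df$timepoint_days))) {
    stop("course must carry timepoint_days", call. = FALSE)
  }
  missing_frac <- mean(df$status == "no_result")
  if (missing_frac > max_missing + 1e-12) {
    stop(sprintf("missing data %.1f%% exceeds the %.0f%% allowance",
                 100 * missing_frac, 100 * max_missing), call. = FALSE)
  }
  ok <- df[df$status == "ok", ]
  tps <- sort(unique(ok$timepoint_days))
  if (!0 %in% tps || length(tps) < 3) {
    stop("acceptance rule: the baseline timepoint (t0) plus at least 2 ",
         "further timepoints must be represented", call. = FALSE)
  }
  fit <- stats::lm(value ~ timepoint_days, data = ok)
  sm <- suppressWarnings(summary(fit))  # noiseless courses fit perfectly
  slope <- unname(stats::coef(fit)["timepoint_days"])
  # degenerate zero-residual courses: exact line through the data; the slope
  # is determined without error, so p = 0 unless the course is exactly flat
  if (sm$sigma < 1e-12) {
    p <- if (abs(slope) < 1e-12) 1 else 0
  } else {
    p <- sm$coefficients["timepoint_days", "Pr(>|t|)"]
  }
  structure(list(donor = df$pool_id[1],
                 baseline_mean = mean(ok$value[ok$timepoint_days == 0]),
                 slope = slope,
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 slope_p_value = p, n_timepoints = length(tps),
                 horizon = max(tps), lm = fit),
            class = "stability_fit")
}

#' Stability duration from the drift-limit rule
#'
#' Drift limits are `baseline_mean * (1 +/- drift_limit/100)`. For a
#' statistically significant positive slope (p < 0.05, two-sided) the duration
#' is the smallest time in `[0, horizon]` at which the one-sided upper 95%
#' pointwise confidence bound of the regression mean reaches the upper limit;
#' for a significant negative slope, the lower bound against the lower limit.
#' If the slope is not significant, or the band never reaches the limit within
#' the tested period, the duration is the horizon (the latest tested
#' timepoint). On a noiseless course the band collapses onto the fitted line,
#' so the duration is the exact line crossing. The crossing is solved by
#' bisection to 1e-3 days.
#'
#' @param fit a [fit_stability_regression()] result.
#' @param drift_limit allowed drift as % of the baseline mean (default 10).
#' @param horizon study horizon in days; defaults to the latest tested
#'   timepoint.
#' @param alpha significance level of the slope gate and one-sided band.
#' @return the fit, extended with `duration_days`, `drift_limit`, and
#'   `duration_branch` (`"non_significant"`, `"crossing"`, or
#'   `"no_crossing"`).
#' @export
stability_duration <- function(fit, drift_limit = 10, horizon = fit$horizon,
                               alpha = 0.05) {
  stopifnot(inherits(fit, "stability_fit"))
  if (drift_limit <= 0) stop("drift_limit must be > 0", call. = FALSE)

  if (fit$slope_p_value >= alpha || fit$slope == 0) {
    fit$duration_days <- horizon
    fit$duration_branch <- "non_significant"
  } else {
    upper <- fit$slope > 0
    limit <- fit$baseline_mean * (1 + (if (upper) 1 else -1) * drift_limit / 100)
    bound <- function(t) {
      pr <- stats::predict(fit$lm, newdata = data.frame(timepoint_days = t),
                           se.fit = TRUE)
      tq <- stats::qt(1 - alpha, df = fit$lm$df.residual)
      if (upper) pr$fit + tq * pr$se.fit else pr$fit - tq * pr$se.fit
    }
    crossed <- function(t) if (upper) bound(t) >= limit else bound(t) <= limit
    # the bound need not be monotone (the band narrows toward the mean
    # timepoint), so scan a grid for the first crossing, then bisect
    grid <- seq(0, horizon, length.out = 1025)
    hit <- which(crossed(grid))[1]
    if (is.na(hit)) {
      fit$duration_days <- horizon
      fit$duration_branch <- "no_crossing"
    } else if (hit == 1) {
      fit$duration_days <- 0
      fit$duration_branch <- "crossing"
    } else {
      lo <- grid[hit - 1]; hi <- grid[hit]
      while (hi - lo > 1e-3) {
        mid <- (lo + hi) / 2
        if (crossed(mid)) hi <- mid else lo <- mid
      }
      fit$duration_days <- hi
      fit$duration_branch <- "crossing"
    }
  }
  fit$drift_limit <- drift_limit
  fit
}

#' Stability summary over donors
#'
#' Runs the per-donor regression and duration rule for every donor in a
#' condition and reports the per-donor table plus the overall stability
#' duration (the minimum over donors).
#'
#' @param courses measurement `data.frame` with one `pool_id` per donor.
#' @param drift_limit,horizon,alpha passed to [stability_duration()].
#' @return list of class `"stability_summary"`: `per_donor` data.frame with
#'   columns donor, baseline_mean, slope, intercept, slope_p_value,
#'   duration_days, branch; `overall_duration`.
#' @export
stability_summary <- function(courses, drift_limit = 10, horizon = NULL,
                              alpha = 0.05) {
  df <- validate_measurements(as.data.frame(courses))
  donors <- unique(df$pool_id)
  rows <- lapply(donors, function(d) {
    fit <- fit_stability_regression(df[df$pool_id == d, ])
    fit <- stability_duration(fit, drift_limit = drift_limit,
                              horizon = if (is.null(horizon)) fit$horizon
                                        else horizon,
                              alpha = alpha)
    data.frame(donor = d, baseline_mean = fit$baseline_mean,
               slope = fit$slope, intercept = fit$intercept,
               slope_p_value = fit$slope_p_value,
               duration_days = fit$duration_days,
               branch = fit$duration_branch, stringsAsFactors = FALSE)
  })
  per_donor <- do.call(rbind, rows)
  structure(list(per_donor = per_donor,
                 overall_duration = min(per_donor$duration_days)),
            class = "stability_summary")
}
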