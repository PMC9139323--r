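# Method comparison (trueness): Passing-Bablok regression with rank-based
# confidence intervals, acceptance verdicts against analyte-specific slope
# tolerances, and spike-recovery analysis for analytes without a reference
# method.

#' Passing-Bablok regression
#'
#' Nonparametric method-comparison regression: the slope is the shifted
#' median of all pairwise slopes `S_ij = (y_j - y_i)/(x_j - x_i)` (i < j),
#' excluding slopes exactly equal to -1 and pairs with identical x and y;
#' pairs with equal x but different y contribute infinite-magnitude slopes of
#' the appropriate sign. The shift is `K`, the number of slopes below -1,
#' which makes the estimator invariant to swapping the two methods. The
#' intercept is `median(y - slope * x)`. Confidence intervals use the classic
#' rank-based normal approximation.
#'
#' @param x,y paired measurements of the two methods (n >= 3, finite).
#' @param conf_level confidence level for the slope/intercept intervals.
#' @return list of class `"pb_fit"`: `slope`, `intercept`, `slope_ci`,
#'   `intercept_ci`, `pearson_r`, `n`, `n_slopes`, `K`.
#' @examples
#' x <- c(1, 2, 3, 4, 5, 6, 7, 8)
#' passing_bablok(x, 2 * x + 1)
#' @export
passing_bablok <- function(x, y, conf_level = 0.95) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired finite values", call. = FALSE)
  if (length(unique(x)) == 1) stop("degenerate abscissa: all x equal",
                                   call. = FALSE)
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  s <- ifelse(dx != 0, dy / dx, ifelse(dy == 0, NA_real_, sign(dy) * Inf))
  s <- s[!is.na(s) & s != -1]
  s <- sort(s)                          # Inf sorts last, -Inf first
  N <- length(s)
  if (N == 0) stop("no valid pairwise slopes", call. = FALSE)
  K <- sum(s < -1)
  shifted_median <- function(v, offset) {
    m <- length(v)
    if (m %% 2 == 1) v[min(max((m + 1) / 2 + offset, 1), m)]
    else mean(v[c(min(max(m / 2 + offset, 1), m),
                  min(max(m / 2 + 1 + offset, 1), m))])
  }
  slope <- shifted_median(s, K)
  intercept <- stats::median(y - slope * x)
  z <- stats::qnorm((1 + conf_level) / 2)
  C <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round((N - C) / 2)
  M2 <- N - M1 + 1
  lo <- s[min(max(M1 + K, 1), N)]
  hi <- s[min(max(M2 + K, 1), N)]
  slope_ci <- c(lo, hi)
  intercept_ci <- c(stats::median(y - hi * x), stats::median(y - lo * x))
  structure(list(slope = slope, intercept = intercept, slope_ci = slope_ci,
                 intercept_ci = intercept_ci,
                 pearson_r = stats::cor(x, y), n = n, n_slopes = N, K = K),
            class = "pb_fit")
}

#' @export
print.pb_fit <- function(x, ...) {
  cat(sprintf("Passing-Bablok: %s; r = %.3f (n = %d)\n",
              format_pb_equation(x), x$pearson_r, x$n))
  cat(sprintf("  slope 95%% CI [%.4f, %.4f]\n", x$slope_ci[1], x$slope_ci[2]))
  invisible(x)
}

# "y = 1.028x - 5.364" style equation string (2-3 significant decimals).
format_pb_equation <- function(fit) {
  b <- fit$slope; a <- fit$intercept
  sprintf("y = %.3fx %s %.3f", b, if (a < 0) "−" else "+", abs(a))
}

#' Trueness verdict from a method-comparison fit
#'
#' Accepts when the Passing-Bablok slope lies within `1 +/- slope_tolerance`
#' and the Pearson correlation is at least `r_threshold`. Tolerances are
#' resolved per analyte from `criteria` (default: 0.15 for creatinine and
#' myo-inositol, 0.075 for valine; r threshold 0.90 for all).
#'
#' @param fit a [passing_bablok()] result.
#' @param analyte analyte name used to look up the tolerance.
#' @param criteria named list per analyte with `slope_tolerance` and
#'   `r_threshold`.
#' @return list of class `"trueness_verdict"`: `analyte`, `slope_tolerance`,
#'   `r_threshold`, `pass_flag`, `reasons`.
#' @examples
#' f <- passing_bablok(1:10, 1.03 * (1:10) - 0.2)
#' assess_trueness(f, "creatinine")
#' @export
assess_trueness <- function(fit, analyte,
                            criteria = default_trueness_criteria()) {
  stopifnot(inherits(fit, "pb_fit"))
  if (!analyte %in% names(criteria)) {
    stop("no trueness tolerance configured for analyte '", analyte, "'",
         call. = FALSE)
  }
  cr <- criteria[[analyte]]
  reasons <- character(0)
  if (abs(fit$slope - 1) > cr$slope_tolerance + 1e-12) {
    reasons <- c(reasons, sprintf(
      "slope %.3f outside 1 ± %.3f", fit$slope, cr$slope_tolerance))
  }
  if (fit$pearson_r < cr$r_threshold) {
    reasons <- c(reasons, sprintf("r %.3f below %.2f",
                                  fit$pearson_r, cr$r_threshold))
  }
  structure(list(analyte = analyte, slope_tolerance = cr$slope_tolerance,
                 r_threshold = cr$r_threshold,
                 pass_flag = length(reasons) == 0, reasons = reasons),
            class = "trueness_verdict")
}

#' @rdname assess_trueness
#' @export
default_trueness_criteria <- function() {
  list(
    creatinine = list(slope_tolerance = 0.15, r_threshold = 0.90),
    myo_inositol = list(slope_tolerance = 0.15, r_threshold = 0.90),
    valine = list(slope_tolerance = 0.075, r_threshold = 0.90)
  )
}

#' Spike-recovery analysis
#'
#' For analytes without a reference method: each sample is split into a
#' mock-spiked aliquot and an aliquot spiked with a known added amount.
#' Per-pair recovery is `(spiked - mock) / added * 100` (%), and trueness is
#' summarised by a Passing-Bablok regression of the observed spiked results
#' on the expected values `mock + added`.
#'
#' @param mock_results,spiked_results,added equal-length aligned numeric
#'   vectors; `added` strictly positive.
#' @return list of class `"spike_recovery"`: `table` (per-pair mock, added,
#'   spiked, expected, recovery %), `mean_recovery`, `fit` (the
#'   Passing-Bablok regression of spiked on expected).
#' @examples
#' spike_recovery(mock_results = c(0.10, 0.12, 0.15, 0.2),
#'                spiked_results = c(0.20, 0.23, 0.24, 0.31),
#'                added = c(0.10, 0.10, 0.10, 0.10))
#' @export
spike_recovery <- function(mock_results, spiked_results, added) {
  n <- length(mock_results)
  if (length(spiked_results) != n || length(added) != n) {
    stop("mock, spiked and added must be aligned and equal length",
         call. = FALSE)
  }
  if (any(added <= 0)) stop("added amounts must be > 0", call. = FALSE)
  recovery <- (spiked_results - mock_results) / added * 100
  expected <- mock_results + added
  fit <- passing_bablok(expected, spiked_results)
  structure(list(table = data.frame(mock = mock_results, added = added,
                                    spiked = spiked_results,
                                    expected = expected, recovery = recovery),
                 mean_recovery = mean(recovery), fit = fit),
            class = "spike_recovery")
}
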