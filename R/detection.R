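# Detection capability (EP17-A2 style): LoB from blank panels, LoD from
# low-level panels (classical pooled-SD path when Cochran's C accepts variance
# homogeneity, nonparametric variant path otherwise), LoQ as the lowest pool
# mean with within-laboratory CV below threshold, maximised over reagent lots.

#' Estimate the limit of blank
#'
#' LoB is the highest result plausibly produced by an analyte-free sample at
#' false-positive rate `alpha`. Parametric: `mean_B + z_{1-alpha} * sd_B`.
#' Nonparametric: the value at fractional rank `0.5 + B * (1 - alpha)` in the
#' sorted blanks (linear interpolation between adjacent order statistics).
#' In `"auto"` mode the nonparametric path is taken when a Shapiro-Wilk test
#' rejects normality of the pooled blanks at 0.05.
#'
#' @param blanks measurement `data.frame` of blank-pool results, or a numeric
#'   vector. All blank pools are pooled; at least 20 ok results are required.
#' @param alpha false-positive rate (default 0.05).
#' @param method `"auto"`, `"parametric"` or `"nonparametric"`.
#' @return list of class `"lob_estimate"`: `lob`, `method` (the method
#'   actually used), `n`, and for auto mode the normality p-value.
#' @examples
#' estimate_lob(rnorm(45, 10, 2), method = "parametric")
#' @export
estimate_lob <- function(blanks, alpha = 0.05,
                         method = c("auto", "parametric", "nonparametric")) {
  method <- match.arg(method)
  x <- if (is.data.frame(blanks)) ok_values(validate_measurements(blanks))
       else as.numeric(blanks[!is.na(blanks)])
  if (length(x) < 20) {
    stop("at least 20 blank results are required", call. = FALSE)
  }
  shapiro_p <- NA_real_
  if (method == "auto") {
    # shapiro.test needs non-degenerate data; constant blanks are trivially
    # non-Gaussian but either path returns the constant.
    shapiro_p <- if (stats::sd(x) == 0) 0 else stats::shapiro.test(x)$p.value
    method <- if (shapiro_p < 0.05) "nonparametric" else "parametric"
  }
  lob <- if (method == "parametric") {
    mean(x) + stats::qnorm(1 - alpha) * stats::sd(x)
  } else {
    rank_quantile(x, 0.5 + length(x) * (1 - alpha))
  }
  structure(list(lob = lob, method = method, n = length(x),
                 shapiro_p = shapiro_p, alpha = alpha),
            class = "lob_estimate")
}

# Value at a fractional rank position in sorted data, linearly interpolating
# between adjacent order statistics; positions are clamped to [1, n].
rank_quantile <- function(x, pos) {
  s <- sort(x)
  n <- length(s)
  pos <- min(max(pos, 1), n)
  lo <- floor(pos); hi <- ceiling(pos)
  if (lo == hi) s[lo] else s[lo] + (pos - lo) * (s[hi] - s[lo])
}

#' Cochran's C test for variance homogeneity
#'
#' Tests whether the largest of `k` group variances is an outlying share of
#' their sum: `C = max(s_i^2) / sum(s_i^2)`. The upper critical value at level
#' `alpha` uses the closed form
#' `C_crit = 1 / (1 + (k - 1) / qf(1 - alpha/k, df, (k - 1) df))`.
#' The test passes (homogeneity accepted) iff `C <= C_crit`.
#'
#' @param group_variances numeric vector of group variances (>= 0, not all 0).
#' @param df_per_group degrees of freedom per group (replicates - 1).
#' @param alpha significance level.
#' @return list of class `"cochran_result"`: `statistic`, `critical_value`,
#'   `n_groups`, `df_per_group`, `pass_flag`.
#' @examples
#' cochran_c_test(c(1, 1.2, 0.9, 1.1), df_per_group = 10)
#' @export
cochran_c_test <- function(group_variances, df_per_group, alpha = 0.05) {
  v <- as.numeric(group_variances)
  if (length(v) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(v < 0)) stop("variances must be >= 0", call. = FALSE)
  if (all(v == 0)) stop("degenerate variances: all groups have zero variance",
                        call. = FALSE)
  k <- length(v)
  statistic <- max(v) / sum(v)
  fq <- stats::qf(1 - alpha / k, df_per_group, (k - 1) * df_per_group)
  critical <- 1 / (1 + (k - 1) / fq)
  structure(list(statistic = statistic, critical_value = critical,
                 n_groups = k, df_per_group = df_per_group,
                 pass_flag = statistic <= critical, alpha = alpha),
            class = "cochran_result")
}

#' Estimate the limit of detection
#'
#' Classical path (when Cochran's C accepts variance homogeneity across the
#' low-level pools): `LoD = LoB + c_p * SD_pooled`, where `SD_pooled` is the
#' pooled within-pool SD and `c_p = z_{1-beta} / (1 - 1/(4f))` with
#' `beta = alpha` and `f = N - k` total degrees of freedom. Variant path (when
#' the homogeneity check fails): the lowest pool mean concentration at which
#' at least `1 - alpha` of that pool's results exceed the LoB.
#'
#' @param low_panels measurement `data.frame` of low-level pools (grouped by
#'   `pool_id`); at least 2 pools with >= 20 ok results each.
#' @param lob the limit of blank (number or [estimate_lob()] result).
#' @param alpha type-II rate beta for the classical path and the exceedance
#'   complement for the variant path (default 0.05).
#' @param method `"auto"` (Cochran decides), `"classical"` or
#'   `"nonparametric_variant"`.
#' @return list of class `"lod_estimate"`: `lod`, `method`, `cochran`
#'   (the homogeneity test result), `sd_pooled`, `c_p`, `per_pool` diagnostics.
#' @export
estimate_lod <- function(low_panels, lob, alpha = 0.05,
                         method = c("auto", "classical",
                                    "nonparametric_variant")) {
  method <- match.arg(method)
  if (inherits(lob, "lob_estimate")) lob <- lob$lob
  df <- validate_measurements(as.data.frame(low_panels))
  df <- df[df$status == "ok", ]
  pools <- split(df$value, df$pool_id)
  if (length(pools) < 2) stop("need at least 2 low-level pools", call. = FALSE)
  if (any(lengths(pools) < 20)) {
    stop("each low-level pool needs at least 20 results", call. = FALSE)
  }
  means <- vapply(pools, mean, numeric(1))
  vars <- vapply(pools, stats::var, numeric(1))
  ns <- lengths(pools)
  # all-zero variances are trivially homogeneous; Cochran needs spread
  cochran <- if (all(vars == 0)) NULL
             else cochran_c_test(vars, df_per_group = round(mean(ns - 1)),
                                 alpha = 0.05)
  if (method == "auto") {
    method <- if (is.null(cochran) || cochran$pass_flag) "classical"
              else "nonparametric_variant"
  }
  if (method == "classical") {
    f <- sum(ns) - length(pools)
    sd_pooled <- sqrt(sum((ns - 1) * vars) / f)
    c_p <- stats::qnorm(1 - alpha) / (1 - 1 / (4 * f))
    lod <- lob + c_p * sd_pooled
    per_pool <- data.frame(pool_id = names(pools), mean = means, sd = sqrt(vars),
                           n = ns, row.names = NULL)
  } else {
    exceed <- vapply(pools, function(x) mean(x > lob), numeric(1))
    per_pool <- data.frame(pool_id = names(pools), mean = means,
                           sd = sqrt(vars), n = ns,
                           frac_above_lob = exceed, row.names = NULL)
    qualifying <- means[exceed >= 1 - alpha]
    if (length(qualifying) == 0) {
      stop("LoD not reached within tested range: no pool has >= ",
           100 * (1 - alpha), "% of results above LoB", call. = FALSE)
    }
    lod <- min(qualifying)
    sd_pooled <- NA_real_; c_p <- NA_real_
  }
  structure(list(lod = lod, method = method, lob = lob, cochran = cochran,
                 sd_pooled = sd_pooled, c_p = c_p, per_pool = per_pool),
            class = "lod_estimate")
}

#' Estimate the limit of quantification
#'
#' Per reagent lot, the LoQ is the minimum pool mean concentration whose
#' within-laboratory precision (day-nested CV%, computed by the precision
#' estimator on that pool's day/replicate structure within the lot) is below
#' `cv_threshold`. The overall LoQ is the maximum of the per-lot LoQs.
#'
#' @param low_panels measurement `data.frame` with `pool_id`, `lot`, `day`,
#'   `replicate`; each pool must span >= 2 days within each lot.
#' @param cv_threshold within-laboratory CV% threshold (default 20).
#' @return list of class `"loq_estimate"`: `loq` (overall), `per_lot_loq`
#'   (named numeric), `per_pool` (mean and CV per pool x lot).
#' @export
estimate_loq <- function(low_panels, cv_threshold = 20) {
  df <- validate_measurements(as.data.frame(low_panels))
  df <- df[df$status == "ok", ]
  if (all(is.na(df$lot))) df$lot <- "lot1"
  lots <- sort(unique(df$lot))
  rows <- list()
  per_lot <- stats::setNames(rep(NA_real_, length(lots)), lots)
  for (lt in lots) {
    dl <- df[df$lot == lt, ]
    pools <- sort(unique(dl$pool_id))
    for (p in pools) {
      dp <- dl[dl$pool_id == p, ]
      if (length(unique(dp$day)) < 2) {
        stop(sprintf("pool '%s' in lot '%s' spans fewer than 2 days", p, lt),
             call. = FALSE)
      }
      cvw <- within_lab_cv_day_nested(dp)
      rows[[length(rows) + 1]] <- data.frame(
        lot = lt, pool_id = p, mean = mean(dp$value), cv_within_lab = cvw,
        stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows[vapply(rows, function(r) r$lot == lt, logical(1))])
    under <- tab[tab$cv_within_lab < cv_threshold, ]
    if (nrow(under) == 0) {
      stop(sprintf("no pool in lot '%s' reaches within-laboratory CV < %g%%",
                   lt, cv_threshold), call. = FALSE)
    }
    per_lot[lt] <- min(under$mean)
  }
  structure(list(loq = max(per_lot), per_lot_loq = per_lot,
                 per_pool = do.call(rbind, rows),
                 cv_threshold = cv_threshold),
            class = "loq_estimate")
}

# Within-laboratory CV from a day-nested design (day + replicate, no run):
# sqrt(cv_repeatability^2 + cv_between_day^2) by method of moments.
within_lab_cv_day_nested <- function(dp) {
  value <- dp$value
  day <- factor(dp$day)
  n <- length(value)
  gm <- mean(value)
  dm <- tapply(value, day, mean)
  ss_e <- sum((value - dm[day])^2)
  df_e <- n - nlevels(day)
  ms_e <- if (df_e > 0) ss_e / df_e else 0
  dms <- nested_ms(value, day)
  n_per_day <- n / nlevels(day)
  var_day <- max(0, (dms$ms - ms_e) / n_per_day)
  100 * sqrt(ms_e + var_day) / gm
}

#' Assemble detection limits for one analyte
#'
#' Merges the LoB/LoD/LoQ estimates (and the upper limit of the linear range,
#' LoL, produced by the linearity stage) into one record, asserting the
#' ordering `LoB <= LoD <= LoQ`. A violated ordering is reported as a flagged
#' inconsistency, never silently reordered.
#'
#' @param analyte analyte name.
#' @param lob,lod,loq estimates (numbers or the corresponding estimate
#'   objects).
#' @param lol optional upper limit of the linear range.
#' @return list of class `"detection_limits"` with fields `analyte`, `lob`,
#'   `lod`, `loq`, `lol`, `lob_method`, `lod_method`, `per_lot_loq`,
#'   `consistent`, `flags`.
#' @export
detection_limits <- function(analyte, lob, lod, loq, lol = NA_real_) {
  lob_method <- NA_character_; lod_method <- NA_character_
  per_lot <- NULL
  if (inherits(lob, "lob_estimate")) { lob_method <- lob$method; lob <- lob$lob }
  if (inherits(lod, "lod_estimate")) {
    lod_method <- if (lod$method == "classical") "classical"
                  else "nonparametric_variant"
    lod <- lod$lod
  }
  if (inherits(loq, "loq_estimate")) { per_lot <- loq$per_lot_loq; loq <- loq$loq }
  flags <- character(0)
  if (lob > lod + 1e-9) flags <- c(flags, "inconsistent: LoB > LoD")
  if (lod > loq + 1e-9) flags <- c(flags, "inconsistent: LoD > LoQ")
  structure(list(analyte = analyte, lob = lob, lod = lod, loq = loq, lol = lol,
                 lob_method = lob_method, lod_method = lod_method,
                 per_lot_loq = per_lot, consistent = length(flags) == 0,
                 flags = flags),
            class = "detection_limits")
}

#' @export
print.detection_limits <- function(x, ...) {
  cat(sprintf("Detection limits for %s\n", x$analyte))
  cat(sprintf("  LoB %.3g (%s)  LoD %.3g (%s)  LoQ %.3g  LoL %s\n",
              x$lob, x$lob_method, x$lod, x$lod_method, x$loq,
              if (is.na(x$lol)) "n.a." else sprintf("<%.3g", x$lol)))
  if (!x$consistent) cat("  FLAGS:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
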