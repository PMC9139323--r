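# Linearity assessment of a dilution series (EP6-A style): Pearson
# correlation and per-level repeatability on all replicate points, a
# first/second/third-order polynomial hierarchy with t-tests on the
# non-linear coefficients, the relative degree of non-linearity for the
# best-fitting non-linear model, and the composite pass rule.

series_frame <- function(series) {
  df <- as.data.frame(series)
  if (!"assigned" %in% names(df)) {
    stop("series must carry an 'assigned' column of nominal concentrations",
         call. = FALSE)
  }
  df <- validate_measurements(df[, c(MEASUREMENT_COLUMNS, "assigned")])
  df
}

#' Fit the polynomial hierarchy to a dilution series
#'
#' Ordinary least-squares fits of orders 1-3 of measured value on assigned
#' concentration, over all replicate points. Returns the coefficients of each
#' order together with the two-sided t-test p-values of the non-linear
#' coefficients: `b2` from the order-2 model and `b3` from the order-3 model.
#' An order with fewer than `p + 2` distinct levels available is skipped (no
#' residual degrees of freedom for the coefficient test) with a logged reason.
#'
#' @param series measurement `data.frame` with an `assigned` column (as
#'   produced by [simulate_linearity_series()]), or a data.frame with columns
#'   `assigned` and `value`.
#' @return list of class `"polynomial_hierarchy"`: per-order `fits` (each with
#'   `coefficients`, `sigma` = residual standard error, `p_values`),
#'   `nonlinear_p_values` (named `b2`, `b3`), `skipped` reasons.
#' @export
fit_polynomial_hierarchy <- function(series) {
  df <- if (is.data.frame(series) && all(c("assigned", "value") %in% names(series)) &&
            !all(MEASUREMENT_COLUMNS %in% names(series))) {
    data.frame(assigned = series$assigned, value = series$value,
               status = "ok", stringsAsFactors = FALSE)
  } else series_frame(series)
  df <- df[df$status == "ok" & !is.na(df$value), ]
  n_levels <- length(unique(df$assigned))
  if (n_levels < 5) {
    stop("need at least 5 distinct levels with results", call. = FALSE)
  }
  fits <- list(); skipped <- character(0)
  for (p in 1:3) {
    if (n_levels < p + 2) {
      skipped <- c(skipped, sprintf(
        "order %d skipped: %d distinct level(s), need %d", p, n_levels, p + 2))
      next
    }
    fml <- switch(p,
                  value ~ assigned,
                  value ~ assigned + I(assigned^2),
                  value ~ assigned + I(assigned^2) + I(assigned^3))
    fit <- stats::lm(fml, data = df)
    sm <- suppressWarnings(summary(fit))  # noiseless series fit perfectly
    co <- stats::coef(fit)
    names(co) <- paste0("b", seq_along(co) - 1)
    pv <- sm$coefficients[, "Pr(>|t|)"]
    names(pv) <- names(co)
    fits[[paste0("order", p)]] <- list(order = p, coefficients = co,
                                       sigma = sm$sigma, p_values = pv,
                                       fit = fit)
  }
  nl <- c(b2 = if (!is.null(fits$order2)) unname(fits$order2$p_values["b2"])
               else NA_real_,
          b3 = if (!is.null(fits$order3)) unname(fits$order3$p_values["b3"])
               else NA_real_)
  structure(list(fits = fits, nonlinear_p_values = nl, skipped = skipped),
            class = "polynomial_hierarchy")
}

#' Assess linearity of a dilution series
#'
#' Applies the composite rule: the series is linear when, over a stretch of at
#' least `min_levels` consecutive dilution levels, missing data is at most
#' `missing_max`, the Pearson correlation of all replicate points with the
#' assigned concentration is at least `r_min`, per-level repeatability CV is
#' below `cv_max`, and either no non-linear polynomial coefficient is
#' significant at `alpha` or the maximum relative degree of non-linearity —
#' `max over levels of |best nonlinear fit - linear fit| / |linear fit| * 100`,
#' with the best non-linear model chosen by smaller residual standard error
#' (ties toward the lower order) — is below `nonlinearity_max`. The upper
#' limit of the linear range (LoL) is the highest assigned concentration in
#' the longest consecutive stretch of passing levels.
#'
#' @param series measurement `data.frame` with `assigned`, `level`, `value`,
#'   `status`.
#' @param r_min minimum Pearson r (default 0.95).
#' @param cv_max per-level repeatability CV% bound (default 15).
#' @param missing_max tolerated missing fraction per level (default 0.15).
#' @param min_levels minimum number of consecutive passing levels (default 5).
#' @param nonlinearity_max tolerated degree of non-linearity in % (default 10).
#' @param alpha significance level for the non-linear coefficient t-tests.
#' @return list of class `"linearity_verdict"`: `pearson_r`, `per_level`
#'   (data.frame with mean, CV, missing fraction, pass), `hierarchy`,
#'   `nonlinear_significant`, `degree_of_nonlinearity` (`NA` when no
#'   non-linear term is significant), `best_nonlinear_order`, `lol`,
#'   `pass_flag`, `reasons`.
#' @examples
#' s <- simulate_linearity_series(curvature = 0, cv = 0, seed = 1)
#' assess_linearity(s)$pass_flag
#' @export
assess_linearity <- function(series, r_min = 0.95, cv_max = 15,
                             missing_max = 0.15, min_levels = 5,
                             nonlinearity_max = 10, alpha = 0.05) {
  df <- series_frame(series)
  ok <- df[df$status == "ok", ]
  if (nrow(ok) == 0) stop("all levels missing", call. = FALSE)
  reasons <- character(0)

  lv <- sort(unique(df$level))
  per_level <- do.call(rbind, lapply(lv, function(l) {
    rows <- df[df$level == l, ]
    v <- ok_values(rows)
    cv <- if (length(v) >= 2 && mean(v) > 0) 100 * stats::sd(v) / mean(v)
          else if (length(v) >= 1) 0 else NA_real_
    data.frame(level = l, assigned = rows$assigned[1],
               n = nrow(rows), n_ok = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               cv = cv, missing = 1 - length(v) / nrow(rows))
  }))
  per_level$pass <- per_level$n_ok > 0 &
    per_level$missing <= missing_max + 1e-12 &
    (is.na(per_level$cv) | per_level$cv < cv_max)

  # longest consecutive stretch of passing levels
  r <- rle(per_level$pass)
  best_len <- 0; best_end <- 0; pos <- 0
  for (i in seq_along(r$lengths)) {
    pos <- pos + r$lengths[i]
    if (r$values[i] && r$lengths[i] > best_len) {
      best_len <- r$lengths[i]; best_end <- pos
    }
  }
  lol <- if (best_len > 0) max(per_level$assigned[(best_end - best_len + 1):best_end])
         else NA_real_

  pearson_r <- stats::cor(ok$assigned, ok$value)
  hier <- fit_polynomial_hierarchy(df)
  nl_p <- hier$nonlinear_p_values
  nonlinear_significant <- any(!is.na(nl_p) & nl_p < alpha)

  degree <- NA_real_; best_order <- NA_integer_
  if (nonlinear_significant) {
    cand <- hier$fits[intersect(c("order2", "order3"), names(hier$fits))]
    sig <- vapply(cand, function(f) f$sigma, numeric(1))
    best <- cand[[which.min(sig)]]   # which.min ties toward the first = lower order
    best_order <- best$order
    x <- per_level$assigned[per_level$n_ok > 0]
    lin_pred <- stats::predict(hier$fits$order1$fit,
                               newdata = data.frame(assigned = x))
    nl_pred <- stats::predict(best$fit, newdata = data.frame(assigned = x))
    degree <- max(abs(nl_pred - lin_pred) / abs(lin_pred)) * 100
  }

  if (best_len < min_levels) {
    reasons <- c(reasons, sprintf(
      "only %d consecutive passing level(s); at least %d required",
      best_len, min_levels))
  }
  if (pearson_r < r_min) {
    reasons <- c(reasons, sprintf("Pearson r %.4f below %.2f", pearson_r, r_min))
  }
  if (any(!is.na(per_level$cv) & per_level$cv >= cv_max)) {
    reasons <- c(reasons, sprintf("per-level repeatability CV >= %g%%", cv_max))
  }
  if (any(per_level$missing > missing_max + 1e-12)) {
    reasons <- c(reasons, sprintf("missing data above %g%% at some level",
                                  100 * missing_max))
  }
  if (nonlinear_significant && !is.na(degree) && degree >= nonlinearity_max) {
    reasons <- c(reasons, sprintf(
      "degree of non-linearity %.1f%% >= %g%%", degree, nonlinearity_max))
  }

  structure(list(pearson_r = pearson_r, per_level = per_level,
                 hierarchy = hier, nonlinear_significant = nonlinear_significant,
                 degree_of_nonlinearity = degree,
                 best_nonlinear_order = best_order, lol = lol,
                 pass_flag = length(reasons) == 0, reasons = reasons),
            class = "linearity_verdict")
}

#' @export
print.linearity_verdict <- function(x, ...) {
  cat("Linearity:", if (x$pass_flag) "PASS" else "FAIL",
      sprintf("(r = %.4f)\n", x$pearson_r))
  if (!is.na(x$degree_of_nonlinearity)) {
    cat(sprintf("  degree of non-linearity %.2f%% (order-%d model)\n",
                x$degree_of_nonlinearity, x$best_nonlinear_order))
  }
  if (!is.na(x$lol)) cat(sprintf("  upper limit of linear range (LoL): %.4g\n", x$lol))
  if (length(x$reasons) > 0) cat(paste0("  - ", x$reasons, collapse = "\n"), "\n")
  invisible(x)
}
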