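# Nested variance-component precision (EP05-A3 style), expressed as CV%.
#
# Single-site design: day > run(day) > replicate. Multi-site design:
# site > day(site) > replicate (one run per day, so no run factor).
# Estimation is by method-of-moments on the nested ANOVA mean squares, the
# guideline's canonical approach; negative component estimates are truncated
# to zero at the variance scale before conversion to CV%, which is why
# published precision tables can show exact 0.0 entries.

# Mean squares for a one-level grouping: SS between group means (weighted by
# group size) over df = n_groups - n_parents.
nested_ms <- function(value, group, parent = NULL) {
  if (is.null(parent)) parent <- rep(1L, length(value))
  g <- interaction(parent, group, drop = TRUE)
  p <- factor(parent)
  gm <- tapply(value, g, mean)
  gn <- tapply(value, g, length)
  parent_of_g <- tapply(as.integer(p), g, `[`, 1)
  pm <- tapply(value, p, mean)
  ss <- sum(gn * (gm - pm[parent_of_g])^2)
  df <- nlevels(g) - nlevels(p)
  list(ss = ss, df = df, ms = if (df > 0) ss / df else NA_real_,
       mean_size = mean(gn))
}

estimate_components_one <- function(df, mode) {
  ok <- df[df$status == "ok", ]
  value <- ok$value
  n <- length(value)
  grand_mean <- mean(value)

  if (mode == "single") {
    for (f in c("day", "run", "replicate")) {
      if (length(unique(ok[[f]])) < 2 && f != "replicate") {
        stop(sprintf("factor '%s' has a single level; the single-site design expects more", f),
             call. = FALSE)
      }
    }
    day <- factor(ok$day)
    runf <- interaction(ok$day, ok$run, drop = TRUE)
    # error stratum: replicates within (day, run)
    em <- tapply(value, runf, mean)
    ss_e <- sum((value - em[runf])^2)
    df_e <- n - nlevels(runf)
    ms_e <- ss_e / df_e
    run_ms <- nested_ms(value, ok$run, parent = ok$day)
    grand <- nested_ms(value, day)
    n_rep <- n / nlevels(runf)              # mean replicates per run
    n_per_day <- n / nlevels(day)           # mean results per day
    var_rep <- ms_e
    var_run <- max(0, (run_ms$ms - ms_e) / n_rep)
    var_day <- max(0, (grand$ms - run_ms$ms) / n_per_day)
    cv <- function(v) 100 * sqrt(v) / grand_mean
    out <- data.frame(
      pool_id = ok$pool_id[1], grand_mean = grand_mean,
      cv_repeatability = cv(var_rep), cv_between_run = cv(var_run),
      cv_between_day = cv(var_day), cv_between_site = NA_real_,
      cv_within_laboratory = sqrt(cv(var_rep)^2 + cv(var_run)^2 + cv(var_day)^2),
      cv_reproducibility = NA_real_, n_used = n,
      stringsAsFactors = FALSE)
  } else {
    for (f in c("site", "day")) {
      if (length(unique(ok[[f]])) < 2) {
        stop(sprintf("factor '%s' has a single level; the multi-site design expects more", f),
             call. = FALSE)
      }
    }
    site <- factor(ok$site)
    dayf <- interaction(ok$site, ok$day, drop = TRUE)
    em <- tapply(value, dayf, mean)
    ss_e <- sum((value - em[dayf])^2)
    df_e <- n - nlevels(dayf)
    ms_e <- ss_e / df_e
    day_ms <- nested_ms(value, ok$day, parent = ok$site)
    grand <- nested_ms(value, site)
    n_rep <- n / nlevels(dayf)
    n_per_site <- n / nlevels(site)
    var_rep <- ms_e
    var_day <- max(0, (day_ms$ms - ms_e) / n_rep)
    var_site <- max(0, (grand$ms - day_ms$ms) / n_per_site)
    cv <- function(v) 100 * sqrt(v) / grand_mean
    wl <- sqrt(cv(var_rep)^2 + cv(var_day)^2)
    out <- data.frame(
      pool_id = ok$pool_id[1], grand_mean = grand_mean,
      cv_repeatability = cv(var_rep), cv_between_run = NA_real_,
      cv_between_day = cv(var_day), cv_between_site = cv(var_site),
      cv_within_laboratory = wl,
      cv_reproducibility = sqrt(wl^2 + cv(var_site)^2), n_used = n,
      stringsAsFactors = FALSE)
  }
  out
}

#' Estimate nested precision components as CV% per pool
#'
#' Method-of-moments nested ANOVA. In single-site mode the components are
#' repeatability (within-run), between-run, and between-day; their
#' root-sum-of-squares is the within-laboratory CV. In multi-site mode (one
#' run per day) they are repeatability, between-day, and between-site;
#' within-laboratory combines repeatability and between-day, and
#' reproducibility additionally folds in the between-site component. The
#' grand mean is the unweighted mean of all ok results in the pool; CVs are
#' 100 * sigma / grand mean. Negative variance estimates (sampling noise can
#' push a mean-square difference below zero) are truncated to 0.
#'
#' @param data measurement `data.frame` covering one or more pools.
#' @param mode `"single"` (day/run/replicate) or `"multi"`
#'   (site/day/replicate).
#' @param design optional [study_design()]; when given, [check_design()] must
#'   pass before estimation.
#' @return `data.frame` of class `"precision_estimate"`, one row per pool,
#'   with columns `pool_id`, `grand_mean`, `cv_repeatability`,
#'   `cv_between_run`, `cv_between_day`, `cv_between_site`,
#'   `cv_within_laboratory`, `cv_reproducibility`, `n_used`. Inapplicable
#'   components are `NA`.
#' @examples
#' d <- simulate_precision_study(true_mean = 80,
#'                               spec = variance_spec(3, 1.5, 2), seed = 11)
#' estimate_components(d)
#' @export
estimate_components <- function(data, mode = c("single", "multi"),
                                design = NULL) {
  mode <- match.arg(mode)
  data <- validate_measurements(as.data.frame(data))
  if (!is.null(design)) {
    chk <- check_design(data, design)
    if (!chk$pass_flag) {
      stop("design check failed: ", paste(chk$reasons, collapse = "; "),
           call. = FALSE)
    }
  }
  pools <- unique(data$pool_id)
  out <- do.call(rbind, lapply(pools, function(p) {
    estimate_components_one(data[data$pool_id == p, ], mode)
  }))
  rownames(out) <- NULL
  class(out) <- c("precision_estimate", class(out))
  out
}

#' Combine CV% components by root-sum-of-squares
#'
#' Within-laboratory precision is the quadratic combination of its nested
#' components over a common mean: `sqrt(sum(components^2))`. Aggregation is
#' done on unrounded components; rounding (one decimal, half away from zero)
#' belongs to report rendering.
#'
#' @param components numeric vector of nonnegative CV percentages.
#' @return combined CV%.
#' @examples
#' aggregate_cv(c(2.8, 1.3, 2.4))  # 3.9 at one decimal
#' @export
aggregate_cv <- function(components) {
  components <- components[!is.na(components)]
  if (any(components < 0)) stop("CV components must be >= 0", call. = FALSE)
  sqrt(sum(components^2))
}

# Round half away from zero (report convention; base round() is half-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
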