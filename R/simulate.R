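# Synthetic study generators. Each emulates one of the supported validation
# designs with the statistical structure its estimator assumes, so the whole
# pipeline is exercisable without instrument data. All generators are
# seed-reproducible bit-for-bit and truncate values at zero (concentrations
# are nonnegative); truncation events are reported via an attribute.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

truncate_at_zero <- function(df) {
  clipped <- !is.na(df$value) & df$value < 0
  df$value[clipped] <- 0
  attr(df, "n_truncated") <- sum(clipped)
  df
}

#' Variance component specification for precision simulations
#'
#' CV% of each hierarchical effect: pure replicate noise (repeatability),
#' a shared run effect, a shared day effect, and (multi-site designs) a shared
#' site effect. Effects are additive on the relative scale, i.e. the simulated
#' value is `true_mean * (1 + site + day + run + e)` with independent zero-mean
#' Gaussian effects whose standard deviations are CV/100.
#'
#' @param cv_repeatability,cv_between_run,cv_between_day,cv_between_site
#'   nonnegative CV percentages.
#' @return list of class `"variance_spec"`.
#' @export
variance_spec <- function(cv_repeatability = 3, cv_between_run = 1.5,
                          cv_between_day = 2, cv_between_site = 0) {
  v <- c(cv_repeatability, cv_between_run, cv_between_day, cv_between_site)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("all CV components must be finite and >= 0", call. = FALSE)
  }
  structure(list(cv_repeatability = cv_repeatability,
                 cv_between_run = cv_between_run,
                 cv_between_day = cv_between_day,
                 cv_between_site = cv_between_site),
            class = "variance_spec")
}

#' Simulate a nested precision study
#'
#' Generates one pool's measurements under a hierarchical design. The
#' single-site layout is 20 days x 2 runs/day x 3 replicates (480 results over
#' 4 pools when combined); the multi-site layout is 3 sites x 5 days x 1
#' run/day x 6 replicates. Day effects are shared within a day, run effects
#' within a run, site effects within a site; replicate noise is independent.
#'
#' @param design a [study_design()] of kind `"precision_single"` (factors
#'   `day`, `run`, `replicate`) or `"precision_multi"` (factors `site`, `day`,
#'   `replicate`); defaults to the 20 x 2 x 3 single-site layout.
#' @param true_mean positive true level (analyte or score units).
#' @param spec a [variance_spec()].
#' @param seed integer seed; fixed seed gives identical output.
#' @param pool_id,analyte labels for the generated rows.
#' @return measurement `data.frame`; attribute `n_truncated` counts values
#'   clipped at zero.
#' @examples
#' d <- simulate_precision_study(true_mean = 80,
#'                               spec = variance_spec(3, 1.5, 2), seed = 7)
#' estimate_components(d)
#' @export
simulate_precision_study <- function(design = study_design("precision_single",
                                       list(day = 20, run = 2, replicate = 3)),
                                     true_mean = 80,
                                     spec = variance_spec(),
                                     seed = NULL,
                                     pool_id = "P1", analyte = "gfr_score") {
  stopifnot(inherits(design, "study_design"), inherits(spec, "variance_spec"))
  if (true_mean <= 0) stop("true_mean must be positive", call. = FALSE)
  cnt <- design$expected_counts
  multi <- design$study_kind == "precision_multi"
  with_seed(seed, {
    if (multi) {
      n_site <- cnt$site %||% 3; n_day <- cnt$day %||% 5
      n_rep <- cnt$replicate %||% 6
      grid <- expand.grid(replicate = seq_len(n_rep), day = seq_len(n_day),
                          site = seq_len(n_site))
      s_eff <- stats::rnorm(n_site, 0, spec$cv_between_site / 100)
      d_eff <- stats::rnorm(n_site * n_day, 0, spec$cv_between_day / 100)
      day_idx <- (grid$site - 1) * n_day + grid$day
      e <- stats::rnorm(nrow(grid), 0, spec$cv_repeatability / 100)
      rel <- s_eff[grid$site] + d_eff[day_idx] + e
      df <- measurements(pool_id = pool_id, analyte = analyte,
                         value = true_mean * (1 + rel),
                         site = paste0("S", grid$site), day = grid$day,
                         run = 1L, replicate = grid$replicate)
    } else {
      n_day <- cnt$day %||% 20; n_run <- cnt$run %||% 2
      n_rep <- cnt$replicate %||% 3
      grid <- expand.grid(replicate = seq_len(n_rep), run = seq_len(n_run),
                          day = seq_len(n_day))
      d_eff <- stats::rnorm(n_day, 0, spec$cv_between_day / 100)
      r_eff <- stats::rnorm(n_day * n_run, 0, spec$cv_between_run / 100)
      run_idx <- (grid$day - 1) * n_run + grid$run
      e <- stats::rnorm(nrow(grid), 0, spec$cv_repeatability / 100)
      rel <- d_eff[grid$day] + r_eff[run_idx] + e
      df <- measurements(pool_id = pool_id, analyte = analyte,
                         value = true_mean * (1 + rel),
                         day = grid$day, run = grid$run,
                         replicate = grid$replicate)
    }
    truncate_at_zero(df)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a linearity dilution series
#'
#' Emulates the linear-intermixture design: `n_levels` equidistant assigned
#' concentrations from `low` to `high` (11 levels in the standard layout),
#' each measured `reps` times. The measured value is the assigned
#' concentration plus a quadratic departure `curvature * (assigned -
#' midpoint)^2`, with multiplicative Gaussian noise at `cv`%.
#'
#' @param low,high concentration range (`high > low >= 0`).
#' @param n_levels number of levels, at least 5.
#' @param reps replicates per level.
#' @param curvature quadratic departure coefficient (0 = perfectly linear).
#' @param cv multiplicative noise CV%.
#' @param seed integer seed.
#' @param pool_id,analyte labels.
#' @return measurement `data.frame` with `level` 0..`n_levels - 1` and an
#'   `assigned` column carrying the nominal concentration.
#' @export
simulate_linearity_series <- function(low = 20, high = 870, n_levels = 11,
                                      reps = 3, curvature = 0, cv = 3,
                                      seed = NULL, pool_id = "LIN",
                                      analyte = "creatinine") {
  if (!(high > low) || low < 0) stop("need high > low >= 0", call. = FALSE)
  if (n_levels < 5) stop("n_levels must be at least 5", call. = FALSE)
  with_seed(seed, {
    lev <- 0:(n_levels - 1)
    assigned <- low + lev * (high - low) / (n_levels - 1)
    mid <- (low + high) / 2
    truth <- assigned + curvature * (assigned - mid)^2
    grid <- expand.grid(replicate = seq_len(reps), level = lev)
    mu <- truth[grid$level + 1]
    value <- mu * (1 + stats::rnorm(nrow(grid), 0, cv / 100))
    df <- measurements(pool_id = pool_id, analyte = analyte, value = value,
                       level = grid$level, replicate = grid$replicate)
    df$assigned <- assigned[grid$level + 1]
    truncate_at_zero(df)
  })
}

#' Simulate blank and low-level detection panels
#'
#' Emulates the detection-capability design: blank pools (analyte-free serum)
#' measured as Gaussian noise around `blank_mean` truncated at zero, and
#' low-level pools with multiplicative noise around `low_means`, replicated
#' across reagent lots and days (the standard layout is 4 pools x 45
#' replicates over 3 days using 3 lots).
#'
#' @param n_blank_pools,n_low_pools number of pools of each kind.
#' @param reps_per_pool replicates per pool, divisible by `lots * days`
#'   (replicates are spread over a crossed lot x day grid).
#' @param lots number of reagent lots.
#' @param days number of measurement days per lot.
#' @param blank_mean,blank_sd Gaussian blank parameters (concentration units).
#' @param low_means vector of true low-pool concentrations, one per low pool.
#' @param low_cv multiplicative CV% for low pools.
#' @param seed integer seed.
#' @param analyte label.
#' @return measurement `data.frame`; blank pools are named `B1..`, low pools
#'   `L1..`; `lot` and `day` annotate the batch structure.
#' @export
simulate_detection_panels <- function(n_blank_pools = 4, n_low_pools = 4,
                                      reps_per_pool = 45, lots = 3, days = 3,
                                      blank_mean = 10, blank_sd = 2,
                                      low_means = c(20, 25, 30, 40),
                                      low_cv = 15, seed = NULL,
                                      analyte = "creatinine") {
  if (n_low_pools > 0 && length(low_means) == 0) {
    stop("low_means must be provided when low-level pools are requested",
         call. = FALSE)
  }
  if (n_low_pools > 0 && length(low_means) != n_low_pools) {
    low_means <- rep_len(low_means, n_low_pools)
  }
  if (reps_per_pool %% (lots * days) != 0) {
    stop("reps_per_pool must be divisible by lots x days for a ",
         "balanced panel", call. = FALSE)
  }
  with_seed(seed, {
    per_cell <- reps_per_pool / (lots * days)
    cells <- expand.grid(replicate = seq_len(per_cell), day = seq_len(days),
                         lot = seq_len(lots))
    one_pool <- function(pid, vals) {
      measurements(pool_id = pid, analyte = analyte, value = vals,
                   day = cells$day, lot = paste0("lot", cells$lot),
                   replicate = cells$replicate)
    }
    out <- list()
    for (b in seq_len(n_blank_pools)) {
      vals <- stats::rnorm(reps_per_pool, blank_mean, blank_sd)
      out[[length(out) + 1]] <- one_pool(paste0("B", b), pmax(vals, 0))
    }
    for (l in seq_len(n_low_pools)) {
      vals <- low_means[l] * (1 + stats::rnorm(reps_per_pool, 0, low_cv / 100))
      out[[length(out) + 1]] <- one_pool(paste0("L", l), vals)
    }
    truncate_at_zero(do.call(rbind, out))
  })
}

#' Simulate a stability time course
#'
#' One donor x condition course: `value = baseline + drift_per_day * t` with
#' multiplicative noise at `cv`%, measured at the given `timepoints` with
#' `reps` replicates each. Each result independently becomes `no_result` with
#' probability `missing_prob`. Default timepoints follow the two storage
#' conditions studied: refrigerated serum at days 0..8, on-board instrument
#' storage at days 0, 1, 4, 7, 9, 10.
#'
#' @param baseline true value at day 0 (score units).
#' @param drift_per_day linear drift (score units per day).
#' @param timepoints numeric days, must include 0.
#' @param reps replicates per timepoint (>= 1).
#' @param cv multiplicative noise CV%.
#' @param missing_prob per-result probability of a lost result, in \[0, 1\].
#' @param seed integer seed.
#' @param pool_id donor label; `analyte` defaults to the composite score.
#' @param analyte label.
#' @return measurement `data.frame` with `timepoint_days` set.
#' @export
simulate_stability_course <- function(baseline = 100, drift_per_day = 0,
                                      timepoints = 0:8, reps = 3, cv = 2,
                                      missing_prob = 0, seed = NULL,
                                      pool_id = "D1", analyte = "gfr_score") {
  if (!0 %in% timepoints) stop("timepoints must include 0", call. = FALSE)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  if (missing_prob < 0 || missing_prob > 1) {
    stop("missing_prob must lie in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(reps), t = sort(timepoints))
    mu <- baseline + drift_per_day * grid$t
    value <- mu * (1 + stats::rnorm(nrow(grid), 0, cv / 100))
    lost <- stats::runif(nrow(grid)) < missing_prob
    value[lost] <- NA_real_
    df <- measurements(pool_id = pool_id, analyte = analyte, value = value,
                       status = ifelse(lost, "no_result", "ok"),
                       timepoint_days = grid$t, replicate = grid$replicate,
                       day = as.integer(floor(grid$t)))
    truncate_at_zero(df)
  })
}

#' Simulate a paired interference screen (spiked vs control aliquots)
#'
#' Two arms from one pool: `n_per_arm` control aliquots around `control_mean`
#' and `n_per_arm` spiked aliquots around `control_mean * (1 +
#' bias_percent/100)`, both with multiplicative noise at `cv`%. Spiked results
#' are independently lost with probability `no_result_prob` (an interfering
#' substance can suppress quantification entirely). The standard screen uses
#' 10 aliquots per arm.
#'
#' @param control_mean positive true control level.
#' @param bias_percent true relative bias of the spiked arm (%).
#' @param n_per_arm aliquots per arm (>= 2).
#' @param cv multiplicative noise CV%.
#' @param no_result_prob per-result loss probability in the spiked arm.
#' @param seed integer seed.
#' @param pool_id,analyte,substance labels; `substance` is stored in `lot`.
#' @return measurement `data.frame` with `arm` `"control"` / `"test"`.
#' @export
simulate_interference_pair <- function(control_mean = 80, bias_percent = 0,
                                       n_per_arm = 10, cv = 3,
                                       no_result_prob = 0, seed = NULL,
                                       pool_id = "high", analyte = "gfr_score",
                                       substance = "substance") {
  if (control_mean <= 0) stop("control_mean must be positive", call. = FALSE)
  if (n_per_arm < 2) stop("n_per_arm must be >= 2", call. = FALSE)
  with_seed(seed, {
    ctrl <- control_mean * (1 + stats::rnorm(n_per_arm, 0, cv / 100))
    test <- control_mean * (1 + bias_percent / 100) *
      (1 + stats::rnorm(n_per_arm, 0, cv / 100))
    lost <- stats::runif(n_per_arm) < no_result_prob
    test[lost] <- NA_real_
    df <- rbind(
      measurements(pool_id = pool_id, analyte = analyte, value = ctrl,
                   arm = "control", replicate = seq_len(n_per_arm),
                   lot = substance),
      measurements(pool_id = pool_id, analyte = analyte, value = test,
                   status = ifelse(lost, "no_result", "ok"), arm = "test",
                   replicate = seq_len(n_per_arm), lot = substance)
    )
    truncate_at_zero(df)
  })
}

#' Parameters of the surrogate composite kidney-function score
#'
#' The published estimating equation combining the serum markers is
#' proprietary; the package therefore ships a documented surrogate with the
#' same qualitative behaviour — a multiplicative power-law score, strictly
#' decreasing in creatinine, myo-inositol, valine and cystatin C and in age,
#' lower for female sex:
#'
#' `score = scale * prod_m (x_m / ref_m)^(-exp_m) * (age/50)^(-age_exponent) * s`
#'
#' with `s = 1` for male and `sex_factor` for female. Defaults are chosen so a
#' typical adult serum profile scores near 90 mL/min/1.73 m^2.
#'
#' @param coefficients named list per marker with elements `ref` (reference
#'   concentration) and `exp` (positive exponent; the score uses `-exp`).
#' @param age_exponent positive age exponent.
#' @param sex_factor multiplicative factor for female sex, in (0, 1].
#' @param scale score at the all-reference input for a 50-year-old male.
#' @return list of class `"surrogate_score_params"`.
#' @export
surrogate_score_params <- function(
    coefficients = list(
      creatinine = list(ref = 80, exp = 0.55),
      myo_inositol = list(ref = 25, exp = 0.25),
      valine = list(ref = 230, exp = 0.05),
      cystatin_c = list(ref = 0.9, exp = 0.35)),
    age_exponent = 0.15, sex_factor = 0.94, scale = 90) {
  stopifnot(age_exponent >= 0, sex_factor > 0, sex_factor <= 1, scale > 0)
  bad <- vapply(coefficients, function(co) co$exp <= 0 || co$ref <= 0,
                logical(1))
  if (any(bad)) stop("marker exponents and references must be positive",
                     call. = FALSE)
  structure(list(coefficients = coefficients, age_exponent = age_exponent,
                 sex_factor = sex_factor, scale = scale),
            class = "surrogate_score_params")
}

#' Surrogate composite kidney-function score
#'
#' Deterministic closed-form score used wherever the pipeline needs a
#' marker-to-score mapping (see [surrogate_score_params()] for the form).
#' Strictly monotone decreasing in every marker by construction.
#'
#' @param markers named numeric vector/list of positive marker concentrations;
#'   must cover every marker named in `params$coefficients`.
#' @param age age in years (> 0).
#' @param sex `"male"` or `"female"`.
#' @param params a [surrogate_score_params()].
#' @return score in mL/min/1.73 m^2.
#' @examples
#' surrogate_score(c(creatinine = 80, myo_inositol = 25,
#'                   valine = 230, cystatin_c = 0.9), age = 50, sex = "male")
#' @export
surrogate_score <- function(markers, age = 50, sex = c("male", "female"),
                            params = surrogate_score_params()) {
  sex <- match.arg(sex)
  markers <- unlist(markers)
  need <- names(params$coefficients)
  absent <- setdiff(need, names(markers))
  if (length(absent) > 0) {
    stop("missing marker(s): ", paste(absent, collapse = ", "), call. = FALSE)
  }
  if (any(markers[need] <= 0)) stop("marker concentrations must be positive",
                                    call. = FALSE)
  if (age <= 0) stop("age must be positive", call. = FALSE)
  f <- params$scale * (age / 50)^(-params$age_exponent)
  for (m in need) {
    co <- params$coefficients[[m]]
    f <- f * (markers[[m]] / co$ref)^(-co$exp)
  }
  unname(f * if (sex == "female") params$sex_factor else 1)
}
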