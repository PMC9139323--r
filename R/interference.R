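# Two-stage interference evaluation (EP07 style): a worst-case screen of
# spiked vs unspiked aliquots judged by mean relative bias, followed by a
# five-level dose-response experiment on flagged substances to localize the
# lowest interfering spike fraction. A substance can also interfere by
# suppressing results entirely ("no result" interference).

#' Interference screen of one substance x pool
#'
#' Mean relative bias is `(mean_test - mean_control) / mean_control * 100`
#' over the ok results. The substance is flagged when `|bias|` exceeds
#' `bias_threshold` (two-sided) or when the test arm loses more results than
#' the missing-data allowance (including the extreme case of an entirely
#' missing test arm, where the bias is undefined but the flag is raised).
#'
#' @param test,control numeric result vectors (`NA` = lost result), or
#'   measurement `data.frame`s (their ok values are used and `no_result` rows
#'   counted as lost).
#' @param substance,pool labels (`pool` conventionally `"high"` or `"low"`).
#' @param bias_threshold flag threshold in % (default 10).
#' @param missing_allowance tolerated no-result fraction (default 0.10).
#' @return list of class `"interference_result"`: `substance`, `pool`,
#'   `mean_relative_bias` (`NA` when the test arm is empty),
#'   `no_result_fraction_test`, `flagged`, `mechanism` (`"bias"`,
#'   `"no_result"`, or `"none"`), `n_test`, `n_control`.
#' @examples
#' screen_interference(test = rep(76.7, 10), control = rep(100, 10),
#'                     substance = "glucose", pool = "high")
#' @export
screen_interference <- function(test, control, substance = "substance",
                                pool = c("high", "low"), bias_threshold = 10,
                                missing_allowance = 0.10) {
  pool <- match.arg(pool)
  as_arm <- function(a) {
    if (is.data.frame(a)) {
      a <- validate_measurements(a)
      ifelse(a$status == "ok", a$value, NA_real_)
    } else as.numeric(a)
  }
  test <- as_arm(test); control <- as_arm(control)
  ctrl_ok <- control[!is.na(control)]
  if (length(ctrl_ok) == 0) stop("invalid control: all results missing",
                                 call. = FALSE)
  test_ok <- test[!is.na(test)]
  no_result_fraction <- mean(is.na(test))
  if (length(test_ok) == 0) {
    bias <- NA_real_
  } else {
    if (length(test_ok) < 2) {
      warning("fewer than 2 ok results in the test arm", call. = FALSE)
    }
    bias <- (mean(test_ok) - mean(ctrl_ok)) / mean(ctrl_ok) * 100
  }
  by_bias <- !is.na(bias) && abs(bias) > bias_threshold
  by_loss <- no_result_fraction > missing_allowance + 1e-12
  structure(list(substance = substance, pool = pool,
                 mean_relative_bias = bias,
                 no_result_fraction_test = no_result_fraction,
                 flagged = by_bias || by_loss,
                 mechanism = if (by_bias) "bias"
                             else if (by_loss) "no_result" else "none",
                 n_test = length(test_ok), n_control = length(ctrl_ok)),
            class = "interference_result")
}

#' Dose-response confirmation of a flagged substance
#'
#' Five replicate fractions containing 0%, 25%, 50%, 75% and 100% of the
#' worst-case spike concentration are measured; per level the relative bias
#' against the level-0 (control) mean is computed. Interference is confirmed
#' at the lowest fraction whose `|bias|` exceeds `bias_threshold` or whose
#' results are lost beyond the missing allowance; if no level trips, the
#' screen finding is not confirmed. The reported threshold concentration is
#' the tripping fraction times the 100% spike concentration; in prose the
#' interfering level is "greater than" the last non-tripping concentration.
#'
#' @param levels named list: spike fraction (as character or numeric, e.g.
#'   `"0"`, `"0.25"`, ...) -> numeric results (`NA` = lost result). Level 0
#'   must be present with >= 2 ok results; at least 3 levels overall.
#' @param substance,pool labels.
#' @param spike_concentration the 100% spike concentration (optional, any
#'   unit); used to convert the tripping fraction into a concentration.
#' @param bias_threshold,missing_allowance as in [screen_interference()].
#' @return list of class `"interference_result"` with `confirmed`,
#'   `threshold_fraction`, `threshold_concentration`,
#'   `last_safe_concentration`, and a `per_level` data.frame (fraction, bias,
#'   no-result fraction, tripped).
#' @examples
#' dr <- dose_response(list("0" = rep(100, 5), "0.25" = rep(98, 5),
#'                          "0.5" = rep(95, 5), "0.75" = rep(87, 5),
#'                          "1" = rep(80, 5)),
#'                     substance = "glucose", spike_concentration = 27.8)
#' dr$threshold_fraction
#' @export
dose_response <- function(levels, substance = "substance",
                          pool = c("high", "low"), spike_concentration = NA,
                          bias_threshold = 10, missing_allowance = 0.10) {
  pool <- match.arg(pool)
  frac <- as.numeric(names(levels))
  if (any(is.na(frac))) stop("levels must be named by spike fraction",
                             call. = FALSE)
  o <- order(frac)
  frac <- frac[o]; levels <- levels[o]
  if (frac[1] != 0) stop("level 0 (control) missing", call. = FALSE)
  if (length(frac) < 3) stop("need at least 3 dose levels", call. = FALSE)
  ctrl <- levels[[1]]
  ctrl_ok <- ctrl[!is.na(ctrl)]
  if (length(ctrl_ok) < 2) stop("level 0 needs at least 2 ok results",
                                call. = FALSE)
  ctrl_mean <- mean(ctrl_ok)
  per_level <- do.call(rbind, lapply(seq_along(frac), function(i) {
    v <- as.numeric(levels[[i]])
    ok <- v[!is.na(v)]
    bias <- if (length(ok) == 0) NA_real_
            else (mean(ok) - ctrl_mean) / ctrl_mean * 100
    nr <- mean(is.na(v))
    data.frame(fraction = frac[i], bias = bias, no_result_fraction = nr,
               tripped = (!is.na(bias) && abs(bias) > bias_threshold) ||
                 nr > missing_allowance + 1e-12)
  }))
  trips <- per_level$fraction > 0 & per_level$tripped
  confirmed <- any(trips)
  threshold_fraction <- if (confirmed) min(per_level$fraction[trips]) else NA_real_
  idx <- if (confirmed) which(per_level$fraction == threshold_fraction) else NA
  last_safe <- if (confirmed && idx > 1) per_level$fraction[idx - 1] else NA_real_
  structure(list(substance = substance, pool = pool,
                 mean_relative_bias = per_level$bias[nrow(per_level)],
                 no_result_fraction_test =
                   per_level$no_result_fraction[nrow(per_level)],
                 flagged = confirmed, confirmed = confirmed,
                 threshold_fraction = threshold_fraction,
                 threshold_concentration = threshold_fraction * spike_concentration,
                 last_safe_concentration = last_safe * spike_concentration,
                 per_level = per_level),
            class = "interference_result")
}

#' @export
print.interference_result <- function(x, ...) {
  cat(sprintf("Interference: %s (%s pool)\n", x$substance, x$pool))
  if (is.na(x$mean_relative_bias)) cat("  mean relative bias: no result\n")
  else cat(sprintf("  mean relative bias: %+.2f%%\n", x$mean_relative_bias))
  if (!is.null(x$confirmed)) {
    if (isTRUE(x$confirmed)) {
      cat(sprintf("  confirmed at spike fraction %.2f", x$threshold_fraction))
      if (!is.na(x$threshold_concentration)) {
        cat(sprintf(" (> %.4g in spike units)", x$last_safe_concentration))
      }
      cat("\n")
    } else cat("  not confirmed in dose-response\n")
  } else {
    cat("  flagged in screen:", if (x$flagged) "yes" else "no",
        sprintf("(%s)\n", x$mechanism))
  }
  invisible(x)
}
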