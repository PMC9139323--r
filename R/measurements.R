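#' @keywords internal
"_PACKAGE"

# Canonical long-format column set shared by every study stage.
MEASUREMENT_COLUMNS <- c(
  "pool_id", "analyte", "value", "status", "site", "day", "run",
  "replicate", "timepoint_days", "level", "arm", "lot"
)

MEASUREMENT_STATUSES <- c("ok", "no_result")
MEASUREMENT_ARMS <- c("test", "control", "mock", "spiked")

#' Construct a measurement table
#'
#' Builds the canonical long-format table used throughout the package: one row
#' per individual measurement, tagged with every design factor a validation
#' study may use. Unused factors are `NA`. A measurement either carries a
#' finite nonnegative `value` with `status = "ok"` or no value at all with
#' `status = "no_result"` (a lost result, e.g. a failed quantification).
#'
#' @param pool_id character, sample-pool label.
#' @param analyte character, measurand name (e.g. `"creatinine"`,
#'   `"gfr_score"`).
#' @param value numeric, nonnegative result in the analyte's units; `NA` iff
#'   `status` is `"no_result"`.
#' @param status character, `"ok"` or `"no_result"`.
#' @param site,day,run,replicate,timepoint_days,level,arm,lot optional design
#'   factors; recycled to the table length, `NA` where not applicable.
#' @return A `data.frame` with the canonical columns, class
#'   `c("measurement_df", "data.frame")`.
#' @examples
#' measurements(pool_id = "P1", analyte = "creatinine",
#'              value = c(80, 82), replicate = 1:2)
#' @export
measurements <- function(pool_id, analyte, value, status = "ok",
                         site = NA_character_, day = NA_integer_,
                         run = NA_integer_, replicate = NA_integer_,
                         timepoint_days = NA_real_, level = NA_integer_,
                         arm = NA_character_, lot = NA_character_) {
  n <- max(lengths(list(pool_id, analyte, value, status)))
  df <- data.frame(
    pool_id = rep_len(as.character(pool_id), n),
    analyte = rep_len(as.character(analyte), n),
    value = rep_len(as.numeric(value), n),
    status = rep_len(as.character(status), n),
    site = rep_len(as.character(site), n),
    day = rep_len(as.integer(day), n),
    run = rep_len(as.integer(run), n),
    replicate = rep_len(as.integer(replicate), n),
    timepoint_days = rep_len(as.numeric(timepoint_days), n),
    level = rep_len(as.integer(level), n),
    arm = rep_len(as.character(arm), n),
    lot = rep_len(as.character(lot), n),
    stringsAsFactors = FALSE
  )
  validate_measurements(df)
}

validate_measurements <- function(df) {
  missing_cols <- setdiff(MEASUREMENT_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_status <- !df$status %in% MEASUREMENT_STATUSES
  if (any(bad_status)) {
    stop("invalid status value(s): ",
         paste(unique(df$status[bad_status]), collapse = ", "), call. = FALSE)
  }
  nr <- df$status == "no_result"
  if (any(!is.na(df$value[nr]))) {
    stop("status 'no_result' rows must have an absent value", call. = FALSE)
  }
  okv <- df$value[!nr]
  if (any(is.na(okv)) || any(!is.finite(okv))) {
    stop("status 'ok' rows must carry a finite value", call. = FALSE)
  }
  if (any(okv < 0)) stop("values must be nonnegative", call. = FALSE)
  bad_arm <- !is.na(df$arm) & !df$arm %in% MEASUREMENT_ARMS
  if (any(bad_arm)) {
    stop("invalid arm value(s): ",
         paste(unique(df$arm[bad_arm]), collapse = ", "), call. = FALSE)
  }
  class(df) <- unique(c("measurement_df", class(df)))
  df
}

#' Declare a study design
#'
#' A `study_design` records the kind of validation study, the expected
#' cardinality of each design factor (so the expected number of results per
#' pool is their product), and the maximum tolerated missing-data fraction per
#' pool (default 10%, the guideline acceptance rule used throughout).
#'
#' @param study_kind one of `"detection"`, `"linearity"`, `"precision_single"`,
#'   `"precision_multi"`, `"trueness"`, `"stability"`,
#'   `"interference_screen"`, `"interference_dose_response"`.
#' @param expected_counts named list/vector: factor name -> expected number of
#'   distinct values (e.g. `list(day = 20, run = 2, replicate = 3)`).
#' @param max_missing_fraction numeric in \[0, 1\].
#' @return An object of class `"study_design"`.
#' @examples
#' study_design("precision_single", list(day = 20, run = 2, replicate = 3))
#' @export
study_design <- function(study_kind,
                         expected_counts = list(),
                         max_missing_fraction = 0.10) {
  kinds <- c("detection", "linearity", "precision_single", "precision_multi",
             "trueness", "stability", "interference_screen",
             "interference_dose_response")
  study_kind <- match.arg(study_kind, kinds)
  stopifnot(is.numeric(max_missing_fraction), length(max_missing_fraction) == 1)
  if (max_missing_fraction < 0 || max_missing_fraction > 1) {
    stop("max_missing_fraction must lie in [0, 1]", call. = FALSE)
  }
  expected_counts <- as.list(expected_counts)
  if (length(expected_counts) > 0 &&
      (is.null(names(expected_counts)) || any(names(expected_counts) == ""))) {
    stop("expected_counts must be named by design factor", call. = FALSE)
  }
  structure(list(study_kind = study_kind,
                 expected_counts = expected_counts,
                 max_missing_fraction = max_missing_fraction),
            class = "study_design")
}

#' Read a measurement table from CSV
#'
#' Reads the canonical long-format CSV (UTF-8, comma separated, header row,
#' decimal point, empty string for absent fields). Rows with
#' `status = "no_result"` are retained with an absent value so missing-data
#' accounting can see them.
#'
#' @param path path to the CSV file.
#' @param design optional [study_design()]; when given, the factor columns its
#'   `expected_counts` name must be present and non-missing, otherwise a schema
#'   error is raised.
#' @return A validated measurement `data.frame` (see [measurements()]).
#' @export
read_measurements <- function(path, design = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = NULL)
  missing_cols <- setdiff(MEASUREMENT_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  blank_to_na <- function(x) ifelse(trimws(x) == "", NA_character_, x)
  raw[] <- lapply(raw, blank_to_na)

  num_or_die <- function(x, col) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      stop(sprintf("parse error: non-numeric '%s' in column '%s' at data row %d",
                   x[bad[1]], col, bad[1]), call. = FALSE)
    }
    out
  }
  df <- data.frame(
    pool_id = raw$pool_id, analyte = raw$analyte,
    value = num_or_die(raw$value, "value"),
    status = ifelse(is.na(raw$status), "ok", raw$status),
    site = raw$site,
    day = as.integer(num_or_die(raw$day, "day")),
    run = as.integer(num_or_die(raw$run, "run")),
    replicate = as.integer(num_or_die(raw$replicate, "replicate")),
    timepoint_days = num_or_die(raw$timepoint_days, "timepoint_days"),
    level = as.integer(num_or_die(raw$level, "level")),
    arm = raw$arm, lot = raw$lot,
    stringsAsFactors = FALSE
  )
  df <- validate_measurements(df)
  if (!is.null(design)) {
    need <- names(design$expected_counts)
    absent <- need[vapply(need, function(f) all(is.na(df[[f]])), logical(1))]
    if (length(absent) > 0) {
      stop("schema error: design factor column(s) entirely missing: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  df
}

#' Write a measurement table to CSV
#'
#' Inverse of [read_measurements()]: absent fields are written as empty
#' strings, so a write/read round trip reproduces every field and status
#' exactly.
#'
#' @param data a measurement `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(data, path) {
  data <- validate_measurements(as.data.frame(data))
  out <- data[, MEASUREMENT_COLUMNS]
  # full-precision values so the round trip is exact
  out$value <- ifelse(is.na(out$value), "", sprintf("%.17g", out$value))
  out[] <- lapply(out, function(x) ifelse(is.na(x), "", as.character(x)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Check design completeness and missing data per pool
#'
#' Compares a measurement table against the expected design: for each pool the
#' expected number of results is the product of the design's expected factor
#' counts, and the missing fraction counts both absent rows and
#' `status = "no_result"` rows (a lost result is missing data). The check
#' passes iff every pool's missing fraction is at most the design's
#' `max_missing_fraction` and every declared factor is observed.
#'
#' @param data measurement `data.frame` (non-empty).
#' @param design a [study_design()].
#' @return A list of class `"design_check"` with elements `missing_fraction`
#'   (named numeric, per pool), `pass_flag`, and `reasons` (character).
#' @examples
#' d <- simulate_precision_study(seed = 1)
#' chk <- check_design(d, study_design("precision_single",
#'                                     list(day = 20, run = 2, replicate = 3)))
#' chk$pass_flag
#' @export
check_design <- function(data, design) {
  data <- validate_measurements(as.data.frame(data))
  if (nrow(data) == 0) stop("no data", call. = FALSE)
  stopifnot(inherits(design, "study_design"))
  counts <- design$expected_counts
  expected_n <- if (length(counts) > 0) prod(unlist(counts)) else NA_real_
  reasons <- character(0)

  for (f in names(counts)) {
    observed_levels <- length(unique(stats::na.omit(data[[f]])))
    if (observed_levels < counts[[f]]) {
      reasons <- c(reasons, sprintf(
        "factor '%s': observed %d level(s), design expects %d",
        f, observed_levels, counts[[f]]))
    }
  }

  pools <- sort(unique(data$pool_id))
  missing_fraction <- vapply(pools, function(p) {
    rows <- data[data$pool_id == p, ]
    n_ok <- sum(rows$status == "ok")
    exp_p <- if (is.na(expected_n)) nrow(rows) else expected_n
    (exp_p - n_ok) / exp_p
  }, numeric(1))
  names(missing_fraction) <- pools
  missing_fraction <- pmax(missing_fraction, 0)

  over <- missing_fraction > design$max_missing_fraction + 1e-12
  if (any(over)) {
    reasons <- c(reasons, sprintf(
      "pool '%s': missing fraction %.1f%% exceeds %.0f%% allowance",
      pools[over], 100 * missing_fraction[over],
      100 * design$max_missing_fraction))
  }
  structure(list(missing_fraction = missing_fraction,
                 pass_flag = length(reasons) == 0,
                 reasons = reasons),
            class = "design_check")
}

#' @export
print.design_check <- function(x, ...) {
  cat("Design check:", if (x$pass_flag) "PASS" else "FAIL", "\n")
  cat("Missing fraction per pool:\n")
  print(round(x$missing_fraction, 4))
  if (length(x$reasons) > 0) cat(paste0("  - ", x$reasons, collapse = "\n"), "\n")
  invisible(x)
}

# Extract the numeric results of 'ok' rows; NA rows dropped.
ok_values <- function(data) {
  data$value[data$status == "ok"]
}
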