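# Cohort CSV round trip. Header matches the schema exactly; missing values
# are written as empty strings; "." decimal, UTF-8.

NUMERIC_COHORT_COLUMNS <- c(
  "weight", "bmi", "height",
  "grip_trial1", "grip_trial2", "walk_trial1", "walk_trial2"
)

#' Write a cohort to CSV
#'
#' @param cohort cohort `data.frame`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort[, COHORT_COLUMNS, drop = FALSE], path,
                   row.names = FALSE, na = "", fileEncoding = "UTF-8",
                   quote = FALSE)
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' Validates the schema on read: all columns must be present, no unknown
#' columns, ids unique, measures numeric, and basic physiological ranges
#' respected (weight > 0; BMI in (10, 60); height in (120, 200); walk
#' trials in (1, 120) when present). Violations raise a schema error naming
#' the offending column and, where applicable, the first offending row.
#'
#' @param path CSV file path.
#' @return a validated cohort `data.frame`.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        colClasses = "character", fileEncoding = "UTF-8")
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop_frailscreen("cohort schema error: missing column(s) %s",
                     paste(missing_cols, collapse = ", "),
                     class = "frailscreen_schema_error")
  }
  unknown <- setdiff(names(df), COHORT_COLUMNS)
  if (length(unknown)) {
    stop_frailscreen("cohort schema error: unknown column(s) %s",
                     paste(unknown, collapse = ", "),
                     class = "frailscreen_schema_error")
  }
  for (col in NUMERIC_COHORT_COLUMNS) {
    v <- df[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad)) {
      stop_frailscreen(
        "cohort schema error: non-numeric value '%s' in column %s, row %d",
        v[bad[1L]], col, bad[1L], class = "frailscreen_schema_error")
    }
    df[[col]] <- num
  }
  if (anyDuplicated(df$id)) {
    dup <- df$id[duplicated(df$id)][1L]
    stop_frailscreen("cohort schema error: duplicate id '%s'", dup,
                     class = "frailscreen_schema_error")
  }
  check_range <- function(col, lo, hi, allow_na = FALSE) {
    v <- df[[col]]
    bad <- which(!is.na(v) & (v <= lo | v >= hi))
    if (!allow_na && anyNA(v)) bad <- c(which(is.na(v)), bad)
    if (length(bad)) {
      stop_frailscreen(
        "cohort schema error: column %s out of range (%g, %g) at row %d",
        col, lo, hi, bad[1L], class = "frailscreen_schema_error")
    }
  }
  if (nrow(df)) {
    check_range("weight", 0, Inf)
    check_range("bmi", 10, 60)
    check_range("height", 120, 200)
    check_range("walk_trial1", 1, 120, allow_na = TRUE)
    check_range("walk_trial2", 1, 120, allow_na = TRUE)
    badsex <- which(!df$sex %in% SEX_LEVELS)
    if (length(badsex)) {
      stop_frailscreen("cohort schema error: unknown sex '%s' at row %d",
                       df$sex[badsex[1L]], badsex[1L],
                       class = "frailscreen_schema_error")
    }
  }
  df[, COHORT_COLUMNS]
}
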