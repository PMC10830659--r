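# Cohort CSV schema, validation and readers/writers.

#' Cohort CSV schema
#'
#' Required column names for a cohort table: one row per patient, sex coded
#' m/f, empty cell = missing. The two pressure columns are optional.
#'
#' @return Named list with `required` and `optional` column names.
#' @export
cohort_columns <- function() {
  list(
    required = c("patient_id", "age", "sex", "height_cm", "weight_kg",
                 "heart_rate", "hemoglobin_g_dl", "sao2", "svo2",
                 "td_co_l_min"),
    optional = c("mpap_mmhg", "mpawp_mmhg")
  )
}

#' Validate and normalize a cohort table
#'
#' Checks the schema and per-row invariants: strictly positive physiological
#' fields where present, valid sex coding, and arterial saturation exceeding
#' mixed-venous saturation. Percent-scale saturations are converted to
#' fractions when `saturation_mode = "percent"`. Violations raise a data
#' error naming up to the first five offending patients.
#'
#' @param cohort A data frame following [cohort_columns()].
#' @param saturation_mode `"fraction"` or `"percent"`.
#' @return The cohort with sex normalized to "male"/"female" and saturations
#'   as fractions.
#' @export
validate_cohort <- function(cohort,
                            saturation_mode = c("fraction", "percent")) {
  saturation_mode <- match.arg(saturation_mode)
  if (!is.data.frame(cohort)) {
    stop_data("cohort must be a data frame")
  }
  cols <- cohort_columns()
  missing_cols <- setdiff(cols$required, names(cohort))
  if (length(missing_cols)) {
    stop_data("cohort is missing required columns: %s",
              paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(names(cohort), c(cols$required, cols$optional))
  if (length(unknown)) {
    stop_data("cohort has unknown columns: %s",
              paste(unknown, collapse = ", "))
  }
  if (nrow(cohort) == 0) {
    stop_data("cohort is empty")
  }
  if (anyDuplicated(cohort$patient_id)) {
    stop_data("cohort has duplicated patient_id values")
  }

  cohort$sex <- normalize_sex(cohort$sex)
  if (saturation_mode == "percent") {
    cohort$sao2 <- cohort$sao2 / 100
    cohort$svo2 <- cohort$svo2 / 100
  }

  complain <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      ids <- cohort$patient_id[which(bad)]
      stop_data("invalid cohort rows (%s): patient_id %s", what,
                paste(head(ids, 5), collapse = ", "))
    }
  }
  pos_fields <- c("age", "height_cm", "weight_kg", "heart_rate",
                  "hemoglobin_g_dl", "td_co_l_min")
  for (f in pos_fields) {
    complain(!is.na(cohort[[f]]) & cohort[[f]] <= 0,
             sprintf("%s must be > 0", f))
  }
  for (f in c("sao2", "svo2")) {
    complain(!is.na(cohort[[f]]) & (cohort[[f]] <= 0 | cohort[[f]] > 1),
             sprintf("%s must be a fraction in (0, 1]%s", f,
                     if (saturation_mode == "fraction")
                       "; 0-100 inputs need saturation_mode = \"percent\""
                     else ""))
  }
  complain(!is.na(cohort$sao2) & !is.na(cohort$svo2) &
             cohort$sao2 <= cohort$svo2,
           "sao2 must exceed svo2")
  if (all(c("mpap_mmhg", "mpawp_mmhg") %in% names(cohort))) {
    complain(!is.na(cohort$mpap_mmhg) & !is.na(cohort$mpawp_mmhg) &
               cohort$mpap_mmhg < cohort$mpawp_mmhg,
             "mpap_mmhg must be >= mpawp_mmhg")
  }
  cohort
}

#' Read a cohort CSV
#'
#' Reads the standard cohort table (see [cohort_columns()]): one row per
#' patient, sex coded m/f, empty cells treated as missing. The table is
#' validated with [validate_cohort()].
#'
#' @param path Path to the CSV file.
#' @param saturation_mode `"fraction"` (default) or `"percent"`.
#' @return A validated cohort data frame (saturations as fractions).
#' @export
read_cohort <- function(path, saturation_mode = c("fraction", "percent")) {
  if (!file.exists(path)) {
    stop_data("cohort file not found: %s", path)
  }
  df <- read.csv(path, stringsAsFactors = FALSE,
                 na.strings = c("", "NA"))
  validate_cohort(df, saturation_mode = saturation_mode)
}

#' Write a cohort CSV
#'
#' Numeric fields are serialized with 17 significant digits so a write/read
#' round trip reproduces the doubles bitwise; the cohort CSV is input data,
#' not a report, and must not lose precision.
#'
#' @param cohort A cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  out$sex <- substr(normalize_sex(out$sex), 1, 1)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), "", sprintf("%.17g", x))
  })
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Write a derived-values CSV
#'
#' Wide table, one column per (formula, quantity), numeric values rounded to
#' 4 decimals at serialization.
#'
#' @param derived Output of [derive_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_derived <- function(derived, path) {
  out <- as.data.frame(derived)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = 4)
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
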