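cohort_schema <- function() {
  list(
    character = c("subject_id", "cohort_name", "care_level", "age_band",
                  "sex", "stage", "pet_visual_read", "ad_status"),
    numeric = c("age", "education", "plasma_ptau217", "plasma_ab42",
                "ms_ptau217", "ms_np_ptau217", "csf_ab42_ptau181",
                "csf_ab42_40"),
    boolean = c("apoe4", "ckd", "diabetes")
  )
}

#' Write a cohort to CSV
#'
#' One row per subject with the documented column schema: booleans encoded
#' as 0/1, missing values as empty fields. Round-trips losslessly through
#' [read_cohort_csv()].
#'
#' @param cohort Cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  sch <- cohort_schema()
  out <- cohort
  for (col in intersect(sch$boolean, names(out))) {
    out[[col]] <- as.integer(out[[col]])
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Validates the documented schema: required columns present, booleans
#' encoded 0/1 (anything else is an error), missing cells become missing
#' marker values (never zeros). Unknown columns are preserved.
#'
#' @param path CSV file path.
#' @return A cohort tibble.
#' @export
read_cohort_csv <- function(path) {
  sch <- cohort_schema()
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = "", progress = FALSE)
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    stop("malformed CSV '", path, "': row ", prob$row[1], ", ",
         prob$expected[1], call. = FALSE)
  }
  required <- c("subject_id", "cohort_name", "ad_status")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("cohort file '", path, "' lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- raw
  for (col in intersect(sch$numeric, names(out))) {
    parsed <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(!is.na(out[[col]]) & is.na(parsed))
    if (length(bad)) {
      stop("column '", col, "' row ", bad[1], ": cannot parse '",
           out[[col]][bad[1]], "' as a number", call. = FALSE)
    }
    out[[col]] <- parsed
  }
  for (col in intersect(sch$boolean, names(out))) {
    x <- out[[col]]
    bad <- which(!is.na(x) & !x %in% c("0", "1"))
    if (length(bad)) {
      stop("column '", col, "' row ", bad[1],
           ": booleans must be encoded 0/1, got '", x[bad[1]], "'",
           call. = FALSE)
    }
    out[[col]] <- x == "1"
  }
  out
}
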