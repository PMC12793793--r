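# Longitudinal cohort tables: long-format CSV, one row per
# subject x timepoint, missing cells as empty strings (never sentinel
# numbers). Unknown columns are preserved verbatim.

#' Read a longitudinal cohort table
#'
#' @param path CSV with at least `subject_id` and `timepoint` columns;
#'   empty cells are read as missing.
#' @return data.frame of class `cohort_table`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    stop_thetamod(sprintf("file not found: %s", path), "thetamod_io_error")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  as_cohort_table(tab)
}

#' Validate a data frame as a cohort table
#' @param tab data.frame with `subject_id` and `timepoint` columns.
#' @return the validated `cohort_table`.
#' @export
as_cohort_table <- function(tab) {
  missing_cols <- setdiff(c("subject_id", "timepoint"), names(tab))
  if (length(missing_cols))
    stop_thetamod(paste0("cohort table missing column(s): ",
                         paste(missing_cols, collapse = ", ")),
                  "thetamod_validation_error")
  key <- paste(tab$subject_id, tab$timepoint, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop_thetamod(sprintf("duplicate (subject_id, timepoint) key: (%s)",
                          gsub("\r", ", ", d)), "thetamod_validation_error")
  }
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Write a cohort table to CSV
#'
#' Missing cells are written as empty strings so the write/read round trip
#' preserves missingness exactly.
#'
#' @param tab a `cohort_table` (or plain data.frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}
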