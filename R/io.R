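# Plain-CSV readers/writers for the documented table schemas, so simulated
# cohorts and extracted gains round-trip through files.

#' Write / read analysis tables as CSV
#'
#' `write_gain_table()`/`read_gain_table()` handle gain-observation tables
#' (one row per subject x condition x direction); `write_trial_table()`
#' writes trial schedules; `write_condition_table()` writes block condition
#' designs; `write_trace_table()` writes long-format traces (`trial_id`,
#' `t_ms`, `value`). All files are UTF-8 CSV with a header row.
#'
#' @param x The table to write.
#' @param path File path.
#' @return `read_gain_table` returns the data frame; writers return the
#'   path invisibly.
#' @export
write_gain_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gain_table
#' @export
read_gain_table <- function(path) {
  need <- c("subject_id", "r_ratio", "p_ratio", "gain")
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(need %in% names(x)))
    stop("gain table must have columns: ", paste(need, collapse = ", "))
  x
}

#' @rdname write_gain_table
#' @export
write_trial_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gain_table
#' @export
write_condition_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gain_table
#' @export
write_trace_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
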