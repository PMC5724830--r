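# Plain-text interchange for session logs and cohort tables ------------------

#' Write / read a trial-level session log (TSV)
#'
#' One row per trial; `ssd_ms` is empty on go trials and `rt_ms` empty when no
#' response occurred.  Logs of several participants can share one file.
#'
#' @param log Session log data frame (schema of [simulate_session()]).
#' @param path File path.
#' @return `write_session_log` returns `path` invisibly; `read_session_log`
#'   returns the data frame (or, with `split = TRUE`, a named list of
#'   per-participant logs).
#' @export
write_session_log <- function(log, path) {
  write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_session_log
#' @param path File path.
#' @param split Return a named list of per-participant logs.
#' @export
read_session_log <- function(path, split = FALSE) {
  log <- read.delim(path, na.strings = "", stringsAsFactors = FALSE,
                    colClasses = c(participant_id = "character"))
  chk_cols(log, c("participant_id", "run", "trial_index", "trial_type",
                  "responded", "outcome"), path)
  if (split) split(log, log$participant_id) else log
}

#' Write / read a cohort table (CSV)
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @return `write_cohort_table` returns `path` invisibly;
#'   `read_cohort_table` the data frame.
#' @export
write_cohort_table <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  read.csv(path, na.strings = "", stringsAsFactors = FALSE,
           colClasses = c(participant_id = "character"))
}
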