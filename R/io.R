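# Plain-text interchange: trial schedules as TSV (0-based TR indices, as
# documented in the header comment), pRF solutions as TSV.

#' Write a trial schedule to TSV
#'
#' One row per trial with the `TrialRecord` fields; `bar_index` and the TR
#' indices are written 0-based and converted back on read.
#'
#' @param schedule Schedule from [build_trial_schedule()].
#' @param path Output file path.
#' @export
write_schedule_tsv <- function(schedule, path) {
  out <- schedule
  out$bar_index <- out$bar_index - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# trial schedule; bar_index and *_tr fields are 0-based", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a trial schedule from TSV
#'
#' @param path File written by [write_schedule_tsv()].
#' @return Schedule `data.frame` with 1-based `bar_index`.
#' @export
read_schedule_tsv <- function(path) {
  sched <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                             stringsAsFactors = FALSE)
  sched$bar_index <- sched$bar_index + 1L
  sched
}

#' Write pRF solutions to TSV
#'
#' @param prfs Long table from [fit_prfs_by_condition()].
#' @param path Output file path.
#' @export
write_prf_tsv <- function(prfs, path) {
  utils::write.table(prfs, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
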