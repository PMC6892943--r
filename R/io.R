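## Plain-text (TSV) serialization of the tabular artifacts.

#' Write / read a TrialMetrics table
#'
#' Tab-separated, one row per trial, with the canonical column order:
#' subject, trial, event_present, n_events, last_duration_s, last_amplitude,
#' last_timing_s, mean_power, log_mep, excluded, exclusion_reason.
#'
#' @param metrics TrialMetrics data frame.
#' @param path file path.
#' @return `readTrialMetrics` returns the data frame.
#' @export
writeTrialMetrics <- function(metrics, path) {
  cols <- c("subject", "trial", "event_present", "n_events",
            "last_duration_s", "last_amplitude", "last_timing_s",
            "mean_power", "log_mep", "excluded", "exclusion_reason")
  stopifnot(all(cols %in% names(metrics)))
  utils::write.table(metrics[, cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeTrialMetrics
#' @export
readTrialMetrics <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(subject = "character",
                                   trial = "character",
                                   exclusion_reason = "character"))
}

#' Write / read an MEP record table
#'
#' @param records MEPRecord data frame from [extractMEPs()].
#' @param path file path.
#' @export
writeMEPRecords <- function(records, path) {
  cols <- c("subject", "trial", "peak_to_peak_mv", "log_amplitude",
            "prestim_power", "template_r", "excluded", "reason")
  stopifnot(all(cols %in% names(records)))
  utils::write.table(records[, cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeMEPRecords
#' @export
readMEPRecords <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(subject = "character",
                                   trial = "character",
                                   reason = "character"))
}

#' Write a per-subject power spectrum as TSV
#'
#' @param psd data frame from [estimatePSD()].
#' @param path file path.
#' @export
writePSD <- function(psd, path) {
  utils::write.table(psd, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the pipeline report table as TSV
#'
#' @param report report data frame from [runPipeline()].
#' @param path file path.
#' @export
writeReport <- function(report, path) {
  utils::write.table(report, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
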