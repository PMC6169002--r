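#' Write a recording to delimited text
#'
#' Plain-text format: two header lines `# fs=<Hz>` and
#' `# triggers=<comma-separated seconds>`, then CSV columns
#' `time,lfp,emg`. Values are written to full double precision so a
#' write/read round trip reproduces the recording exactly.
#'
#' @param recording a [TimeSeriesRecording-class]
#' @param path output file path
#' @return `path`, invisibly.
#' @seealso [readRecording()]
#' @export
writeRecording <- function(recording, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.17g", recording@fs), con)
  writeLines(paste0("# triggers=",
                    paste(sprintf("%.17g", recording@triggerTimes),
                          collapse = ",")), con)
  writeLines("time,lfp,emg", con)
  n <- length(recording@lfp)
  tt <- (seq_len(n) - 1) / recording@fs
  writeLines(sprintf("%.17g,%.17g,%.17g", tt, recording@lfp, recording@emg), con)
  invisible(path)
}

#' Read a recording from delimited text
#'
#' Parses the format written by [writeRecording()]; malformed headers are
#' reported with their line number.
#'
#' @param path input file path
#' @return A [TimeSeriesRecording-class].
#' @export
readRecording <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  hdr <- readLines(path, n = 3)
  if (length(hdr) < 3) stop("truncated file: ", path)
  if (!startsWith(hdr[1], "# fs="))
    stop("line 1: expected '# fs=<Hz>' header in ", path)
  fs <- suppressWarnings(as.numeric(sub("^# fs=", "", hdr[1])))
  if (is.na(fs) || fs <= 0) stop("line 1: invalid sampling rate in ", path)
  if (!startsWith(hdr[2], "# triggers="))
    stop("line 2: expected '# triggers=<seconds>' header in ", path)
  trigStr <- sub("^# triggers=", "", hdr[2])
  triggers <- if (nzchar(trigStr))
    as.numeric(strsplit(trigStr, ",", fixed = TRUE)[[1]]) else numeric(0)
  if (anyNA(triggers)) stop("line 2: unparseable trigger times in ", path)
  dat <- read.csv(path, skip = 2)
  need <- c("time", "lfp", "emg")
  if (!all(need %in% names(dat)))
    stop("line 3: expected columns time,lfp,emg in ", path)
  new("TimeSeriesRecording", lfp = dat$lfp, emg = dat$emg, fs = fs,
      triggerTimes = triggers, metadata = list(source = path))
}

#' Write / read a per-trial estimates table
#'
#' Plain CSV with the documented columns (subject, ntb, phase, measure,
#' direction, trial, value_nats, p_surrogate, lfp_amp, emg_amp).
#'
#' @param table estimates data.frame
#' @param path file path
#' @return `path` invisibly (write); the data.frame (read).
#' @export
writeEstimates <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEstimates
#' @export
readEstimates <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  read.csv(path)
}
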