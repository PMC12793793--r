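#' Construct an EEG recording object
#'
#' The canonical in-memory container for continuous multichannel EEG. The
#' signal is stored as a channels x samples matrix in microvolts; all
#' readers convert to this unit at load time.
#'
#' @param signal numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of unique channel names (10-20
#'   convention, e.g. `"Fz"`), one per signal row.
#' @param meta free-form named list of provenance (source file, subject id,
#'   timepoint label, ...).
#' @return An object of class `eeg_recording` with elements `signal`, `fs`,
#'   `channel_labels` and `meta`.
#' @export
eeg_recording <- function(signal, fs, channel_labels, meta = list()) {
  signal <- as.matrix(signal)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop_thetamod("`fs` must be a single positive number", "thetamod_param_error")
  if (length(channel_labels) != nrow(signal))
    stop_thetamod(sprintf(
      "number of channel labels (%d) does not match signal rows (%d)",
      length(channel_labels), nrow(signal)), "thetamod_param_error")
  if (anyDuplicated(channel_labels))
    stop_thetamod("channel labels must be unique", "thetamod_param_error")
  if (!all(is.finite(signal)))
    stop_thetamod("signal contains non-finite values", "thetamod_param_error")
  structure(
    list(signal = signal, fs = fs,
         channel_labels = as.character(channel_labels), meta = meta),
    class = "eeg_recording")
}

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @return length in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$signal) / rec$fs

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples (%.1f s @ %g Hz)\n",
              nrow(x$signal), ncol(x$signal), recording_duration(x), x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  scalar <- x$meta[vapply(x$meta, function(v) is.atomic(v) && length(v) == 1,
                          TRUE)]
  if (length(scalar))
    cat("  meta:", paste(names(scalar), vapply(scalar, format, ""),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}
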