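# Preprocessing: zero-phase FIR band-pass, 1-second segmentation,
# amplitude- and gaze-based epoch rejection, minimum-clean-segment gate.

#' Zero-phase FIR band-pass filter
#'
#' Linear-phase Hamming-windowed sinc FIR design (via [signal::fir1()]),
#' applied by FFT convolution with the group delay compensated, so the net
#' phase shift is zero. Transition widths default to 1 Hz at the low edge
#' and 10 Hz at the high edge; the filter order follows from the narrower
#' transition.
#'
#' @param rec an [eeg_recording()].
#' @param low,high cut-off frequencies in Hz; `high` must be below Nyquist.
#' @param transition_low,transition_high transition widths in Hz.
#' @return the filtered [eeg_recording()].
#' @export
bandpass_filter <- function(rec, low = 1, high = 100,
                            transition_low = 1, transition_high = 10) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (high >= fs / 2)
    stop_thetamod(sprintf("high cut-off (%g Hz) must be below Nyquist (%g Hz)",
                          high, fs / 2), "thetamod_param_error")
  if (low <= 0 || low >= high)
    stop_thetamod("need 0 < low < high", "thetamod_param_error")
  order <- ceiling(3.3 * fs / min(transition_low, transition_high))
  if (order %% 2 == 1) order <- order + 1          # type-I (odd-length) FIR
  h <- signal::fir1(order, c(low, high) / (fs / 2), type = "pass")
  delay <- order / 2
  n <- ncol(rec$signal)
  out <- rec
  # FFT convolution at a fast (highly composite) length, all channels at once
  nfft <- stats::nextn(n + length(h) - 1)
  H <- stats::fft(c(h, numeric(nfft - length(h))))
  pad <- rbind(t(rec$signal), matrix(0, nfft - n, nrow(rec$signal)))
  Y <- stats::mvfft(pad) * H
  y <- Re(stats::mvfft(Y, inverse = TRUE)) / nfft
  out$signal <- t(y[(delay + 1):(delay + n), , drop = FALSE])
  out$meta$filter <- list(low = low, high = high, order = order)
  out
}

#' Average re-reference
#'
#' Subtracts the instantaneous mean across channels. Optional; the band
#' contrasts computed downstream do not require it.
#' @param rec an [eeg_recording()].
#' @return re-referenced recording.
#' @export
average_reference <- function(rec) {
  rec$signal <- sweep(rec$signal, 2, colMeans(rec$signal))
  rec
}

# one-shot window extraction: channels x samples x windows
extract_windows <- function(signal, onsets, fs, n_len) {
  idx <- outer(seq_len(n_len), as.integer(round(onsets * fs)), "+")
  array(signal[, as.vector(idx)], dim = c(nrow(signal), n_len, length(onsets)))
}

new_epoch_set <- function(data, onsets, length, overlap, fs, channel_labels,
                          bad_amp = NULL, bad_gaze = NULL) {
  n_ep <- dim(data)[3]
  structure(list(data = data, onsets = onsets, length = length,
                 overlap = overlap, fs = fs, channel_labels = channel_labels,
                 bad_amp = bad_amp %||% logical(n_ep),
                 bad_gaze = bad_gaze %||% logical(n_ep)),
            class = "epoch_set")
}

#' Epoch statuses
#'
#' One status per epoch: `kept`, `rejected_amplitude` or `rejected_gaze`
#' (amplitude takes precedence when both rules fire, but rejection
#' operators commute on the kept set).
#' @param ep an `epoch_set`.
#' @return character vector.
#' @export
epoch_status <- function(ep) {
  ifelse(ep$bad_amp, "rejected_amplitude",
         ifelse(ep$bad_gaze, "rejected_gaze", "kept"))
}

#' @export
print.epoch_set <- function(x, ...) {
  st <- table(factor(epoch_status(x),
                     levels = c("kept", "rejected_amplitude", "rejected_gaze")))
  cat(sprintf("<epoch_set> %d epochs of %g s (overlap %g), %d channels\n",
              length(x$onsets), x$length, x$overlap, dim(x$data)[1]))
  cat(sprintf("  kept %d | rejected_amplitude %d | rejected_gaze %d\n",
              st[1], st[2], st[3]))
  invisible(x)
}

#' Cut a recording into fixed-length epochs
#'
#' Windows tile the recording from t = 0 with step
#' `length * (1 - overlap)`; a trailing partial window is dropped. Each
#' epoch retains its onset in seconds from recording start.
#'
#' @param rec an [eeg_recording()].
#' @param length epoch length in seconds (`length * fs` must be integral).
#' @param overlap overlap fraction, 0 or 0.5.
#' @return an `epoch_set` with all epochs initially kept.
#' @export
epoch_recording <- function(rec, length = 1, overlap = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  n_len <- length * fs
  if (abs(n_len - round(n_len)) > 1e-9)
    stop_thetamod("epoch length times sampling rate must be integral",
                  "thetamod_param_error")
  n_len <- as.integer(round(n_len))
  dur <- recording_duration(rec)
  if (dur < length)
    stop_thetamod(sprintf("recording (%.3f s) shorter than epoch length (%g s)",
                          dur, length), "thetamod_param_error")
  step <- length * (1 - overlap)
  onsets <- seq(0, dur - length + 1e-9, by = step)
  onsets <- onsets[onsets * fs + n_len <= ncol(rec$signal) + 1e-6]
  data <- extract_windows(rec$signal, onsets, fs, n_len)
  new_epoch_set(data, onsets, length, overlap, fs, rec$channel_labels)
}

#' Amplitude-based epoch rejection
#'
#' Marks any epoch containing a sample outside `+/- threshold` microvolts
#' on any channel as `rejected_amplitude`; other epochs are untouched.
#'
#' @param ep an `epoch_set`.
#' @param threshold rejection threshold in microvolts.
#' @return the updated `epoch_set`.
#' @export
reject_amplitude <- function(ep, threshold = 150) {
  stopifnot(inherits(ep, "epoch_set"))
  peak <- apply(abs(ep$data), 3, max)
  ep$bad_amp <- ep$bad_amp | (peak > threshold)
  ep
}

#' Gaze-based epoch rejection
#'
#' Marks epochs whose window `[onset, onset + length)` overlaps a
#' look-away interval by more than `min_overlap * length` seconds (default
#' 0: any overlap rejects) as `rejected_gaze`.
#'
#' @param ep an `epoch_set`.
#' @param intervals data.frame with `onset`, `offset`, `label` (seconds).
#' @param min_overlap minimum overlap fraction required to reject.
#' @param away_label interval label to treat as look-away.
#' @return the updated `epoch_set`.
#' @export
reject_gaze <- function(ep, intervals, min_overlap = 0,
                        away_label = "look_away") {
  stopifnot(inherits(ep, "epoch_set"))
  iv <- intervals[intervals$label == away_label, , drop = FALSE]
  if (!nrow(iv)) return(ep)
  ov <- vapply(ep$onsets, function(o) {
    sum(pmax(0, pmin(iv$offset, o + ep$length) - pmax(iv$onset, o)))
  }, 0)
  ep$bad_gaze <- ep$bad_gaze | (ov > min_overlap * ep$length)
  ep
}

#' Subset an epoch set to kept epochs
#' @param ep an `epoch_set`.
#' @return an `epoch_set` containing only kept epochs.
#' @export
kept_epochs <- function(ep) {
  keep <- epoch_status(ep) == "kept"
  new_epoch_set(ep$data[, , keep, drop = FALSE], ep$onsets[keep], ep$length,
                ep$overlap, ep$fs, ep$channel_labels)
}

#' Minimum clean-segment inclusion gate
#'
#' A participant's recording enters the analysis only if at least
#' `min_segments` clean non-overlapping segments survive rejection.
#'
#' @param ep the non-overlapping `epoch_set` after rejection.
#' @param min_segments required clean-segment count.
#' @return list with `included` (logical) and `n_clean`.
#' @export
inclusion_gate <- function(ep, min_segments = 10) {
  n_clean <- sum(epoch_status(ep) == "kept")
  list(included = n_clean >= min_segments, n_clean = n_clean)
}

#' Cut 50%-overlap epochs within contiguous clean runs
#'
#' Builds the PSD-path epoch stream: half-overlapping windows are cut only
#' inside contiguous runs of kept non-overlapping segments, so no window
#' spans a rejected second (a run of m clean seconds yields 2m - 1
#' windows).
#'
#' @param rec the filtered [eeg_recording()].
#' @param ep the rejected non-overlapping `epoch_set` of `rec`.
#' @param overlap overlap fraction for the new windows.
#' @return an `epoch_set` (all kept).
#' @export
overlap_epochs_within_runs <- function(rec, ep, overlap = 0.5) {
  keep_on <- ep$onsets[epoch_status(ep) == "kept"]
  if (!length(keep_on))
    stop_thetamod("no kept segments to window", "thetamod_empty_error")
  len <- ep$length
  step <- len * (1 - overlap)
  runs <- split(keep_on, cumsum(c(1, diff(keep_on) > len + 1e-9)))
  onsets <- unlist(lapply(runs, function(r) {
    seq(r[1], r[length(r)], by = step)
  }), use.names = FALSE)
  fs <- rec$fs
  n_len <- as.integer(round(len * fs))
  data <- extract_windows(rec$signal, onsets, fs, n_len)
  new_epoch_set(data, onsets, len, overlap, fs, rec$channel_labels)
}

#' Export the per-epoch status table
#' @param ep an `epoch_set`.
#' @return data.frame with `onset` and `status` for audit.
#' @export
epoch_status_table <- function(ep) {
  data.frame(onset = ep$onsets, status = epoch_status(ep),
             stringsAsFactors = FALSE)
}
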