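# Band-activity indices: Welch PSD, log-domain absolute band power,
# linear relative band power, per-segment band power and the modulation
# index (power-versus-time Pearson correlation).

roi_indices <- function(channel_labels, roi) {
  idx <- match(roi, channel_labels)
  if (anyNA(idx))
    stop_thetamod(paste0("ROI channel(s) not present in recording: ",
                         paste(roi[is.na(idx)], collapse = ", ")),
                  "thetamod_channel_error")
  idx
}

band_bins <- function(freqs, band, endpoints = "inclusive") {
  if (endpoints == "inclusive")
    which(freqs >= band$low - 1e-9 & freqs <= band$high + 1e-9)
  else
    which(freqs >= band$low - 1e-9 & freqs < band$high - 1e-9)
}

band_integral <- function(freqs, vals, rule = "trapezoid") {
  if (rule == "trapezoid") trapz(freqs, vals) else sum(vals)
}

# One-sided Hamming-windowed periodograms for every epoch at once.
# Returns freqs and an array n_freq x n_ch x n_epoch of densities in
# microvolt^2 / Hz; total one-sided integral of a stationary signal
# matches its variance (window-energy corrected).
epoch_periodograms <- function(ep) {
  d <- dim(ep$data)
  n_ch <- d[1]; n_len <- d[2]; n_ep <- d[3]
  w <- hamming_window(n_len)
  U <- ep$fs * sum(w^2)
  # samples x (channels*epochs) matrix, windowed, one FFT call
  m <- matrix(aperm(ep$data, c(2, 1, 3)), nrow = n_len) * w
  X <- stats::mvfft(m)
  nf <- n_len %/% 2 + 1
  p <- Mod(X[seq_len(nf), , drop = FALSE])^2 / U
  if (nf > 2) p[2:(nf - 1), ] <- 2 * p[2:(nf - 1), ]
  freqs <- (seq_len(nf) - 1) * ep$fs / n_len
  list(freqs = freqs, p = array(p, dim = c(nf, n_ch, n_ep)))
}

#' Welch power spectral density of an epoch set
#'
#' Averages Hamming-windowed one-sided periodograms over the kept epochs.
#' With 1-second windows the frequency resolution is 1 Hz. Scaling is
#' density (microvolt^2/Hz) with window-energy correction, so the
#' integrated PSD of a stationary signal matches its variance.
#'
#' @param ep an `epoch_set` (typically the 50%-overlap stream); only kept
#'   epochs contribute.
#' @return list of class `psd_result`: `freqs`, `psd` (channels x
#'   frequencies), `n_windows_used`, `channel_labels`.
#' @export
compute_psd <- function(ep) {
  stopifnot(inherits(ep, "epoch_set"))
  ep <- kept_epochs(ep)
  n_ep <- dim(ep$data)[3]
  if (n_ep == 0)
    stop_thetamod("no kept epochs to estimate a PSD from", "thetamod_empty_error")
  pg <- epoch_periodograms(ep)
  psd <- t(rowMeans(pg$p, dims = 2))          # channels x freqs
  structure(list(freqs = pg$freqs, psd = psd, n_windows_used = n_ep,
                 channel_labels = ep$channel_labels),
            class = "psd_result")
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf("<psd_result> %d channels, %g-%g Hz at %g Hz resolution (%d windows)\n",
              nrow(x$psd), min(x$freqs), max(x$freqs), diff(x$freqs[1:2]),
              x$n_windows_used))
  invisible(x)
}

#' Absolute band power (log-domain band-integrated PSD)
#'
#' The PSD is log-transformed per channel and frequency bin, averaged over
#' the ROI channels, and integrated over the band (trapezoid rule on the
#' 1-Hz grid, endpoints inclusive, by default). Log-then-average ordering
#' matters and is tested; the result is in log-power units.
#'
#' @param psd a `psd_result`.
#' @param band a [band_definition()].
#' @param roi channel labels to average over.
#' @param log_base base of the log transform (10 by default).
#' @param rule `"trapezoid"` or `"rectangular"`.
#' @param endpoints `"inclusive"` or `"half_open"`.
#' @return scalar band power.
#' @export
absolute_band_power <- function(psd, band, roi = ROI_FRONTOCENTRAL,
                                log_base = 10, rule = "trapezoid",
                                endpoints = "inclusive") {
  idx <- roi_indices(psd$channel_labels, roi)
  bins <- band_bins(psd$freqs, band, endpoints)
  if (!length(bins))
    stop_thetamod("band contains no frequency bins", "thetamod_param_error")
  block <- psd$psd[idx, bins, drop = FALSE]
  if (any(block <= 0))
    stop_thetamod("PSD is zero in the band on an ROI channel; log-domain power undefined",
                  "thetamod_log_error")
  avg <- colMeans(log(block, base = log_base))
  band_integral(psd$freqs[bins], avg, rule)
}

#' Relative band power
#'
#' ROI-averaged linear band power divided by ROI-averaged linear total
#' power (1-45 Hz by default); no log transform. Lies in (0, 1) and
#' disjoint bands partitioning the total band sum to 1.
#'
#' @inheritParams absolute_band_power
#' @param total the denominator [band_definition()].
#' @return scalar in (0, 1).
#' @export
relative_band_power <- function(psd, band, total = band_total(),
                                roi = ROI_FRONTOCENTRAL, rule = "trapezoid",
                                endpoints = "inclusive") {
  idx <- roi_indices(psd$channel_labels, roi)
  avg <- colMeans(psd$psd[idx, , drop = FALSE])
  bins_b <- band_bins(psd$freqs, band, endpoints)
  bins_t <- band_bins(psd$freqs, total, endpoints)
  denom <- band_integral(psd$freqs[bins_t], avg[bins_t], rule)
  if (denom <= 0)
    stop_thetamod("total band power is zero", "thetamod_division_error")
  band_integral(psd$freqs[bins_b], avg[bins_b], rule) / denom
}

#' Per-segment band power series
#'
#' One-sided Hamming periodogram per kept non-overlapping segment, linear
#' band integral, averaged over ROI channels. Original segment onsets are
#' carried through for the modulation index.
#'
#' @param ep the non-overlapping `epoch_set`; only kept segments are used.
#' @inheritParams absolute_band_power
#' @return list of class `band_power_series`: `onsets` (s), `power`
#'   (microvolt^2).
#' @export
band_power_per_segment <- function(ep, band, roi = ROI_FRONTOCENTRAL,
                                   rule = "trapezoid",
                                   endpoints = "inclusive") {
  stopifnot(inherits(ep, "epoch_set"))
  ep <- kept_epochs(ep)
  if (dim(ep$data)[3] == 0)
    stop_thetamod("no kept segments", "thetamod_empty_error")
  idx <- roi_indices(ep$channel_labels, roi)
  pg <- epoch_periodograms(ep)
  bins <- band_bins(pg$freqs, band, endpoints)
  pwr <- vapply(seq_len(dim(pg$p)[3]), function(k) {
    avg <- rowMeans(pg$p[bins, idx, k, drop = FALSE], dims = 1)
    band_integral(pg$freqs[bins], avg, rule)
  }, 0)
  structure(list(onsets = ep$onsets, power = pwr),
            class = "band_power_series")
}

#' Modulation index: power-versus-time correlation
#'
#' Pearson correlation between per-segment band power and time, indexing
#' the change of band power over stimulus viewing. The time vector is the
#' segment's chronological onset by default, or its rank within the
#' retained sequence.
#'
#' @param series a `band_power_series`.
#' @param time_basis `"onset_time"` or `"retained_rank"`.
#' @return Pearson r in `[-1, 1]`.
#' @export
modulation_index <- function(series,
                             time_basis = c("onset_time", "retained_rank")) {
  time_basis <- match.arg(time_basis)
  n <- length(series$power)
  if (n < 3)
    stop_thetamod(sprintf("need at least 3 segments for a modulation index (got %d)", n),
                  "thetamod_insufficient_data")
  tv <- if (time_basis == "onset_time") series$onsets else seq_len(n)
  if (stats::sd(series$power) == 0 || stats::sd(tv) == 0)
    stop_thetamod("constant power or time vector: correlation undefined",
                  "thetamod_undefined_correlation")
  stats::cor(series$power, tv)
}

#' Compute the full index set for one recording
#'
#' Runs the index pipeline: band-pass filter, 1-second segmentation (both
#' the non-overlapping modulation stream and the 50%-overlap PSD stream),
#' amplitude and gaze rejection, the minimum-clean-segment gate, then the
#' three indices over the ROI. Excluded recordings yield `included =
#' FALSE` with missing indices.
#'
#' @param rec an [eeg_recording()].
#' @param gaze data.frame of look-away intervals (may be empty).
#' @param band a [band_definition()].
#' @param config a [theta_config()].
#' @return list of class `index_set`: `absolute_power`, `relative_power`,
#'   `modulation_index`, `n_clean_segments`, `included`, `band`.
#' @export
compute_index_set <- function(rec, gaze = NULL, band = band_theta(),
                              config = theta_config()) {
  roi_indices(rec$channel_labels, config$roi)    # fail early, naming channel
  filt <- bandpass_filter(rec, config$filter_low, config$filter_high,
                          config$transition_low, config$transition_high)
  if (isTRUE(config$average_reference)) filt <- average_reference(filt)
  ep0 <- epoch_recording(filt, config$epoch_length, overlap = 0)
  ep0 <- reject_amplitude(ep0, config$amplitude_threshold)
  if (!is.null(gaze) && nrow(gaze))
    ep0 <- reject_gaze(ep0, gaze, config$gaze_min_overlap)
  gate <- inclusion_gate(ep0, config$min_segments)
  if (!gate$included) {
    return(structure(list(absolute_power = NA_real_, relative_power = NA_real_,
                          modulation_index = NA_real_,
                          n_clean_segments = gate$n_clean, included = FALSE,
                          band = band$name), class = "index_set"))
  }
  ep_half <- if (isTRUE(config$overlap_after_selection)) {
    overlap_epochs_within_runs(filt, ep0, config$power_overlap)
  } else {
    eph <- epoch_recording(filt, config$epoch_length, config$power_overlap)
    eph <- reject_amplitude(eph, config$amplitude_threshold)
    if (!is.null(gaze) && nrow(gaze))
      eph <- reject_gaze(eph, gaze, config$gaze_min_overlap)
    eph
  }
  psd <- compute_psd(ep_half)
  abs_p <- absolute_band_power(psd, band, config$roi, config$log_base,
                               config$integration, config$band_endpoints)
  rel_p <- relative_band_power(psd, band, config$total_band, config$roi,
                               config$integration, config$band_endpoints)
  series <- band_power_per_segment(ep0, band, config$roi,
                                   config$integration, config$band_endpoints)
  mi <- modulation_index(series, config$time_basis)
  structure(list(absolute_power = abs_p, relative_power = rel_p,
                 modulation_index = mi, n_clean_segments = gate$n_clean,
                 included = TRUE, band = band$name), class = "index_set")
}

#' @export
print.index_set <- function(x, ...) {
  cat(sprintf("<index_set> band %s | included %s | n_clean %d\n",
              x$band, x$included, x$n_clean_segments))
  if (x$included)
    cat(sprintf("  absolute %.3f | relative %.3f | modulation %.3f\n",
                x$absolute_power, x$relative_power, x$modulation_index))
  invisible(x)
}
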