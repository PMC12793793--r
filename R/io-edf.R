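# Minimal European Data Format (EDF) reader and writer.
#
# Covers the plain continuous-EEG subset of EDF: 16-bit little-endian
# samples, one fixed-length data record layout, per-channel linear
# digital-to-physical scaling. Annotations channels (EDF+) are not handled.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) edf_pad(formatC(x, format = "g", digits = 7), width)

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16 bits over each channel's observed range, the
#' usual EDF encoding; the quantization step is `range/65535` microvolts.
#' Recordings whose sample count is not a whole number of 1-second records
#' are zero-padded on disk and the true sample count is stored in the header
#' reserved field so [read_edf()] restores the exact length.
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop_thetamod("EDF writer requires an integer sampling rate", "thetamod_param_error")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$signal)
  n_samp <- ncol(rec$signal)
  n_rec <- ceiling(n_samp / fs)

  # headroom so the formatted 8-char physical range never clips a sample;
  # digitization must use the formatted (truncated) range the header stores
  r <- pmax(apply(abs(rec$signal), 1, max), 1) * 1.01
  pmin_fmt <- as.numeric(edf_num(-r, 8))
  pmax_fmt <- as.numeric(edf_num(r, 8))
  digital <- matrix(0L, ns, n_rec * fs)
  for (ch in seq_len(ns)) {
    x <- rec$signal[ch, ]
    d <- round((x - pmin_fmt[ch]) / (pmax_fmt[ch] - pmin_fmt[ch]) * 65535 - 32768)
    digital[ch, seq_len(n_samp)] <- as.integer(pmin(pmax(d, -32768), 32767))
  }

  header_bytes <- 256L + 256L * ns
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  put(edf_pad("0", 8))
  put(edf_pad(rec$meta$subject_id %||% "X", 80))
  put(edf_pad(rec$meta$recording_id %||% "thetamod", 80))
  put(edf_pad("01.01.00", 8))
  put(edf_pad("00.00.00", 8))
  put(edf_pad(header_bytes, 8))
  put(edf_pad(sprintf("NS:%d", n_samp), 44))
  put(edf_pad(n_rec, 8))
  put(edf_pad("1", 8))
  put(edf_pad(ns, 4))
  put(paste0(vapply(rec$channel_labels, edf_pad, "", width = 16), collapse = ""))
  put(strrep(" ", 80 * ns))
  put(strrep(edf_pad("uV", 8), ns))
  put(paste0(edf_num(pmin_fmt, 8), collapse = ""))
  put(paste0(edf_num(pmax_fmt, 8), collapse = ""))
  put(strrep(edf_pad("-32768", 8), ns))
  put(strrep(edf_pad("32767", 8), ns))
  put(strrep(" ", 80 * ns))
  put(strrep(edf_pad(fs, 8), ns))
  put(strrep(" ", 32 * ns))
  # data records: per record, each signal's fs samples contiguously
  arr <- array(digital, dim = c(ns, fs, n_rec))
  writeBin(as.integer(as.vector(aperm(arr, c(2, 1, 3)))), con,
           size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF recording
#'
#' @param path path to an EDF file.
#' @return an [eeg_recording()] in microvolts, channel order as on disk.
#' @export
read_edf <- function(path) {
  if (!file.exists(path))
    stop_thetamod(sprintf("file not found: %s", path), "thetamod_io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  get <- function(n) {
    raw <- readChar(con, n, useBytes = TRUE)
    if (nchar(raw, type = "bytes") < n)
      stop_thetamod("truncated EDF header (fixed part)", "thetamod_format_error")
    trimws(raw)
  }
  num <- function(s, field) {
    v <- suppressWarnings(as.numeric(s))
    if (anyNA(v))
      stop_thetamod(sprintf("EDF header field '%s' is not numeric: '%s'",
                            field, s[is.na(v)][1]), "thetamod_format_error")
    v
  }
  get(8)                       # version
  patient <- get(80)
  recording_id <- get(80)
  get(8); get(8)               # date, time
  num(get(8), "header_bytes")
  reserved <- get(44)
  n_rec <- num(get(8), "n_records")
  rec_dur <- num(get(8), "record_duration")
  ns <- as.integer(num(get(4), "n_signals"))
  if (ns < 1) stop_thetamod("EDF header field 'n_signals' must be >= 1",
                            "thetamod_format_error")
  field <- function(w) vapply(seq_len(ns), function(i) get(w), "")
  labels <- field(16)
  field(80)                    # transducer
  dims <- field(8)
  pmin <- num(field(8), "physical_min")
  pmax_ <- num(field(8), "physical_max")
  dmin <- num(field(8), "digital_min")
  dmax <- num(field(8), "digital_max")
  field(80)                    # prefiltering
  spr <- as.integer(num(field(8), "samples_per_record"))
  field(32)                    # reserved

  if (length(unique(spr)) != 1)
    stop_thetamod("EDF reader supports a single common sampling rate only",
                  "thetamod_format_error")
  fs <- spr[1] / rec_dur
  n_total <- n_rec * spr[1]
  vals <- readBin(con, "integer", n = n_total * ns, size = 2,
                  signed = TRUE, endian = "little")
  if (length(vals) < n_total * ns)
    stop_thetamod("EDF data section shorter than header declares",
                  "thetamod_format_error")
  # vals laid out record-major: [rec1: sig1 spr, sig2 spr, ...][rec2: ...]
  arr <- array(vals, dim = c(spr[1], ns, n_rec))
  signal <- matrix(0, ns, n_total)
  for (ch in seq_len(ns)) signal[ch, ] <- as.vector(arr[, ch, ])

  scale_unit <- vapply(dims, function(d) {
    if (d %in% c("uV", "µV", "μV")) 1
    else if (d == "V") 1e6
    else stop_thetamod(
      sprintf("unsupported physical dimension '%s' (expected uV or V)", d),
      "thetamod_unit_error")
  }, 0)
  gain <- (pmax_ - pmin) / (dmax - dmin)
  signal <- (signal - dmin) * gain + pmin
  signal <- signal * scale_unit

  if (grepl("^NS:\\d+$", reserved)) {
    true_n <- as.integer(sub("^NS:", "", reserved))
    if (true_n <= n_total) signal <- signal[, seq_len(true_n), drop = FALSE]
  }
  eeg_recording(signal, fs, labels,
                meta = list(source = path, patient = patient,
                            recording_id = recording_id))
}
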