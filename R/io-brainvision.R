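# BrainVision Core format (.vhdr header + .eeg data + .vmrk markers).
# Supports multiplexed/vectorized orientation, IEEE_FLOAT_32 or INT_16
# binary data, and ASCII data; per-channel resolution and unit scaling.

parse_vhdr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("Brain Vision Data Exchange Header File",
                               lines[1], ignore.case = TRUE))
    stop_thetamod("not a BrainVision header: missing identification line",
                  "thetamod_format_error")
  section <- ""
  kv <- list(); channels <- list()
  for (ln in lines[-1]) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) { section <- tolower(gsub("\\[|\\]", "", ln)); next }
    m <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(m) != 3) next
    key <- trimws(m[2]); val <- trimws(m[3])
    if (section == "channel infos" && grepl("^Ch[0-9]+$", key)) {
      channels[[as.integer(sub("^Ch", "", key))]] <- strsplit(val, ",")[[1]]
    } else {
      kv[[paste(section, tolower(key), sep = ".")]] <- val
    }
  }
  list(kv = kv, channels = channels)
}

#' Read a BrainVision Core recording
#'
#' Resolves the data (and marker) files named in the `.vhdr` header,
#' applies per-channel resolution and converts units to microvolts.
#'
#' @param path path to the `.vhdr` header file.
#' @return an [eeg_recording()] in microvolts.
#' @export
read_brainvision <- function(path) {
  if (!file.exists(path))
    stop_thetamod(sprintf("file not found: %s", path), "thetamod_io_error")
  h <- parse_vhdr(path)
  kv <- h$kv
  need <- function(key) {
    v <- kv[[key]]
    if (is.null(v))
      stop_thetamod(sprintf("BrainVision header missing field '%s'",
                            sub("^[^.]*\\.", "", key)), "thetamod_format_error")
    v
  }
  data_file <- file.path(dirname(path), need("common infos.datafile"))
  if (!file.exists(data_file))
    stop_thetamod(sprintf("header references missing data file '%s'",
                          basename(data_file)), "thetamod_format_error")
  n_ch <- as.integer(need("common infos.numberofchannels"))
  samp_int_us <- as.numeric(need("common infos.samplinginterval"))
  fs <- 1e6 / samp_int_us
  orientation <- toupper(kv[["common infos.dataorientation"]] %||% "MULTIPLEXED")
  format <- toupper(need("common infos.dataformat"))

  if (length(h$channels) < n_ch)
    stop_thetamod("BrainVision header missing field 'Channel Infos'",
                  "thetamod_format_error")
  ch <- h$channels[seq_len(n_ch)]
  labels <- vapply(ch, function(x) trimws(x[1]), "")
  resolution <- vapply(ch, function(x) {
    r <- if (length(x) >= 3) suppressWarnings(as.numeric(trimws(x[3]))) else NA
    if (is.na(r)) 1 else r
  }, 0)
  unit <- vapply(ch, function(x)
    if (length(x) >= 4 && nzchar(trimws(x[4]))) trimws(x[4]) else "µV", "")
  unit_scale <- vapply(unit, function(u) {
    if (u %in% c("uV", "µV", "μV")) 1
    else if (u == "V") 1e6
    else stop_thetamod(sprintf("unsupported channel unit '%s' (expected uV or V)", u),
                       "thetamod_unit_error")
  }, 0)

  if (format == "BINARY") {
    bin_fmt <- toupper(kv[["binary infos.binaryformat"]] %||% "IEEE_FLOAT_32")
    sz <- file.size(data_file)
    con <- file(data_file, "rb"); on.exit(close(con))
    if (bin_fmt == "IEEE_FLOAT_32") {
      n_val <- sz %/% 4
      vals <- readBin(con, "numeric", n = n_val, size = 4, endian = "little")
    } else if (bin_fmt == "INT_16") {
      n_val <- sz %/% 2
      vals <- readBin(con, "integer", n = n_val, size = 2, signed = TRUE,
                      endian = "little")
    } else {
      stop_thetamod(sprintf("unsupported BinaryFormat '%s'", bin_fmt),
                    "thetamod_format_error")
    }
    n_samp <- n_val %/% n_ch
    vals <- vals[seq_len(n_samp * n_ch)]
    signal <- if (orientation == "MULTIPLEXED") {
      matrix(vals, nrow = n_ch)                # channel fastest
    } else {
      t(matrix(vals, nrow = n_samp))           # VECTORIZED: sample fastest
    }
  } else if (format == "ASCII") {
    tab <- utils::read.table(data_file, header = FALSE)
    signal <- if (orientation == "MULTIPLEXED") t(as.matrix(tab)) else as.matrix(tab)
    if (nrow(signal) != n_ch && ncol(signal) == n_ch) signal <- t(signal)
  } else {
    stop_thetamod(sprintf("unsupported DataFormat '%s'", format),
                  "thetamod_format_error")
  }
  signal <- signal * resolution * unit_scale
  eeg_recording(signal, fs, labels, meta = list(source = path))
}

#' Write a recording as a BrainVision Core triplet
#'
#' Writes `.vhdr`, `.vmrk` and a multiplexed IEEE float-32 `.eeg` file in
#' microvolts (resolution 1).
#'
#' @param rec an [eeg_recording()].
#' @param path path of the `.vhdr` file to create; companion files take the
#'   same stem.
#' @return `path`, invisibly.
#' @export
write_brainvision <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  stem <- sub("\\.vhdr$", "", path)
  eeg_file <- paste0(basename(stem), ".eeg")
  vmrk_file <- paste0(basename(stem), ".vmrk")
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", eeg_file),
    paste0("MarkerFile=", vmrk_file),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(rec$signal)),
    paste0("SamplingInterval=", format(1e6 / rec$fs, digits = 12)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nrow(rec$signal)), rec$channel_labels))
  writeLines(hdr, paste0(stem, ".vhdr"))
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "[Common Infos]", paste0("DataFile=", eeg_file),
               "[Marker Infos]",
               "Mk1=New Segment,,1,1,0,00000000000000000000"),
             paste0(stem, ".vmrk"))
  con <- file(paste0(stem, ".eeg"), "wb"); on.exit(close(con))
  writeBin(as.vector(rec$signal), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a recording in EDF or BrainVision format
#'
#' @param path input file (`.edf`, or a BrainVision `.vhdr`).
#' @param format `"edf"`, `"brainvision"` or `"auto"` (from the extension).
#' @return an [eeg_recording()] in microvolts; channel order as in the file.
#' @export
read_recording <- function(path, format = c("auto", "edf", "brainvision")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", vhdr = "brainvision",
                     stop_thetamod(sprintf(
                       "cannot infer format from extension '.%s'", ext),
                       "thetamod_format_error"))
  }
  switch(format, edf = read_edf(path), brainvision = read_brainvision(path))
}
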