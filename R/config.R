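#' Frontocentral region of interest
#'
#' The six frontocentral 10-20 electrodes over which all band indices are
#' averaged.
#' @export
ROI_FRONTOCENTRAL <- c("F3", "Fz", "F4", "FC3", "FCz", "FC4")

#' Band definitions
#'
#' Infant-EEG conventions: theta 3-6 Hz and alpha 6-9 Hz (the shared 6 Hz
#' bin belongs to both bands under the default inclusive-endpoint rule);
#' total broadband power is taken over 1-45 Hz.
#'
#' @param name band name.
#' @param low,high band edges in Hz, `0 < low < high`.
#' @return list of class `band_definition`.
#' @export
band_definition <- function(name, low, high) {
  if (!(low > 0 && high > low))
    stop_thetamod("band edges must satisfy 0 < low < high", "thetamod_param_error")
  structure(list(name = name, low = low, high = high), class = "band_definition")
}

#' @rdname band_definition
#' @export
band_theta <- function() band_definition("theta", 3, 6)

#' @rdname band_definition
#' @export
band_alpha <- function() band_definition("alpha", 6, 9)

#' @rdname band_definition
#' @export
band_total <- function() band_definition("total", 1, 45)

#' Pipeline configuration
#'
#' One flat list mapping every numeric parameter of the pipeline to a named
#' key. Defaults are the values used throughout the analyses: a 1-100 Hz
#' zero-phase Hamming FIR band-pass, 1-second epochs (50% overlap on the
#' PSD path, none on the per-segment modulation path), a +/-150 microvolt
#' rejection threshold, gaze-away rejection at any overlap, a 10-segment
#' inclusion minimum, log10 power transform, trapezoid band integration
#' with inclusive endpoints, and chronological-onset time basis for the
#' modulation index.
#'
#' @param ... overrides for any default key.
#' @return named list of class `theta_config`.
#' @export
theta_config <- function(...) {
  cfg <- list(
    filter_low = 1,              # Hz, band-pass low cut-off
    filter_high = 100,           # Hz, band-pass high cut-off
    transition_low = 1,          # Hz, FIR transition width at the low edge
    transition_high = 10,        # Hz, FIR transition width at the high edge
    epoch_length = 1,            # s
    power_overlap = 0.5,         # PSD-path epoch overlap fraction
    amplitude_threshold = 150,   # microvolts, rejection if |x| exceeds
    gaze_min_overlap = 0,        # fraction of epoch; 0 = any overlap rejects
    min_segments = 10,           # clean non-overlap segments for inclusion
    total_band = band_total(),   # denominator band for relative power
    log_base = 10,               # log transform base for absolute power
    integration = "trapezoid",   # or "rectangular"
    band_endpoints = "inclusive",# or "half_open" (drop the upper edge bin)
    time_basis = "onset_time",   # or "retained_rank"
    overlap_after_selection = TRUE, # cut 50%-overlap windows within kept runs
    average_reference = FALSE,   # optional re-reference before indexing
    roi = ROI_FRONTOCENTRAL,
    icc_form = "agreement",      # or "consistency"
    spearman_brown = FALSE)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop_thetamod(paste0("unknown configuration key(s): ",
                         paste(unknown, collapse = ", ")),
                  "thetamod_param_error")
  cfg[names(dots)] <- dots
  structure(cfg, class = "theta_config")
}
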