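# Synthetic continuous EEG: 1/f^chi Gaussian background, narrowband
# oscillations with a linear amplitude envelope (band-limited noise or pure
# sinusoid carrier), and Poisson-placed raised-cosine artifact transients.

#' Describe one narrowband oscillation
#'
#' @param center_freq center frequency in Hz.
#' @param bandwidth full bandwidth in Hz (carrier occupies
#'   `center_freq +/- bandwidth/2`).
#' @param base_amplitude envelope value at t = 0, in microvolts. For the
#'   `"noise"` carrier this is the instantaneous RMS amplitude; for the
#'   `"sinusoid"` carrier it is the peak amplitude.
#' @param amplitude_slope envelope change in microvolts per second; a
#'   positive slope makes band power rise over the recording.
#' @param target_channels channels receiving the oscillation.
#' @param carrier `"noise"` (band-limited Gaussian noise, the realistic
#'   default) or `"sinusoid"` (analytic tone, used for closed-form oracles).
#' @return list of class `oscillation_spec`.
#' @export
oscillation_spec <- function(center_freq, bandwidth, base_amplitude,
                             amplitude_slope = 0,
                             target_channels = ROI_FRONTOCENTRAL,
                             carrier = c("noise", "sinusoid")) {
  carrier <- match.arg(carrier)
  if (bandwidth <= 0)
    stop_thetamod("oscillation bandwidth must be > 0", "thetamod_config_error")
  if (base_amplitude < 0)
    stop_thetamod("oscillation amplitude must be >= 0", "thetamod_config_error")
  structure(list(center_freq = center_freq, bandwidth = bandwidth,
                 base_amplitude = base_amplitude,
                 amplitude_slope = amplitude_slope,
                 target_channels = target_channels, carrier = carrier),
            class = "oscillation_spec")
}

#' Configuration for the EEG signal generator
#'
#' Defaults emulate the study conditions: a 134-second stimulus-viewing
#' recording at 500 Hz over the six frontocentral ROI channels plus two
#' occipital distractor channels, a 1/f background, a theta oscillation
#' whose amplitude ramps up over viewing, a weaker ramping alpha
#' oscillation, and occasional high-amplitude artifacts that trip the
#' +/-150 microvolt rejection rule.
#'
#' @param duration recording length in seconds.
#' @param fs sampling rate in Hz.
#' @param channel_labels channel names.
#' @param aperiodic_exponent chi of the 1/f^chi background power spectrum.
#' @param aperiodic_scale background RMS amplitude in microvolts.
#' @param oscillations list of [oscillation_spec()] entries.
#' @param artifact_rate transients per minute.
#' @param artifact_amplitude transient peak in microvolts.
#' @param seed RNG seed (NULL = use current stream).
#' @return list of class `signal_sim_config`.
#' @export
signal_sim_config <- function(duration = 134, fs = 500,
                              channel_labels = c(ROI_FRONTOCENTRAL, "O1", "O2"),
                              aperiodic_exponent = 1, aperiodic_scale = 15,
                              oscillations = list(
                                oscillation_spec(4.5, 3, 6, 0.03),
                                oscillation_spec(7.5, 3, 4, 0.01)),
                              artifact_rate = 2, artifact_amplitude = 300,
                              seed = NULL) {
  n <- duration * fs
  if (abs(n - round(n)) > 1e-9)
    stop_thetamod("duration * fs must be a whole number of samples",
                  "thetamod_config_error")
  for (osc in oscillations) {
    if (osc$base_amplitude + osc$amplitude_slope * duration < 0)
      stop_thetamod(
        "oscillation envelope becomes negative before the recording ends",
        "thetamod_config_error")
  }
  structure(list(duration = duration, fs = fs, channel_labels = channel_labels,
                 aperiodic_exponent = aperiodic_exponent,
                 aperiodic_scale = aperiodic_scale,
                 oscillations = oscillations, artifact_rate = artifact_rate,
                 artifact_amplitude = artifact_amplitude, seed = seed),
            class = "signal_sim_config")
}

# Gaussian noise with a prescribed amplitude spectrum, unit RMS per
# column. Synthesized in the frequency domain: complex white coefficients
# shaped by `amp` (a symmetric two-sided amplitude profile), one inverse
# FFT; the real part is a Gaussian process with PSD proportional to amp^2.
shaped_noise <- function(n, amp, n_col) {
  # hermitian half-spectrum with draws only at nonzero-amplitude bins
  pos <- 2:(floor((n - 1) / 2) + 1)
  pos <- pos[amp[pos] != 0]
  m <- length(pos)
  Z <- matrix(0i, n, n_col)
  Z[pos, ] <- complex(real = stats::rnorm(m * n_col),
                      imaginary = stats::rnorm(m * n_col)) * amp[pos]
  Z[n + 2 - pos, ] <- Conj(Z[pos, ])
  if (n %% 2 == 0 && amp[n / 2 + 1] != 0)
    Z[n / 2 + 1, ] <- stats::rnorm(n_col) * amp[n / 2 + 1]
  x <- Re(stats::mvfft(Z, inverse = TRUE))
  x / rep(sqrt(colMeans(x^2)), each = n)
}

two_sided_freqs <- function(n, fs) {
  f <- c(0, seq_len(n - 1)) * fs / n
  pmin(f, fs - f)
}

# 1/f^chi background, unit RMS per column
colored_noise <- function(n, fs, chi, n_col = 1) {
  if (chi == 0) return(matrix(stats::rnorm(n * n_col), n, n_col))
  f <- two_sided_freqs(n, fs)
  amp <- ifelse(f > 0, f^(-chi / 2), 0)
  shaped_noise(n, amp, n_col)
}

# Band-limited unit-RMS Gaussian noise (brick-wall band selection)
bandlimited_noise <- function(n, fs, low, high, n_col = 1) {
  f <- two_sided_freqs(n, fs)
  shaped_noise(n, as.numeric(f >= low & f <= high), n_col)
}

#' Simulate a continuous EEG recording
#'
#' Background, oscillations and artifacts are summed per channel; a fixed
#' seed yields identical output. See [signal_sim_config()] for the model.
#'
#' @param config a [signal_sim_config()].
#' @return an [eeg_recording()].
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "signal_sim_config"))
  with_seed(config$seed, {
    fs <- config$fs
    n <- as.integer(round(config$duration * fs))
    labels <- config$channel_labels
    n_ch <- length(labels)
    t <- (seq_len(n) - 1) / fs
    sig <- config$aperiodic_scale *
      t(colored_noise(n, fs, config$aperiodic_exponent, n_ch))
    for (osc in config$oscillations) {
      env <- osc$base_amplitude + osc$amplitude_slope * t
      targets <- match(osc$target_channels, labels)
      targets <- targets[!is.na(targets)]
      if (!length(targets)) next
      lo <- osc$center_freq - osc$bandwidth / 2
      hi <- osc$center_freq + osc$bandwidth / 2
      carriers <- if (osc$carrier == "noise") {
        bandlimited_noise(n, fs, lo, hi, length(targets))
      } else {
        sapply(seq_along(targets), function(i)
          sin(2 * pi * osc$center_freq * t + stats::runif(1, 0, 2 * pi)))
      }
      sig[targets, ] <- sig[targets, ] + t(carriers * env)
    }
    n_art <- stats::rpois(1, config$artifact_rate * config$duration / 60)
    if (n_art > 0) {
      width <- 0.2                                  # 200 ms raised cosine
      wn <- round(width * fs)
      shape <- 0.5 * (1 - cos(2 * pi * (0:(wn - 1)) / (wn - 1)))
      onsets <- stats::runif(n_art, 0, config$duration - width)
      for (o in onsets) {
        i0 <- round(o * fs) + 1
        idx <- i0:(i0 + wn - 1)
        sig[, idx] <- sig[, idx] +
          rep(config$artifact_amplitude * shape, each = n_ch)
      }
      attr_onsets <- onsets
    } else attr_onsets <- numeric()
    rec <- eeg_recording(sig, fs, labels,
                         meta = list(simulated = TRUE,
                                     artifact_onsets = sort(attr_onsets),
                                     artifact_width = 0.2))
    rec
  })
}

#' Simulate gaze look-away annotations
#'
#' Alternating look / look-away bouts with exponential lengths. The away
#' bout mean is `mean_bout_length`; the look bout mean is chosen so the
#' long-run away fraction equals `away_fraction`. The first state is drawn
#' from the stationary distribution so the realized fraction is unbiased.
#'
#' @param duration recording length in seconds.
#' @param away_fraction target fraction of time looking away, in `[0, 1)`.
#' @param mean_bout_length mean look-away bout length in seconds.
#' @param seed RNG seed.
#' @return data.frame of `look_away` intervals (possibly empty), disjoint,
#'   inside `[0, duration]`.
#' @export
simulate_gaze <- function(duration, away_fraction, mean_bout_length = 3,
                          seed = NULL) {
  if (away_fraction < 0 || away_fraction >= 1)
    stop_thetamod("away_fraction must be in [0, 1)", "thetamod_config_error")
  empty <- data.frame(onset = numeric(), offset = numeric(),
                      label = character(), stringsAsFactors = FALSE)
  if (away_fraction == 0) return(empty)
  with_seed(seed, {
    mean_away <- mean_bout_length
    mean_look <- mean_away * (1 - away_fraction) / away_fraction
    t <- 0
    away <- stats::runif(1) < away_fraction
    res <- list()
    while (t < duration) {
      len <- stats::rexp(1, 1 / (if (away) mean_away else mean_look))
      end <- min(t + len, duration)
      if (away && end > t)
        res[[length(res) + 1]] <- c(t, end)
      t <- end
      away <- !away
    }
    if (!length(res)) return(empty)
    m <- do.call(rbind, res)
    data.frame(onset = m[, 1], offset = m[, 2], label = "look_away",
               stringsAsFactors = FALSE)
  })
}
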