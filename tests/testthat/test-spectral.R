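test_that("Welch PSD satisfies the Parseval tone oracle", {
  # analytic tone: band integral over 3-6 Hz equals A^2/2
  rec <- tone_recording(4.5, 10, duration = 60)
  psd <- compute_psd(epoch_recording(rec, 1, 0.5))
  bins <- psd$freqs >= 3 & psd$freqs <= 6
  integral <- sum(diff(psd$freqs[bins]) *
                    (head(colMeans(psd$psd)[bins], -1) +
                       tail(colMeans(psd$psd)[bins], -1)) / 2)
  expect_equal(integral, 50, tolerance = 0.05)
})

test_that("Welch PSD integrates to the variance of white noise", {
  rec <- white_recording(8, duration = 100, seed = 21)
  psd <- compute_psd(epoch_recording(rec, 1, 0.5))
  total <- sum(colMeans(psd$psd))          # 1-Hz bins: rectangular integral
  expect_equal(total, 64, tolerance = 0.05)
})

test_that("all-zero epochs give an identically zero PSD", {
  rec <- eeg_recording(matrix(0, 2, 5000), 500, c("Fz", "Cz"))
  psd <- compute_psd(epoch_recording(rec, 1, 0.5))
  expect_true(all(psd$psd == 0))
})

test_that("PSD estimation refuses an empty epoch set", {
  rec <- white_recording(5, duration = 4, channels = "Fz")
  ep <- epoch_recording(rec, 1, 0)
  ep$bad_amp[] <- TRUE
  expect_error(compute_psd(ep), class = "thetamod_empty_error")
})

# hand-built PSD object for closed-form index checks
flat_psd <- function(levels, freqs = 0:50,
                     channels = c("F3", "Fz", "F4")) {
  psd <- matrix(rep(levels, each = length(freqs)),
                nrow = length(channels), byrow = TRUE)
  structure(list(freqs = freqs, psd = psd, n_windows_used = 1,
                 channel_labels = channels), class = "psd_result")
}

test_that("absolute band power reproduces constant-spectrum closed forms", {
  psd <- flat_psd(c(10, 10, 10))
  # log10(10) = 1 per bin, trapezoid over [3,6] = 3.0
  expect_equal(absolute_band_power(psd, band_theta(), c("F3", "Fz", "F4")), 3)
  # doubling the PSD adds bandwidth * log10(2)
  psd2 <- flat_psd(c(20, 20, 20))
  expect_equal(absolute_band_power(psd2, band_theta(), c("F3", "Fz", "F4")) -
                 absolute_band_power(psd, band_theta(), c("F3", "Fz", "F4")),
               3 * log10(2))
})

test_that("channels are log-transformed before averaging, not after", {
  psd <- flat_psd(c(10, 1000), channels = c("F3", "Fz"))
  # mean of log10(10)=1 and log10(1000)=3 is 2 per bin -> integral 6;
  # log of the mean power would give log10(505) = 2.70 per bin instead
  expect_equal(absolute_band_power(psd, band_theta(), c("F3", "Fz")), 6)
})

test_that("zero PSD inside the band raises a log-domain error", {
  psd <- flat_psd(c(10, 10, 10))
  psd$psd[2, 5] <- 0
  expect_error(absolute_band_power(psd, band_theta(), c("F3", "Fz", "F4")),
               class = "thetamod_log_error")
})

test_that("monotonicity: pointwise larger PSD gives larger absolute power", {
  set.seed(31)
  for (i in 1:10) {
    base <- flat_psd(runif(3, 1, 5))
    base$psd <- base$psd * rep(runif(51, 0.5, 2), each = 3)
    larger <- base
    larger$psd <- larger$psd * rep(runif(51, 1, 3), each = 3)
    expect_gt(absolute_band_power(larger, band_theta(), c("F3", "Fz", "F4")),
              absolute_band_power(base, band_theta(), c("F3", "Fz", "F4")))
  }
})

test_that("white-noise relative theta approaches the flat-spectrum ratio", {
  rec <- white_recording(8, duration = 100, seed = 23)
  psd <- compute_psd(epoch_recording(rec, 1, 0.5))
  rel <- relative_band_power(psd, band_theta(), roi = c("F3", "Fz", "F4"))
  expect_lt(abs(rel - 3 / 44), 0.01)
})

test_that("relative power is exactly 1 when band equals total", {
  psd <- flat_psd(c(3, 7, 11))
  expect_equal(relative_band_power(psd, band_total(), roi = c("F3", "Fz", "F4")),
               1)
})

test_that("disjoint bands partitioning the total range sum to one", {
  set.seed(33)
  psd <- flat_psd(c(1, 1, 1))
  psd$psd <- psd$psd * rep(runif(51, 0.5, 4), each = 3)
  cuts <- c(1, 7, 13, 28, 45)
  parts <- sapply(1:4, function(i)
    relative_band_power(psd, band_definition("p", cuts[i], cuts[i + 1]),
                        roi = c("F3", "Fz", "F4")))
  expect_equal(sum(parts), 1, tolerance = 1e-6)
})

test_that("per-segment power is stationary for a pure tone", {
  rec <- tone_recording(4.5, 10, duration = 30)
  series <- band_power_per_segment(kept_epochs(epoch_recording(rec, 1, 0)),
                                   band_theta(), c("F3", "Fz", "F4"))
  expect_equal(length(series$power), 30)
  expect_lt(sd(series$power) / mean(series$power), 0.05)
})

test_that("doubling the envelope quadruples per-segment band power", {
  fs <- 500; dur <- 30
  t <- (seq_len(dur * fs) - 1) / fs
  env <- 5 * (1 + t / dur)                # 5 -> 10 uV over the recording
  x <- env * sin(2 * pi * 4.5 * t)
  rec <- eeg_recording(matrix(x, 1), fs, "Fz")
  series <- band_power_per_segment(kept_epochs(epoch_recording(rec, 1, 0)),
                                   band_theta(), "Fz")
  ratio <- series$power[dur] / series$power[1]
  expect_equal(ratio, 4, tolerance = 0.2)
  # single kept segment still yields a length-1 series
  one <- epoch_recording(rec, 1, 0)
  one$bad_amp[-1] <- TRUE
  expect_equal(length(band_power_per_segment(kept_epochs(one), band_theta(),
                                             "Fz")$power), 1)
})

test_that("modulation index handles monotone, constant and short series", {
  mk <- function(p, o = seq_along(p) - 1)
    structure(list(onsets = o, power = p), class = "band_power_series")
  expect_equal(modulation_index(mk(1:5)), 1)
  expect_equal(modulation_index(mk(5:1)), -1)
  expect_error(modulation_index(mk(c(2, 2, 2))),
               class = "thetamod_undefined_correlation")
  expect_error(modulation_index(mk(c(1, 2))),
               class = "thetamod_insufficient_data")
})

test_that("modulation index is centered at zero under shuffling", {
  set.seed(35)
  base <- (1:50) + rnorm(50)
  rs <- replicate(1000, {
    p <- sample(base)
    cor(p, 0:49)
  })
  # independent permutation null for the implementation to match
  mk <- structure(list(onsets = 0:49, power = base),
                  class = "band_power_series")
  expect_equal(modulation_index(mk), cor(base, 0:49))
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("modulation index is invariant to affine rescaling", {
  set.seed(36)
  p <- cumsum(runif(20)); o <- sort(runif(20, 0, 100))
  mk <- function(p, o) structure(list(onsets = o, power = p),
                                 class = "band_power_series")
  r0 <- modulation_index(mk(p, o))
  expect_equal(modulation_index(mk(3 * p + 7, o)), r0)
  expect_equal(modulation_index(mk(p, 0.5 * o + 2)), r0)
})

test_that("retained-rank and onset-time bases agree on gap-free series", {
  mk <- structure(list(onsets = 0:19, power = (1:20) + sin(1:20)),
                  class = "band_power_series")
  expect_equal(modulation_index(mk, "onset_time"),
               modulation_index(mk, "retained_rank"))
})

test_that("the index pipeline recovers a ramping theta oscillation", {
  cfg <- signal_sim_config(
    duration = 134, seed = 55, artifact_rate = 0,
    oscillations = list(oscillation_spec(4.5, 3, 6, 0.03)))
  idx <- compute_index_set(simulate_recording(cfg), NULL)
  expect_true(idx$included)
  expect_gt(idx$modulation_index, 0)
  expect_true(idx$relative_power > 0 && idx$relative_power < 1)
})

test_that("heavy artifacts below the segment minimum exclude the subject", {
  rec <- white_recording(5, duration = 20, channels = ROI_FRONTOCENTRAL,
                         seed = 44)
  rec$signal[1, seq(100, 9600, by = 450)] <- 400   # trips most epochs
  gaze <- data.frame(onset = 0, offset = 6, label = "look_away")
  idx <- compute_index_set(rec, gaze)
  expect_false(idx$included)
  expect_true(is.na(idx$absolute_power))
  expect_true(is.na(idx$modulation_index))
  expect_lt(idx$n_clean_segments, 10)
})

test_that("out-of-band tones leave relative theta near the noise floor", {
  fs <- 500; dur <- 60
  t <- (seq_len(dur * fs) - 1) / fs
  set.seed(45)
  noise <- matrix(rnorm(6 * dur * fs, sd = 5), 6)
  tone <- 30 * sin(2 * pi * 12 * t)
  rec <- eeg_recording(noise + rep(tone, each = 6), fs, ROI_FRONTOCENTRAL)
  idx_theta <- compute_index_set(rec, NULL, band_theta())
  # theta band holds only the white-noise floor ~ 3/44 of noise power,
  # shrunk further by the tone's contribution to the 1-45 Hz total
  expect_lt(idx_theta$relative_power, 3 / 44)
})

test_that("missing ROI channels are reported by name", {
  rec <- white_recording(5, duration = 15, channels = c("F3", "Fz", "F4"))
  expect_error(compute_index_set(rec, NULL), class = "thetamod_channel_error")
  expect_error(compute_index_set(rec, NULL), "FC3")
})
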