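test_that("band-pass filter attenuates sub-band tones by at least 20 dB", {
  rec <- tone_recording(0.1, 10, duration = 60, channels = "Fz")
  out <- bandpass_filter(rec)
  atten_db <- 20 * log10(sd(out$signal[1, ]) / sd(rec$signal[1, ]))
  expect_lt(atten_db, -20)
})

test_that("band-pass filter passes in-band tones essentially unchanged", {
  rec <- tone_recording(10, 10, duration = 60, channels = "Fz")
  out <- bandpass_filter(rec)
  mid <- 5000:25000                       # avoid convolution edge roll-in
  ratio <- sd(out$signal[1, mid]) / sd(rec$signal[1, mid])
  expect_equal(ratio, 1, tolerance = 0.05)
})

test_that("filter frequency response has < 0.5 dB passband ripple (2-90 Hz)", {
  fs <- 500
  order <- ceiling(3.3 * fs / 1); if (order %% 2 == 1) order <- order + 1
  h <- signal::fir1(order, c(1, 100) / (fs / 2), type = "pass")
  nfft <- 2^16
  H <- abs(fft(c(h, numeric(nfft - length(h)))))[1:(nfft / 2)]
  f <- (0:(nfft / 2 - 1)) * fs / nfft
  pass <- f >= 2 & f <= 90
  expect_lt(max(abs(20 * log10(H[pass]))), 0.5)
})

test_that("filtering is zero-phase: a passband tone keeps its phase", {
  rec <- tone_recording(10, 10, duration = 20, channels = "Fz")
  out <- bandpass_filter(rec)
  mid <- 3000:7000
  # delay-compensated linear phase FIR: output aligns with input exactly
  expect_gt(cor(out$signal[1, mid], rec$signal[1, mid]), 0.99999)
})

test_that("all-zero signals filter to all-zero", {
  rec <- eeg_recording(matrix(0, 2, 2000), 500, c("Fz", "Cz"))
  expect_equal(max(abs(bandpass_filter(rec)$signal)), 0)
})

test_that("cut-offs at or above Nyquist are rejected", {
  rec <- tone_recording(10, 1, duration = 2, channels = "Fz")
  expect_error(bandpass_filter(rec, 1, 250), class = "thetamod_param_error")
})

test_that("epoch counts follow the window arithmetic", {
  rec <- white_recording(5, duration = 134, channels = "Fz")
  expect_equal(length(epoch_recording(rec, 1, 0)$onsets), 134)
  expect_equal(length(epoch_recording(rec, 1, 0.5)$onsets), 267)
  short <- white_recording(5, duration = 10, channels = "Fz")
  short$signal <- short$signal[, 1:400, drop = FALSE]  # 0.8 s
  expect_error(epoch_recording(short, 1), class = "thetamod_param_error")
})

test_that("trailing partial windows are dropped and onsets retained", {
  rec <- white_recording(5, duration = 11, channels = "Fz")
  rec$signal <- rec$signal[, 1:(10.5 * 500), drop = FALSE]
  ep <- epoch_recording(rec, 1, 0)
  expect_equal(length(ep$onsets), 10)
  expect_equal(ep$onsets, 0:9)
})

test_that("amplitude rejection respects the +/-150 uV boundary", {
  rec <- white_recording(1, duration = 5, channels = "Fz", seed = 2)
  rec$signal[1, 1200] <- 200                 # one sample inside epoch 3
  rec$signal[1, 2100] <- 149.9               # below threshold, epoch 5
  ep <- reject_amplitude(epoch_recording(rec, 1, 0))
  expect_equal(epoch_status(ep),
               c("kept", "kept", "rejected_amplitude", "kept", "kept"))
})

test_that("amplitude rejection matches a brute-force artifact-overlap oracle", {
  cfg <- signal_sim_config(duration = 134, seed = 17, aperiodic_scale = 5,
                           oscillations = list(), artifact_rate = 2,
                           artifact_amplitude = 300,
                           channel_labels = c("F3", "Fz", "F4"))
  rec <- simulate_recording(cfg)
  ep <- reject_amplitude(epoch_recording(rec, 1, 0))
  onsets <- rec$meta$artifact_onsets
  # oracle: an epoch [k, k+1) is hit iff any artifact [o, o+0.2] overlaps it
  hit <- vapply(ep$onsets, function(k)
    any(onsets < k + 1 & onsets + 0.2 > k), TRUE)
  # the artifact peak (amplitude 300) exceeds threshold over most of its
  # support; epochs overlapping only the shallow tail can stay subthreshold,
  # so compare on epochs overlapping the transient's >150 uV core
  core <- vapply(ep$onsets, function(k) {
    any(onsets + 0.061 < k + 1 & onsets + 0.139 > k)  # where transient > 200 uV
  }, TRUE)
  expect_true(all(ep$bad_amp[core]))
  expect_true(all(!ep$bad_amp[!hit]))
})

test_that("gaze rejection marks exactly the overlapping epochs", {
  rec <- white_recording(1, duration = 3, channels = "Fz")
  iv <- data.frame(onset = 1.25, offset = 1.75, label = "look_away")
  ep <- reject_gaze(epoch_recording(rec, 1, 0), iv)
  expect_equal(epoch_status(ep), c("kept", "rejected_gaze", "kept"))
  # no intervals: statuses unchanged
  ep2 <- reject_gaze(epoch_recording(rec, 1, 0),
                     data.frame(onset = numeric(), offset = numeric(),
                                label = character()))
  expect_true(all(epoch_status(ep2) == "kept"))
})

test_that("gaze rejection equals a sample-level mask oracle on random sets", {
  set.seed(12)
  rec <- white_recording(1, duration = 30, channels = "Fz")
  for (rep in 1:10) {
    on <- sort(runif(5, 0, 29))
    iv <- merge_intervals(data.frame(onset = on,
                                     offset = on + runif(5, 0.05, 1.2),
                                     label = "look_away"))
    iv$offset <- pmin(iv$offset, 30)
    ep <- reject_gaze(epoch_recording(rec, 1, 0), iv)
    # oracle: mark each 2-ms sample inside an away interval, reject epochs
    # containing any marked sample
    grid <- seq(0, 30 - 1e-3, by = 1/500)
    away <- rep(FALSE, length(grid))
    for (r in seq_len(nrow(iv)))
      away <- away | (grid >= iv$onset[r] & grid < iv$offset[r])
    oracle <- vapply(0:29, function(k)
      any(away[grid >= k & grid < k + 1]), TRUE)
    expect_equal(ep$bad_gaze, oracle)
  }
})

test_that("rejection operators are idempotent and commute on statuses", {
  rec <- white_recording(60, duration = 20, channels = "Fz", seed = 3)
  rec$signal[1, 3000] <- 400
  iv <- data.frame(onset = c(2.2, 10.4), offset = c(3.1, 12.0),
                   label = "look_away")
  ep <- epoch_recording(rec, 1, 0)
  ab <- reject_gaze(reject_amplitude(ep), iv)
  ba <- reject_amplitude(reject_gaze(ep, iv))
  expect_equal(epoch_status(ab) == "kept", epoch_status(ba) == "kept")
  expect_equal(epoch_status(reject_amplitude(ab)), epoch_status(ab))
  expect_equal(epoch_status(reject_gaze(ab, iv)), epoch_status(ab))
})

test_that("kept non-overlapping epochs reconstruct the recording exactly", {
  rec <- white_recording(10, duration = 8, channels = c("Fz", "Cz"), seed = 6)
  ep <- kept_epochs(epoch_recording(rec, 1, 0))
  recon <- matrix(ep$data, nrow = 2)
  expect_identical(recon, rec$signal)
})

test_that("the inclusion gate applies the 10-clean-segment minimum", {
  rec <- white_recording(5, duration = 12, channels = "Fz", seed = 9)
  ep <- epoch_recording(rec, 1, 0)
  ep$bad_amp[1:3] <- TRUE                  # 9 clean
  expect_false(inclusion_gate(ep)$included)
  ep$bad_amp[3] <- FALSE                   # 10 clean
  g <- inclusion_gate(ep)
  expect_true(g$included)
  expect_equal(g$n_clean, 10)
  # a typical clean recording (cohort mean ~64 segments) is included
  rec2 <- white_recording(5, duration = 64, channels = "Fz", seed = 10)
  expect_true(inclusion_gate(reject_amplitude(epoch_recording(rec2)))$included)
})

test_that("half-overlap windows are cut only within contiguous clean runs", {
  rec <- white_recording(5, duration = 10, channels = "Fz", seed = 13)
  ep <- epoch_recording(rec, 1, 0)
  ep$bad_amp[4] <- TRUE                   # break at second 3: runs 3 + 6
  half <- overlap_epochs_within_runs(rec, ep, 0.5)
  # runs of 3 and 6 clean seconds give (2*3-1) + (2*6-1) = 16 windows
  expect_equal(length(half$onsets), 16)
  # no window may span the rejected second [3, 4)
  expect_true(all(half$onsets + 1 <= 3 + 1e-9 | half$onsets >= 4 - 1e-9))
})
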