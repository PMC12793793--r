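# Shared fixtures: small recordings and independent oracles built in code.

# pure-tone recording on every channel
tone_recording <- function(freq, amplitude, duration = 10, fs = 500,
                           channels = c("F3", "Fz", "F4"), phase = 0) {
  t <- (seq_len(duration * fs) - 1) / fs
  x <- amplitude * sin(2 * pi * freq * t + phase)
  eeg_recording(matrix(rep(x, each = length(channels)),
                       nrow = length(channels)),
                fs, channels)
}

white_recording <- function(sd_uv, duration = 10, fs = 500,
                            channels = c("F3", "Fz", "F4"), seed = 1) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(length(channels) * duration * fs, sd = sd_uv),
                       nrow = length(channels)),
                fs, channels)
}

# tiny ROI config for fixtures that only carry three channels
cfg3 <- function(...) theta_config(roi = c("F3", "Fz", "F4"), ...)

# independent sums-of-squares ICC oracle (balanced two-way, single measure)
icc_anova_oracle <- function(x, y, form = "consistency") {
  m <- cbind(x, y); n <- nrow(m); k <- 2
  grand <- mean(m)
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  sse <- sum((m - outer(rowMeans(m), rep(1, k)) -
                outer(rep(1, n), colMeans(m)) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (form == "consistency") (msr - mse) / (msr + (k - 1) * mse)
  else (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# exhaustive-search AIC oracle over all subsets of candidate predictors
exhaustive_aic_oracle <- function(outcome, candidates, data) {
  d <- data[stats::complete.cases(data[c(outcome, candidates)]),
            c(outcome, candidates)]
  n <- nrow(d)
  best <- NULL; best_aic <- Inf
  for (mask in 0:(2^length(candidates) - 1)) {
    set <- candidates[bitwAnd(mask, 2^(seq_along(candidates) - 1)) > 0]
    fml <- stats::reformulate(if (length(set)) set else "1", outcome)
    rss <- sum(stats::residuals(stats::lm(fml, d))^2)
    aic <- n * log(rss / n) + 2 * (length(set) + 1)
    if (aic < best_aic) { best_aic <- aic; best <- set }
  }
  list(selected = best, aic = best_aic)
}
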