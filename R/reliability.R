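# Reliability and stability: split-half modulation indices, two-way
# single-measure ICC with F-based confidence intervals, one-sample and
# paired t-tests, Pearson stability, and a mixed-model longitudinal ICC.

#' Split-half modulation indices
#'
#' Partitions the kept non-overlapping segments by parity of their position
#' in the retained sequence (1st, 3rd, ... versus 2nd, 4th, ...) and
#' computes a modulation index per half, each segment keeping its own time
#' value. Position parity (not original second number) guarantees
#' near-equal half sizes under arbitrary rejection patterns.
#'
#' @param ep the rejected non-overlapping `epoch_set`.
#' @param band a [band_definition()].
#' @param config a [theta_config()].
#' @return list with `r_odd` and `r_even` (modulation index of the
#'   odd-/even-numbered segments).
#' @export
split_half_modulation <- function(ep, band = band_theta(),
                                  config = theta_config()) {
  series <- band_power_per_segment(ep, band, config$roi,
                                   config$integration, config$band_endpoints)
  n <- length(series$power)
  pos <- seq_len(n)
  halves <- list(odd = pos %% 2 == 1, even = pos %% 2 == 0)
  if (min(vapply(halves, sum, 0L)) < 3)
    stop_thetamod(sprintf(
      "need at least 3 segments per half (got %d kept segments)", n),
      "thetamod_insufficient_data")
  one <- function(sel) {
    sub <- structure(list(onsets = series$onsets[sel],
                          power = series$power[sel]),
                     class = "band_power_series")
    # retained_rank uses the segment's rank in the FULL retained sequence
    if (config$time_basis == "retained_rank") {
      if (stats::sd(sub$power) == 0)
        stop_thetamod("constant power in a half: correlation undefined",
                      "thetamod_undefined_correlation")
      stats::cor(sub$power, pos[sel])
    } else {
      modulation_index(sub, "onset_time")
    }
  }
  list(r_odd = one(halves$odd), r_even = one(halves$even))
}

#' Intraclass correlation for paired measures
#'
#' Two-way single-measure ICC from the classical variance decomposition
#' (Shrout-Fleiss / McGraw-Wong), with a 95% confidence interval from
#' F-distribution bounds. `form = "agreement"` (absolute agreement,
#' ICC(A,1)) is the default; `"consistency"` (ICC(C,1)) is also available.
#' An optional Spearman-Brown step-up projects the single-half ICC to the
#' full-length measure.
#'
#' @param x,y paired per-subject measures (e.g. odd- and even-half
#'   modulation indices); incomplete pairs are dropped.
#' @param form `"agreement"` or `"consistency"`.
#' @param conf confidence level.
#' @param spearman_brown apply the 2-half step-up correction.
#' @return list of class `splithalf_result`: `icc`, `ci95`, `form`,
#'   `n_subjects`, mean squares.
#' @export
icc_pairs <- function(x, y, form = c("agreement", "consistency"),
                      conf = 0.95, spearman_brown = FALSE) {
  form <- match.arg(form)
  ok <- stats::complete.cases(x, y)
  m <- cbind(x[ok], y[ok])
  n <- nrow(m); k <- 2
  if (n < 5)
    stop_thetamod(sprintf("need at least 5 complete pairs (got %d)", n),
                  "thetamod_insufficient_data")
  grand <- mean(m)
  rm_ <- rowMeans(m); cm <- colMeans(m)
  if (stats::var(rm_) < .Machine$double.eps * max(1, grand^2))
    stop_thetamod("zero between-subject variance: ICC undefined",
                  "thetamod_degenerate_variance")
  MSR <- k * sum((rm_ - grand)^2) / (n - 1)
  MSC <- n * sum((cm - grand)^2) / (k - 1)
  SSE <- sum((m - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  alpha <- 1 - conf
  if (MSE <= .Machine$double.eps * MSR) {
    icc <- 1; ci <- c(1, 1)
  } else if (form == "consistency") {
    icc <- (MSR - MSE) / (MSR + (k - 1) * MSE)
    Fobs <- MSR / MSE
    FL <- Fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    FU <- Fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
  } else {
    icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
    Fj <- MSC / MSE
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FU <- stats::qf(1 - alpha / 2, n - 1, v)
    FL <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (MSR - FU * MSE) /
      (FU * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    hi <- n * (FL * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FL * MSR)
    ci <- c(lo, hi)
  }
  project <- function(r) 2 * r / (1 + r)
  if (spearman_brown) { icc <- project(icc); ci <- project(ci) }
  structure(list(icc = icc, ci95 = ci, form = form, n_subjects = n,
                 ms = c(MSR = MSR, MSC = MSC, MSE = MSE),
                 spearman_brown = spearman_brown),
            class = "splithalf_result")
}

#' One-sample t-test with Cohen's d
#'
#' @param x sample values (NAs dropped).
#' @param mu0 null value.
#' @return list: `t`, `df`, `p`, `cohen_d`, `mean`, `sd`, `n`.
#' @export
one_sample_t <- function(x, mu0 = 0) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2)
    stop_thetamod("need at least 2 observations", "thetamod_insufficient_data")
  s <- stats::sd(x)
  if (s == 0)
    stop_thetamod("zero variance: t undefined", "thetamod_degenerate_variance")
  tt <- stats::t.test(x, mu = mu0)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       cohen_d = (mean(x) - mu0) / s, mean = mean(x), sd = s, n = n)
}

#' Paired t-test on complete pairs
#'
#' Tests the mean of `x12 - x6` against zero; pairs with any missing value
#' are dropped. A zero-variance difference with zero mean reports t = 0;
#' with nonzero mean it is a degenerate case and errors.
#'
#' @param x6,x12 paired measures at the two timepoints.
#' @return list: `t`, `df`, `p`, `mean_diff`, `n`.
#' @export
paired_t <- function(x6, x12) {
  ok <- stats::complete.cases(x6, x12)
  d <- x12[ok] - x6[ok]
  n <- length(d)
  if (n < 2)
    stop_thetamod("need at least 2 complete pairs", "thetamod_insufficient_data")
  if (stats::sd(d) < 1e-10 * max(1, abs(mean(d)))) {
    if (mean(d) == 0)
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0, n = n))
    stop_thetamod("constant nonzero difference: t is infinite",
                  "thetamod_degenerate_variance")
  }
  tt <- stats::t.test(d, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = mean(d), n = n)
}

#' Longitudinal stability of an index
#'
#' Pearson correlation (complete pairs, df = n - 2), paired t-test, and a
#' mixed-model ICC over all available observations.
#'
#' @param x6,x12 per-subject values at 6 and 12 months (aligned; NAs allowed).
#' @return list of class `stability_result`: `pearson_r`, `p`, `df`,
#'   `paired_t`, `paired_df`, `paired_p`, `icc_mixed`, `n_pairs`.
#' @export
stability <- function(x6, x12) {
  ok <- stats::complete.cases(x6, x12)
  n <- sum(ok)
  if (n < 5)
    stop_thetamod(sprintf("need at least 5 complete pairs (got %d)", n),
                  "thetamod_insufficient_data")
  if (stats::sd(x6[ok]) == 0 || stats::sd(x12[ok]) == 0)
    stop_thetamod("constant series: correlation undefined",
                  "thetamod_undefined_correlation")
  ct <- stats::cor.test(x6[ok], x12[ok])
  pt <- paired_t(x6, x12)
  long <- data.frame(
    subject = rep(seq_along(x6), 2),
    timepoint = rep(c("6m", "12m"), each = length(x6)),
    value = c(x6, x12))
  long <- long[!is.na(long$value), ]
  icc <- tryCatch(longitudinal_icc(long)$icc, error = function(e) NA_real_)
  structure(list(pearson_r = unname(ct$estimate), p = ct$p.value,
                 df = unname(ct$parameter), paired_t = pt$t,
                 paired_df = pt$df, paired_p = pt$p, icc_mixed = icc,
                 n_pairs = n),
            class = "stability_result")
}

#' Mixed-model intraclass correlation
#'
#' Random-intercept linear mixed model (REML) with timepoint as a fixed
#' effect: `value ~ timepoint + (1 | subject)`. The ICC is
#' `sigma2_subject / (sigma2_subject + sigma2_residual)`; unbalanced
#' missingness is tolerated. A subject variance estimated at the boundary
#' (0) yields ICC 0 with `boundary = TRUE`.
#'
#' @param long data.frame with columns `subject`, `timepoint`, `value`.
#' @return list: `icc`, `sigma2_subject`, `sigma2_residual`, `boundary`,
#'   `n_subjects`, `n_obs`.
#' @export
longitudinal_icc <- function(long) {
  need <- setdiff(c("subject", "timepoint", "value"), names(long))
  if (length(need))
    stop_thetamod(paste0("missing column(s): ", paste(need, collapse = ", ")),
                  "thetamod_validation_error")
  long <- long[!is.na(long$value), ]
  if (length(unique(long$timepoint)) < 2)
    stop_thetamod("need at least 2 timepoints", "thetamod_insufficient_data")
  if (length(unique(long$subject)) < 10)
    stop_thetamod("need at least 10 subjects", "thetamod_insufficient_data")
  fit <- tryCatch(
    lme4::lmer(value ~ timepoint + (1 | subject), data = long, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)),
    error = function(e)
      stop_thetamod(paste0("mixed model failed to converge: ",
                           conditionMessage(e)), "thetamod_estimation_error"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2_subj <- vc$vcov[vc$grp == "subject"]
  s2_res <- vc$vcov[vc$grp == "Residual"]
  boundary <- s2_subj < 1e-8 * (s2_subj + s2_res) || s2_res < 1e-8
  icc <- if (s2_subj + s2_res == 0) 0 else s2_subj / (s2_subj + s2_res)
  list(icc = icc, sigma2_subject = s2_subj, sigma2_residual = s2_res,
       boundary = boundary, n_subjects = length(unique(long$subject)),
       n_obs = nrow(long))
}
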