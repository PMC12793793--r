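# Synthetic longitudinal cohort: per-subject latent traits give each EEG
# index a configurable cross-age correlation; outcomes are driven by the
# composite standardized absolute-power score and age at outcome.

#' Default index population parameters
#'
#' Means and SDs per index x timepoint used by [simulate_cohort()]. Theta
#' rows follow the descriptive statistics of the study cohort (log-domain
#' absolute power around 9 with SD ~1, relative power ~0.5 falling to
#' ~0.46, modulation ~0.20 falling to ~0.13); alpha rows are analogous
#' values with weaker modulation.
#' @return data.frame with columns `index`, `band`, `mean_6m`, `sd_6m`,
#'   `mean_12m`, `sd_12m`.
#' @export
default_index_params <- function() {
  data.frame(
    index = rep(c("absolute_power", "relative_power", "modulation_index"), 2),
    band = rep(c("theta", "alpha"), each = 3),
    mean_6m = c(9.01, 0.50, 0.20, 8.60, 0.30, 0.16),
    sd_6m = c(0.95, 0.06, 0.19, 0.95, 0.05, 0.19),
    mean_12m = c(9.67, 0.46, 0.13, 9.20, 0.28, 0.07),
    sd_12m = c(1.02, 0.05, 0.21, 1.00, 0.05, 0.21),
    stringsAsFactors = FALSE)
}

#' Configuration for the cohort generator
#'
#' @param n_subjects cohort size at enrolment.
#' @param index_params data.frame as [default_index_params()].
#' @param cross_age_correlation latent-trait loading rho: the expected
#'   complete-case Pearson correlation between the 6- and 12-month values
#'   of every index.
#' @param outcome_effect standardized effect of the composite absolute-power
#'   score on the cognitive outcome.
#' @param age_effect standardized effect of age at outcome on the cognitive
#'   and language outcomes.
#' @param missing_rate named list: probability a subject misses the 6-month
#'   EEG, the 12-month EEG, or the outcome visit (independent stages).
#' @param seed RNG seed.
#' @return list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_subjects = 140,
                              index_params = default_index_params(),
                              cross_age_correlation = 0.4,
                              outcome_effect = 0.2, age_effect = 0.2,
                              missing_rate = list(eeg_6m = 0.30,
                                                  eeg_12m = 0.35,
                                                  outcome = 0.17),
                              seed = NULL) {
  if (abs(cross_age_correlation) > 1)
    stop_thetamod("|cross_age_correlation| must be <= 1", "thetamod_config_error")
  if (any(c(index_params$sd_6m, index_params$sd_12m) <= 0))
    stop_thetamod("index SDs must be > 0", "thetamod_config_error")
  for (m in missing_rate)
    if (m < 0 || m >= 1)
      stop_thetamod("missing rates must be in [0, 1)", "thetamod_config_error")
  structure(list(n_subjects = n_subjects, index_params = index_params,
                 cross_age_correlation = cross_age_correlation,
                 outcome_effect = outcome_effect, age_effect = age_effect,
                 missing_rate = missing_rate, seed = seed),
            class = "cohort_sim_config")
}

#' Simulate a two-timepoint longitudinal cohort
#'
#' Each index value is `mu_t + sigma_t * (sqrt(rho) * trait_s +
#' sqrt(1 - rho) * eps_st)`, so the complete-case cross-age correlation of
#' every index equals `rho` in expectation. The cognitive outcome is
#' `beta_comp * composite + beta_age * age_z + noise` on the standardized
#' scale (composite = standardized mean of the subject's within-timepoint
#' absolute-theta z-scores), rescaled to the outcome's population mean and
#' SD. Language subscales load on one age-related factor; selective
#' attention is pure noise. Missingness is applied independently per stage.
#'
#' @param config a [cohort_sim_config()].
#' @return long `cohort_table` with one row per subject x timepoint
#'   (6m, 12m, 24m); EEG indices on the 6m/12m rows, outcomes and
#'   `age_at_outcome` on the 24m row. Attribute `"truth"` carries the
#'   per-cell latent z-scores and the missingness indicators.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  with_seed(config$seed, {
    n <- config$n_subjects
    rho <- config$cross_age_correlation
    ip <- config$index_params
    k <- nrow(ip)
    ids <- sprintf("S%03d", seq_len(n))
    base_seed <- config$seed %||% sample.int(2147483646, 1)

    # one substream per subject, keyed by id: adding subjects to a cohort
    # never perturbs the draws of existing ones
    z6 <- z12 <- matrix(0, n, k)
    age <- e_cog <- e_lang <- numeric(n)
    e_att <- numeric(n)
    e_sub <- matrix(0, n, 3)
    miss6 <- miss12 <- missout <- logical(n)
    for (i in seq_len(n)) {
      with_seed(derive_seed(base_seed, ids[i]), {
        tr <- stats::rnorm(k)
        z6[i, ] <- sqrt(rho) * tr + sqrt(1 - rho) * stats::rnorm(k)
        z12[i, ] <- sqrt(rho) * tr + sqrt(1 - rho) * stats::rnorm(k)
        age[i] <- stats::rnorm(1, 744, 18)
        e_cog[i] <- stats::rnorm(1)
        e_att[i] <- stats::rnorm(1)
        e_lang[i] <- stats::rnorm(1)
        e_sub[i, ] <- stats::rnorm(3)
        miss6[i] <- stats::runif(1) < config$missing_rate$eeg_6m
        miss12[i] <- stats::runif(1) < config$missing_rate$eeg_12m
        missout[i] <- stats::runif(1) < config$missing_rate$outcome
      })
    }
    col6 <- t(ip$mean_6m + t(z6) * ip$sd_6m)
    col12 <- t(ip$mean_12m + t(z12) * ip$sd_12m)
    idx_names <- paste(ip$index, ip$band, sep = "_")

    # outcomes on the standardized scale
    j_abs_theta <- which(ip$index == "absolute_power" & ip$band == "theta")
    comp <- (z6[, j_abs_theta] + z12[, j_abs_theta]) / 2
    comp_std <- comp / sqrt((1 + rho) / 2)
    age_z <- (age - 744) / 18
    b1 <- config$outcome_effect; b2 <- config$age_effect
    resid_sd <- sqrt(max(0, 1 - b1^2 - b2^2))
    cog_z <- b1 * comp_std + b2 * age_z + resid_sd * e_cog
    cognitive_index <- 67 + 5 * cog_z
    selective_attention <- pmax(0, 3.38 + 1.33 * e_att)
    lang_resid <- sqrt(max(0, 1 - b2^2))
    lang_factor <- b2 * age_z + lang_resid * e_lang
    subscale <- function(mean, sd, j, load = 0.7)
      mean + sd * (sqrt(load) * lang_factor + sqrt(1 - load) * e_sub[, j])
    elfra_expressive <- pmax(0, subscale(129, 59, 1))
    elfra_syntax <- pmax(0, subscale(25, 13, 2))
    elfra_morphology <- pmax(0, subscale(6, 4, 3))

    col6[miss6, ] <- NA
    col12[miss12, ] <- NA

    na_out <- function(x) { x[missout] <- NA; x }
    eeg_row <- function(tp, vals) {
      d <- data.frame(subject_id = ids, timepoint = tp,
                      stringsAsFactors = FALSE)
      d[idx_names] <- as.data.frame(vals)
      d[c("cognitive_index", "selective_attention", "elfra_expressive",
          "elfra_syntax", "elfra_morphology", "age_at_outcome")] <- NA_real_
      d
    }
    r6 <- eeg_row("6m", col6)
    r12 <- eeg_row("12m", col12)
    r24 <- eeg_row("24m", matrix(NA_real_, n, nrow(ip)))
    r24$cognitive_index <- na_out(cognitive_index)
    r24$selective_attention <- na_out(selective_attention)
    r24$elfra_expressive <- na_out(elfra_expressive)
    r24$elfra_syntax <- na_out(elfra_syntax)
    r24$elfra_morphology <- na_out(elfra_morphology)
    r24$age_at_outcome <- na_out(age)

    tab <- rbind(r6, r12, r24)
    tab <- tab[order(tab$subject_id, match(tab$timepoint,
                                           c("6m", "12m", "24m"))), ]
    rownames(tab) <- NULL
    out <- as_cohort_table(tab)
    attr(out, "truth") <- list(
      subject_id = ids, z6 = z6, z12 = z12,
      index_names = idx_names, comp_std = comp_std, age = age,
      miss6 = miss6, miss12 = miss12, missout = missout, config = config)
    out
  })
}

#' Pivot a long cohort table to one row per subject
#'
#' EEG index columns are suffixed `_6m` / `_12m`; outcome columns come from
#' the 24m row.
#'
#' @param cohort a long `cohort_table`.
#' @return wide data.frame, one row per subject.
#' @export
cohort_wide <- function(cohort) {
  idx_cols <- grep("^(absolute_power|relative_power|modulation_index)_",
                   names(cohort), value = TRUE)
  out_cols <- intersect(c("cognitive_index", "selective_attention",
                          "elfra_expressive", "elfra_syntax",
                          "elfra_morphology", "language_composite",
                          "age_at_outcome"), names(cohort))
  ids <- unique(cohort$subject_id)
  pick <- function(tp, cols) {
    sub <- cohort[cohort$timepoint == tp, c("subject_id", cols), drop = FALSE]
    sub[match(ids, sub$subject_id), cols, drop = FALSE]
  }
  wide <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (tp in c("6m", "12m")) {
    if (!any(cohort$timepoint == tp)) next
    block <- pick(tp, idx_cols)
    names(block) <- paste0(idx_cols, "_", tp)
    wide <- cbind(wide, block)
  }
  if (any(cohort$timepoint == "24m")) wide <- cbind(wide, pick("24m", out_cols))
  rownames(wide) <- NULL
  wide
}
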