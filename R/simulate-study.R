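#' Simulate a complete study directory
#'
#' Generates one EDF recording and one gaze annotation file per subject x
#' EEG timepoint, an outcome CSV, and a JSON manifest with every true
#' parameter. The per-subject theta and alpha oscillation amplitudes are
#' tied to the subject's latent index z-scores from the cohort generator
#' (`amplitude = base * exp(log_amp_sd * z)`), so a pipeline run on the raw
#' signals can recover cohort-level stability and prediction effects. Each
#' oscillation's envelope ramps by `ramp_frac` of its base amplitude over
#' the recording, producing positive modulation indices. All randomness is
#' derived from `seed` through per-subject substreams keyed by subject id,
#' so adding subjects never perturbs existing ones.
#'
#' @param signal_config template [signal_sim_config()]; its first
#'   oscillation is treated as theta and its second (if present) as alpha.
#' @param cohort_config a [cohort_sim_config()].
#' @param out_dir output directory.
#' @param seed master seed.
#' @param force overwrite a non-empty `out_dir`.
#' @param away_fraction gaze look-away fraction passed to [simulate_gaze()].
#' @param ramp_frac envelope increase over the recording as a fraction of
#'   the subject's base amplitude.
#' @param log_amp_sd between-subject log-spread of the overall EEG gain per
#'   absolute-power latent SD. The gain multiplies the oscillation and the
#'   broadband background alike, as overall scalp-EEG amplitude differences
#'   do, so it moves absolute power without moving relative power.
#' @param log_ratio_sd between-subject log-spread of the
#'   oscillation-to-background amplitude ratio per relative-power latent
#'   SD; the ratio carries relative power and cancels out of the overall
#'   gain, so the two derived indices inherit independent traits.
#' @param mod_slope_sd relative spread of the envelope ramp per modulation
#'   latent SD, giving the modulation index its own between-subject signal.
#' @return invisibly, the manifest list (files, truth, configs).
#' @export
simulate_study <- function(signal_config = signal_sim_config(),
                           cohort_config = cohort_sim_config(),
                           out_dir, seed = 1, force = FALSE,
                           away_fraction = 0.2, ramp_frac = 0.67,
                           log_amp_sd = 0.35, log_ratio_sd = 0.3,
                           mod_slope_sd = 0.4) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force)
    stop_thetamod(sprintf("output directory '%s' is not empty (use force = TRUE)",
                          out_dir), "thetamod_io_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort_config$seed <- derive_seed(seed, "cohort")
  cohort <- simulate_cohort(cohort_config)
  truth <- attr(cohort, "truth")
  ip <- cohort_config$index_params
  j_of <- function(index, b) which(ip$index == index & ip$band == b)

  files <- list()
  rec_truth <- list()
  for (i in seq_along(truth$subject_id)) {
    sid <- truth$subject_id[i]
    for (tp in c("6m", "12m")) {
      missing_eeg <- if (tp == "6m") truth$miss6[i] else truth$miss12[i]
      if (missing_eeg) next
      zmat <- if (tp == "6m") truth$z6 else truth$z12
      cfg <- signal_config
      cfg$seed <- derive_seed(seed, paste(sid, tp, "eeg"))
      z_at <- function(index, b) {
        j <- j_of(index, b)
        if (length(j)) zmat[i, j] else 0
      }
      # overall gain G (absolute-power trait of the primary band) scales
      # oscillations and background alike; the oscillation-to-background
      # ratio R (relative-power trait) cancels out of G, so absolute and
      # relative power vary along independent latent axes
      G <- exp(log_amp_sd * z_at("absolute_power", "theta"))
      R <- exp(log_ratio_sd * z_at("relative_power", "theta"))
      cfg$aperiodic_scale <- signal_config$aperiodic_scale * G / sqrt(R)
      for (k in seq_along(cfg$oscillations)) {
        band <- if (k == 1) "theta" else "alpha"
        gain <- if (band == "theta") G * sqrt(R) else
          exp(log_amp_sd * z_at("absolute_power", band))
        base <- cfg$oscillations[[k]]$base_amplitude * gain
        ramp <- ramp_frac *
          max(-0.95, 1 + mod_slope_sd * z_at("modulation_index", band))
        cfg$oscillations[[k]]$base_amplitude <- base
        cfg$oscillations[[k]]$amplitude_slope <- ramp * base / cfg$duration
      }
      rec <- simulate_recording(cfg)
      rec$meta$subject_id <- sid
      rec$meta$timepoint <- tp
      stem <- file.path(out_dir, sprintf("%s_%s", sid, tp))
      write_edf(rec, paste0(stem, ".edf"))
      gaze <- simulate_gaze(cfg$duration, away_fraction,
                            seed = derive_seed(seed, paste(sid, tp, "gaze")))
      write_intervals(gaze, paste0(stem, "_gaze.tsv"))
      files[[length(files) + 1]] <- list(
        subject_id = sid, timepoint = tp,
        recording = basename(paste0(stem, ".edf")),
        gaze = basename(paste0(stem, "_gaze.tsv")))
      rec_truth[[length(rec_truth) + 1]] <- list(
        subject_id = sid, timepoint = tp,
        theta_amplitude = cfg$oscillations[[1]]$base_amplitude,
        theta_slope = cfg$oscillations[[1]]$amplitude_slope)
    }
  }
  outcome_path <- file.path(out_dir, "outcomes.csv")
  write_cohort(cohort, outcome_path)

  files <- do.call(rbind, lapply(files, function(f)
    as.data.frame(f, stringsAsFactors = FALSE)))
  manifest <- list(
    seed = seed,
    away_fraction = away_fraction, ramp_frac = ramp_frac,
    log_amp_sd = log_amp_sd, log_ratio_sd = log_ratio_sd,
    mod_slope_sd = mod_slope_sd,
    signal_config = unclass(signal_config),
    cohort_config = unclass(cohort_config)[
      c("n_subjects", "cross_age_correlation", "outcome_effect",
        "age_effect", "missing_rate")],
    outcomes = basename(outcome_path),
    recordings = files,
    recording_truth = rec_truth,
    latent_z = list(subject_id = truth$subject_id,
                    index = truth$index_names,
                    z6 = truth$z6, z12 = truth$z12))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
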