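# End-to-end orchestration over a study directory: index every recording,
# assemble the cohort table, and run the reliability, stability and
# prediction stages.

#' Compute EEG indices for every recording in a study directory
#'
#' Reads the manifest written by [simulate_study()] (or a hand-written one
#' with the same `recordings` layout), runs [compute_index_set()] per
#' recording and band, and merges the results into the outcome table,
#' replacing any index columns present there. Subjects failing the
#' inclusion gate keep missing indices.
#'
#' @param dir study directory containing `manifest.json` and the files it
#'   lists.
#' @param bands list of [band_definition()]s to index.
#' @param config a [theta_config()].
#' @return long `cohort_table` with EEG-derived index columns; attribute
#'   `"epoch_sets"` holds the rejected non-overlapping `epoch_set` per
#'   recording (for split-half reliability).
#' @export
index_study <- function(dir, bands = list(band_theta(), band_alpha()),
                        config = theta_config()) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path))
    stop_thetamod(sprintf("no manifest.json in '%s'", dir), "thetamod_io_error")
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  outcomes <- read_cohort(file.path(dir, man$outcomes))
  idx_cols <- grep("^(absolute_power|relative_power|modulation_index)_",
                   names(outcomes), value = TRUE)
  outcomes[idx_cols] <- NULL
  recs <- man$recordings
  rows <- vector("list", nrow(recs))
  epoch_sets <- list()
  for (i in seq_len(nrow(recs))) {
    rec <- read_recording(file.path(dir, recs$recording[i]))
    gaze <- read_intervals(file.path(dir, recs$gaze[i]))
    row <- list(subject_id = recs$subject_id[i], timepoint = recs$timepoint[i])
    filt <- bandpass_filter(rec, config$filter_low, config$filter_high,
                            config$transition_low, config$transition_high)
    ep0 <- reject_amplitude(epoch_recording(filt, config$epoch_length, 0),
                            config$amplitude_threshold)
    if (nrow(gaze)) ep0 <- reject_gaze(ep0, gaze, config$gaze_min_overlap)
    gate <- inclusion_gate(ep0, config$min_segments)
    row$n_clean_segments <- gate$n_clean
    row$included <- gate$included
    if (gate$included) {
      ep_half <- overlap_epochs_within_runs(filt, ep0, config$power_overlap)
      psd <- compute_psd(ep_half)
      for (band in bands) {
        row[[paste0("absolute_power_", band$name)]] <-
          absolute_band_power(psd, band, config$roi, config$log_base,
                              config$integration, config$band_endpoints)
        row[[paste0("relative_power_", band$name)]] <-
          relative_band_power(psd, band, config$total_band, config$roi,
                              config$integration, config$band_endpoints)
        series <- band_power_per_segment(ep0, band, config$roi,
                                         config$integration,
                                         config$band_endpoints)
        row[[paste0("modulation_index_", band$name)]] <-
          modulation_index(series, config$time_basis)
      }
    } else {
      for (band in bands)
        row[paste0(c("absolute_power_", "relative_power_",
                     "modulation_index_"), band$name)] <- NA_real_
    }
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
    epoch_sets[[paste(recs$subject_id[i], recs$timepoint[i], sep = "_")]] <- ep0
  }
  idx_tab <- do.call(rbind, rows)
  merged <- merge(outcomes, idx_tab, by = c("subject_id", "timepoint"),
                  all.x = TRUE, sort = FALSE)
  merged <- merged[order(merged$subject_id,
                         match(merged$timepoint, c("6m", "12m", "24m"))), ]
  rownames(merged) <- NULL
  out <- as_cohort_table(merged)
  attr(out, "epoch_sets") <- epoch_sets
  out
}

#' Stability statistics for every index at two timepoints
#'
#' @param cohort long `cohort_table` with index columns.
#' @param band band name.
#' @return data.frame: one row per index with Pearson r, df, p, paired t,
#'   mixed-model ICC and pair count.
#' @export
stability_suite <- function(cohort, band = "theta") {
  wide <- cohort_wide(cohort)
  idx <- paste0(c("absolute_power_", "relative_power_", "modulation_index_"),
                band)
  out <- lapply(idx, function(col) {
    st <- stability(wide[[paste0(col, "_6m")]], wide[[paste0(col, "_12m")]])
    data.frame(index = col, pearson_r = st$pearson_r, df = st$df, p = st$p,
               paired_t = st$paired_t, paired_p = st$paired_p,
               icc_mixed = st$icc_mixed, n_pairs = st$n_pairs,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Split-half reliability of the modulation index across a study
#'
#' Computes odd-/even-half modulation indices per recording at one
#' timepoint and the ICC between the halves.
#'
#' @param epoch_sets named list of rejected non-overlapping `epoch_set`s
#'   (as attached by [index_study()]), names `subject_timepoint`.
#' @param timepoint which timepoint's recordings to use.
#' @param band a [band_definition()].
#' @param config a [theta_config()].
#' @return list: `halves` data.frame (subject, r_odd, r_even), `icc` the
#'   [icc_pairs()] result.
#' @export
splithalf_suite <- function(epoch_sets, timepoint = "6m",
                            band = band_theta(), config = theta_config()) {
  sel <- grep(paste0("_", timepoint, "$"), names(epoch_sets), value = TRUE)
  halves <- lapply(sel, function(nm) {
    h <- tryCatch(split_half_modulation(epoch_sets[[nm]], band, config),
                  thetamod_error = function(e) NULL)
    if (is.null(h)) return(NULL)
    data.frame(subject = sub(paste0("_", timepoint, "$"), "", nm),
               r_odd = h$r_odd, r_even = h$r_even, stringsAsFactors = FALSE)
  })
  halves <- do.call(rbind, halves)
  icc <- icc_pairs(halves$r_odd, halves$r_even, form = config$icc_form,
                   spearman_brown = config$spearman_brown)
  list(halves = halves, icc = icc)
}
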