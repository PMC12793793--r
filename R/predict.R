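# Outcome prediction: composite standardized scores, OLS with
# standardized coefficients, stepwise AIC model selection with an explicit
# trace, and variance inflation factors.

#' Composite standardized EEG scores
#'
#' For each index, values are z-scored within timepoint (over the subjects
#' with valid data at that timepoint) and averaged over the subject's
#' available timepoints; a subject with data at only one timepoint keeps
#' that timepoint's z-score. Subjects with no valid EEG at either
#' timepoint get a missing composite.
#'
#' @param cohort long `cohort_table` with EEG index columns on the 6m/12m
#'   rows.
#' @param index_cols index column names (default: all index columns found).
#' @return data.frame: `subject_id`, one `composite_<index>` column per
#'   index, `n_timepoints_contributing`.
#' @export
composite_scores <- function(cohort, index_cols = NULL) {
  if (is.null(index_cols))
    index_cols <- grep("^(absolute_power|relative_power|modulation_index)_",
                       names(cohort), value = TRUE)
  ids <- unique(cohort$subject_id)
  z_at <- function(tp, col) {
    sub <- cohort[cohort$timepoint == tp, ]
    v <- sub[[col]][match(ids, sub$subject_id)]
    ok <- !is.na(v)
    if (sum(ok) < 2)
      stop_thetamod(sprintf("fewer than 2 valid values for %s at %s", col, tp),
                    "thetamod_insufficient_data")
    s <- stats::sd(v[ok])
    if (s == 0)
      stop_thetamod(sprintf("zero SD for %s at %s: z-scores undefined", col, tp),
                    "thetamod_degenerate_variance")
    (v - mean(v[ok])) / s
  }
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  contributing <- NULL
  for (col in index_cols) {
    z <- cbind(z_at("6m", col), z_at("12m", col))
    out[[paste0("composite_", col)]] <- rowMeans(z, na.rm = TRUE)
    out[[paste0("composite_", col)]][rowSums(!is.na(z)) == 0] <- NA
    if (is.null(contributing)) contributing <- rowSums(!is.na(z))
  }
  out$n_timepoints_contributing <- contributing
  out
}

#' Language composite score
#'
#' Mean of the within-sample z-scored questionnaire subscales (expressive
#' vocabulary, syntax, morphology); a subject missing a subscale gets the
#' mean of the available z-scores.
#'
#' @param elfra data.frame of per-subject subscale scores.
#' @param cols subscale column names.
#' @return numeric vector, NA where all subscales are missing.
#' @export
language_composite <- function(elfra,
                               cols = c("elfra_expressive", "elfra_syntax",
                                        "elfra_morphology")) {
  z <- sapply(cols, function(col) {
    v <- elfra[[col]]
    ok <- !is.na(v)
    if (sum(ok) < 2)
      stop_thetamod(sprintf("fewer than 2 valid values for %s", col),
                    "thetamod_insufficient_data")
    s <- stats::sd(v[ok])
    if (s == 0)
      stop_thetamod(sprintf("zero SD for %s", col),
                    "thetamod_degenerate_variance")
    (v - mean(v[ok])) / s
  })
  out <- rowMeans(z, na.rm = TRUE)
  out[rowSums(!is.na(z)) == 0] <- NA
  unname(out)
}

#' Ordinary least squares with standardized coefficients
#'
#' Fits the raw-scale model for the F statistic and R-squared, and a
#' z-scored model for standardized betas with t-based 95% confidence
#' intervals. Listwise deletion on the named columns.
#'
#' @param outcome outcome column name.
#' @param predictors character vector of predictor column names (may be
#'   empty for an intercept-only model).
#' @param data data.frame.
#' @param conf confidence level for the coefficient intervals.
#' @return list of class `linear_fit`: `coefficients` data.frame
#'   (predictor, beta_std, ci_low, ci_high, t, p), `r_squared`,
#'   `adj_r_squared`, `f_statistic`, `f_df`, `f_p`, `vif`, `n`, `model`.
#' @export
fit_linear <- function(outcome, predictors, data, conf = 0.95) {
  if (!outcome %in% names(data))
    stop_thetamod(sprintf("outcome column '%s' not found", outcome),
                  "thetamod_config_error")
  missing_pred <- setdiff(predictors, names(data))
  if (length(missing_pred))
    stop_thetamod(paste0("predictor column(s) not found: ",
                         paste(missing_pred, collapse = ", ")),
                  "thetamod_config_error")
  cols <- c(outcome, predictors)
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  n <- nrow(d); k <- length(predictors)
  if (n <= k + 1)
    stop_thetamod(sprintf("n (%d) must exceed predictors + 1 (%d)", n, k + 1),
                  "thetamod_insufficient_data")
  fml <- stats::reformulate(if (k) predictors else "1", response = outcome)
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit))))
    stop_thetamod(paste0("rank-deficient design; aliased column(s): ",
                         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                               collapse = ", ")),
                  "thetamod_collinearity_error")
  sm <- summary(fit)
  coefs <- NULL
  if (k) {
    dz <- as.data.frame(lapply(d, function(x) as.numeric(scale(x))))
    fitz <- stats::lm(fml, data = dz)
    smz <- summary(fitz)
    est <- smz$coefficients[predictors, , drop = FALSE]
    tcrit <- stats::qt(1 - (1 - conf) / 2, df = n - k - 1)
    coefs <- data.frame(
      predictor = predictors,
      beta_std = est[, 1],
      ci_low = est[, 1] - tcrit * est[, 2],
      ci_high = est[, 1] + tcrit * est[, 2],
      t = est[, 3], p = est[, 4],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  fstat <- if (k) unname(sm$fstatistic) else c(NA, NA, NA)
  list_vif <- if (k >= 2) vif(predictors, d) else
    stats::setNames(rep(NA_real_, k), predictors)
  structure(list(
    coefficients = coefs,
    r_squared = if (k) sm$r.squared else 0,
    adj_r_squared = if (k) sm$adj.r.squared else 0,
    f_statistic = fstat[1], f_df = fstat[2:3],
    f_p = if (k) stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
          else NA_real_,
    vif = list_vif, n = n, model = fit),
    class = "linear_fit")
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing predictor j on the others.
#' Perfect collinearity is flagged with an infinite VIF (and a warning)
#' rather than an error.
#'
#' @param predictors predictor column names (at least 2).
#' @param data data.frame (complete cases on `predictors` are used).
#' @return named numeric vector of VIFs (all >= 1).
#' @export
vif <- function(predictors, data) {
  if (length(predictors) < 2)
    stop_thetamod("VIF needs at least 2 predictors", "thetamod_param_error")
  d <- data[stats::complete.cases(data[predictors]), predictors, drop = FALSE]
  if (nrow(d) <= length(predictors) + 1)
    stop_thetamod("not enough rows for VIF", "thetamod_insufficient_data")
  out <- vapply(predictors, function(p) {
    r2 <- summary(stats::lm(stats::reformulate(setdiff(predictors, p),
                                               response = p), data = d))$r.squared
    if (r2 >= 1 - 1e-12) {
      warning(sprintf("predictor '%s' is perfectly collinear; VIF infinite", p))
      Inf
    } else 1 / (1 - r2)
  }, 0)
  out
}

aic_rss <- function(outcome, predictors, data) {
  fml <- stats::reformulate(if (length(predictors)) predictors else "1",
                            response = outcome)
  fit <- stats::lm(fml, data = data)
  rss <- sum(stats::residuals(fit)^2)
  n <- nrow(data)
  n * log(rss / n) + 2 * (length(predictors) + 1)
}

#' Stepwise AIC model selection
#'
#' Starts from the full model and, at each step, evaluates every
#' single-predictor deletion and addition, taking the move with the lowest
#' AIC (`n * ln(RSS/n) + 2 * (k + 1)`, constants omitted); the search stops
#' when no move lowers the AIC. The intercept is always retained. On an
#' exact tie a deletion is preferred over an addition (parsimony) and,
#' among tied deletions, the predictor with the largest p-value is
#' dropped. Listwise deletion is fixed at the full candidate set before
#' the search so every visited model uses the same n.
#'
#' @param outcome outcome column name.
#' @param candidates candidate predictor column names.
#' @param data data.frame.
#' @param direction currently `"both"` (the study's setting).
#' @return list of class `model_selection_result`: `selected` predictor
#'   set, `aic_trace` data.frame (step, action, predictor, aic), `fit`
#'   ([fit_linear()] of the selected model), `n`.
#' @export
stepwise_aic <- function(outcome, candidates, data, direction = "both") {
  if (!outcome %in% names(data))
    stop_thetamod(sprintf("outcome column '%s' not found", outcome),
                  "thetamod_config_error")
  cols <- c(outcome, candidates)
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  n <- nrow(d)
  if (n <= length(candidates) + 1)
    stop_thetamod("n must exceed the full-model parameter count",
                  "thetamod_insufficient_data")
  current <- candidates
  cur_aic <- aic_rss(outcome, current, d)
  trace <- data.frame(step = 0L, action = "start",
                      predictor = NA_character_, aic = cur_aic,
                      stringsAsFactors = FALSE)
  step_i <- 0L
  repeat {
    moves <- list()
    for (p in current)
      moves[[length(moves) + 1]] <- list(action = "drop", predictor = p,
                                         set = setdiff(current, p))
    for (p in setdiff(candidates, current))
      moves[[length(moves) + 1]] <- list(action = "add", predictor = p,
                                         set = c(current, p))
    if (!length(moves)) break
    aics <- vapply(moves, function(m) aic_rss(outcome, m$set, d), 0)
    best <- min(aics)
    if (best >= cur_aic - 1e-10) break
    cand <- which(abs(aics - best) < 1e-10)
    if (length(cand) > 1) {
      drops <- cand[vapply(moves[cand], function(m) m$action == "drop", TRUE)]
      if (length(drops)) {
        if (length(drops) > 1) {
          sm <- summary(stats::lm(stats::reformulate(current, outcome), d))
          pvals <- vapply(moves[drops],
                          function(m) sm$coefficients[m$predictor, 4], 0)
          drops <- drops[which.max(pvals)]
        }
        cand <- drops[1]
      } else cand <- cand[1]
    }
    chosen <- moves[[cand[1]]]
    current <- chosen$set
    cur_aic <- aics[cand[1]]
    step_i <- step_i + 1L
    trace <- rbind(trace, data.frame(step = step_i, action = chosen$action,
                                     predictor = chosen$predictor,
                                     aic = cur_aic, stringsAsFactors = FALSE))
  }
  fit <- fit_linear(outcome, current, d)
  structure(list(selected = current, aic_trace = trace, fit = fit,
                 aic = cur_aic, n = n, outcome = outcome,
                 candidates = candidates),
            class = "model_selection_result")
}

#' @export
print.model_selection_result <- function(x, ...) {
  cat(sprintf("<model_selection> %s ~ %s\n", x$outcome,
              if (length(x$selected)) paste(x$selected, collapse = " + ")
              else "1 (intercept only)"))
  cat(sprintf("  AIC %.2f after %d move(s), n = %d\n", x$aic,
              max(x$aic_trace$step), x$n))
  if (!is.null(x$fit$coefficients)) {
    cf <- x$fit$coefficients
    for (i in seq_len(nrow(cf)))
      cat(sprintf("  %-36s beta = %6.3f  95%% CI [%.3f, %.3f]  t = %.3f  p = %.4f\n",
                  cf$predictor[i], cf$beta_std[i], cf$ci_low[i], cf$ci_high[i],
                  cf$t[i], cf$p[i]))
    cat(sprintf("  F(%d, %d) = %.3f, p = %.4f, R2 = %.3f (adj %.3f)\n",
                x$fit$f_df[1], x$fit$f_df[2], x$fit$f_statistic, x$fit$f_p,
                x$fit$r_squared, x$fit$adj_r_squared))
  }
  invisible(x)
}

#' Run the outcome-prediction suite
#'
#' Builds the per-subject analysis table (EEG composites or separate
#' 6-/12-month predictors, the language composite, age at outcome) and
#' runs one stepwise AIC selection per outcome, mirroring the full-model
#' specification: age at outcome plus the three band indices.
#'
#' @param cohort long `cohort_table` including outcome rows.
#' @param band `"theta"` or `"alpha"`.
#' @param outcomes outcome column names; `"language_composite"` is computed
#'   from the questionnaire subscales.
#' @param covariates always-candidate covariate columns.
#' @param use_composites if `FALSE`, use separate 6- and 12-month
#'   predictors (complete-case across both timepoints).
#' @return named list of [stepwise_aic()] results, one per outcome, with
#'   the assembled analysis table in attribute `"data"`.
#' @export
run_prediction_suite <- function(cohort, band = "theta",
                                 outcomes = c("cognitive_index",
                                              "selective_attention",
                                              "language_composite"),
                                 covariates = "age_at_outcome",
                                 use_composites = TRUE) {
  idx_cols <- paste0(c("absolute_power_", "relative_power_",
                       "modulation_index_"), band)
  missing_idx <- setdiff(idx_cols, names(cohort))
  if (length(missing_idx))
    stop_thetamod(paste0("cohort lacks index column(s): ",
                         paste(missing_idx, collapse = ", ")),
                  "thetamod_config_error")
  wide <- cohort_wide(cohort)
  if (all(c("elfra_expressive", "elfra_syntax", "elfra_morphology")
          %in% names(wide)))
    wide$language_composite <- language_composite(wide)
  if (use_composites) {
    comp <- composite_scores(cohort, idx_cols)
    wide <- merge(wide, comp, by = "subject_id", sort = FALSE)
    predictors <- paste0("composite_", idx_cols)
  } else {
    predictors <- c(paste0(idx_cols, "_6m"), paste0(idx_cols, "_12m"))
  }
  res <- list()
  for (oc in outcomes) {
    if (!oc %in% names(wide))
      stop_thetamod(sprintf("outcome column '%s' not found in cohort", oc),
                    "thetamod_config_error")
    res[[oc]] <- stepwise_aic(oc, c(covariates, predictors), wide)
  }
  attr(res, "data") <- wide
  res
}
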