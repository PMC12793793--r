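#!/usr/bin/env Rscript
# Stage 5: do first-year EEG indices predict 24-month outcomes? Composite
# standardized scores (mean of within-timepoint z-scores), stepwise AIC
# selection from the full model {age at outcome, composite absolute power,
# composite relative power, composite modulation}, VIF collinearity check,
# standardized coefficients with 95% CIs.

library(thetamod)

cohort <- read_cohort("results/02_cohort_indices.csv")

res <- run_prediction_suite(cohort)       # theta band, three outcomes
reports <- list()
for (oc in names(res)) {
  cat("\n")
  print(res[[oc]])
  sel <- res[[oc]]
  reports[[oc]] <- list(
    selected = sel$selected,
    aic_trace = sel$aic_trace,
    n = sel$n,
    r_squared = sel$fit$r_squared,
    adj_r_squared = sel$fit$adj_r_squared,
    coefficients = sel$fit$coefficients,
    vif = as.list(sel$fit$vif))
}

# collinearity of the full candidate set, mirroring the VIF check
d <- attr(res, "data")
full_vif <- vif(c("age_at_outcome", "composite_absolute_power_theta",
                  "composite_relative_power_theta",
                  "composite_modulation_index_theta"), d)
cat("\nfull-model VIFs:\n"); print(round(full_vif, 3))

jsonlite::write_json(reports, "results/05_prediction_models.json",
                     auto_unbox = TRUE, digits = NA, force = TRUE,
                     dataframe = "rows")
cat("model reports -> results/05_prediction_models.json\n")
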