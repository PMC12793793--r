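make_cohort <- function(v6, v12, col = "absolute_power_theta") {
  n <- length(v6)
  ids <- sprintf("S%03d", seq_len(n))
  tab <- data.frame(subject_id = rep(ids, 2),
                    timepoint = rep(c("6m", "12m"), each = n),
                    stringsAsFactors = FALSE)
  tab[[col]] <- c(v6, v12)
  as_cohort_table(tab)
}

test_that("composites follow the z-score-then-average rule", {
  v6 <- c(10, 12, 14, NA, 10)
  v12 <- c(20, 22, NA, 24, 20)
  co <- make_cohort(v6, v12)
  cs <- composite_scores(co, "absolute_power_theta")
  z6 <- (v6 - mean(v6, na.rm = TRUE)) / sd(v6, na.rm = TRUE)
  z12 <- (v12 - mean(v12, na.rm = TRUE)) / sd(v12, na.rm = TRUE)
  expect_equal(cs$composite_absolute_power_theta,
               rowMeans(cbind(z6, z12), na.rm = TRUE))
  # subject with a single timepoint keeps that timepoint's z-score
  expect_equal(cs$composite_absolute_power_theta[3], z6[3])
  expect_equal(cs$n_timepoints_contributing, c(2, 2, 1, 1, 2))
})

test_that("subjects at the timepoint means get composite zero", {
  v6 <- c(1, 2, 3); v12 <- c(4, 6, 8)
  cs <- composite_scores(make_cohort(v6, v12), "absolute_power_theta")
  expect_equal(cs$composite_absolute_power_theta[2], 0)
})

test_that("a 6m-only subject keeps their single-timepoint z-score", {
  v6 <- c(10, 12, 14, 15)
  v12 <- c(1, 2, 3, NA)                    # subject 4 has no 12-m EEG
  cs <- composite_scores(make_cohort(v6, v12), "absolute_power_theta")
  expect_equal(cs$composite_absolute_power_theta[4],
               (15 - mean(v6)) / sd(v6))
})

test_that("composite tracks the generating trait more tightly as rho grows", {
  set.seed(71)
  track <- sapply(c(0.1, 0.5, 0.9), function(rho) {
    mean(replicate(20, {
      cc <- cohort_sim_config(n_subjects = 150, cross_age_correlation = rho,
                              missing_rate = list(eeg_6m = 0, eeg_12m = 0,
                                                  outcome = 0))
      co <- simulate_cohort(cc)
      tru <- attr(co, "truth")
      cs <- composite_scores(co, "absolute_power_theta")
      j <- which(tru$index_names == "absolute_power_theta")
      trait_proxy <- tru$z6[, j] + tru$z12[, j]
      cor(cs$composite_absolute_power_theta, trait_proxy)
    }))
  })
  expect_true(all(diff(track) > 0) || track[3] > track[1])
})

test_that("language composite averages the available subscale z-scores", {
  d <- data.frame(elfra_expressive = c(100, 150, 200),
                  elfra_syntax = c(10, 20, 30),
                  elfra_morphology = c(2, NA, 10))
  lc <- language_composite(d)
  z1 <- scale(d$elfra_expressive)[, 1]
  z2 <- scale(d$elfra_syntax)[, 1]
  z3 <- (d$elfra_morphology - 6) / sd(d$elfra_morphology, na.rm = TRUE)
  expect_equal(lc[2], mean(c(z1[2], z2[2])))
  expect_equal(lc[1], mean(c(z1[1], z2[1], z3[1])))
  # all three at the sample means give zero
  d2 <- data.frame(elfra_expressive = c(1, 2, 3), elfra_syntax = c(4, 5, 6),
                   elfra_morphology = c(7, 8, 9))
  expect_equal(language_composite(d2)[2], 0)
})

test_that("language composite variance matches the averaging closed form", {
  set.seed(72)
  rho <- 0.5
  vars <- replicate(100, {
    f <- rnorm(400)
    d <- data.frame(elfra_expressive = sqrt(rho) * f + sqrt(1 - rho) * rnorm(400),
                    elfra_syntax = sqrt(rho) * f + sqrt(1 - rho) * rnorm(400),
                    elfra_morphology = sqrt(rho) * f + sqrt(1 - rho) * rnorm(400))
    var(language_composite(d))
  })
  expect_equal(mean(vars), (1 + 2 * rho) / 3, tolerance = 0.03)
})

test_that("fit_linear reproduces hand-computed normal equations", {
  # textbook five-point data
  d <- data.frame(x = c(1, 2, 3, 4, 5), y = c(2, 4, 5, 4, 5))
  fit <- fit_linear("y", "x", d)
  # hand computation: slope = Sxy/Sxx = 6/10, intercept = 4 - 0.6*3
  expect_equal(unname(coef(fit$model)), c(2.2, 0.6), tolerance = 1e-12)
  expect_equal(fit$r_squared, 0.6^2 * 10 / 6, tolerance = 1e-12)
  # perfect linear relation: standardized beta 1, R^2 1
  d2 <- data.frame(x = rnorm(30)); d2$y <- d2$x
  fit2 <- suppressWarnings(fit_linear("y", "x", d2))
  expect_equal(fit2$coefficients$beta_std, 1, tolerance = 1e-9)
  expect_equal(fit2$r_squared, 1)
})

test_that("standardized betas are invariant to affine rescaling", {
  set.seed(73)
  d <- data.frame(x1 = rnorm(80), x2 = rnorm(80))
  d$y <- 0.5 * d$x1 - 0.3 * d$x2 + rnorm(80)
  f1 <- fit_linear("y", c("x1", "x2"), d)
  d2 <- data.frame(x1 = 100 * d$x1 - 7, x2 = 0.01 * d$x2 + 3,
                   y = 5 * d$y + 100)
  f2 <- fit_linear("y", c("x1", "x2"), d2)
  expect_equal(f1$coefficients$beta_std, f2$coefficients$beta_std,
               tolerance = 1e-9)
  expect_equal(f1$coefficients$ci_low, f2$coefficients$ci_low,
               tolerance = 1e-9)
})

test_that("null predictors have a calibrated type-I error rate", {
  set.seed(74)
  ps <- replicate(1000, {
    d <- data.frame(x = rnorm(100), y = rnorm(100))
    fit_linear("y", "x", d)$coefficients$p
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.015)
})

test_that("rank-deficient designs raise a collinearity error", {
  d <- data.frame(x1 = 1:20, y = rnorm(20))
  d$x2 <- d$x1 * 2
  expect_error(fit_linear("y", c("x1", "x2"), d),
               class = "thetamod_collinearity_error")
})

test_that("VIF matches the closed form for correlated predictors", {
  set.seed(75)
  # orthogonal predictors: VIF exactly 1
  x1 <- rep(c(-1, 1), 50); x2 <- rep(c(-1, -1, 1, 1), 25)
  expect_equal(unname(vif(c("x1", "x2"), data.frame(x1 = x1, x2 = x2))),
               c(1, 1), tolerance = 1e-12)
  # correlation r gives 1/(1-r^2): construct exact sample correlation 0.6
  n <- 200
  a <- as.numeric(scale(rnorm(n)))
  b <- as.numeric(scale(residuals(lm(rnorm(n) ~ a))))
  x <- a; y <- 0.6 * a + sqrt(1 - 0.36) * b
  got <- vif(c("x", "y"), data.frame(x = x, y = y))
  expect_equal(unname(got), rep(1 / (1 - 0.36), 2), tolerance = 1e-6)
  # near-duplicated predictor explodes
  d <- data.frame(x1 = rnorm(50))
  d$x2 <- d$x1 + rnorm(50, sd = 1e-4)
  expect_gt(max(vif(c("x1", "x2"), d)), 10)
})

test_that("stepwise AIC matches the stepAIC convention and selection", {
  skip_if_not_installed("MASS")
  set.seed(76)
  d <- data.frame(x1 = rnorm(60), x2 = rnorm(60), x3 = rnorm(60))
  d$y <- 0.8 * d$x1 + rnorm(60)
  got <- stepwise_aic("y", c("x1", "x2", "x3"), d)
  ref <- MASS::stepAIC(lm(y ~ x1 + x2 + x3, d), direction = "both",
                       trace = 0)
  expect_setequal(got$selected, setdiff(names(coef(ref)), "(Intercept)"))
  # identical AIC value convention (extractAIC scale)
  expect_equal(got$aic, extractAIC(ref)[2], tolerance = 1e-9)
})

test_that("stepwise equals exhaustive search on random small problems", {
  set.seed(77)
  agree <- replicate(40, {
    d <- data.frame(matrix(rnorm(60 * 4), 60, 4))
    names(d) <- paste0("x", 1:4)
    d$y <- 0.4 * d$x2 + rnorm(60)
    got <- stepwise_aic("y", paste0("x", 1:4), d)
    oracle <- exhaustive_aic_oracle("y", paste0("x", 1:4), d)
    isTRUE(all.equal(got$aic, oracle$aic, tolerance = 1e-9))
  })
  expect_gte(mean(agree), 0.99)
})

test_that("a full model already optimal produces a zero-move trace", {
  set.seed(78)
  d <- data.frame(x1 = rnorm(100), x2 = rnorm(100))
  d$y <- d$x1 + d$x2 + rnorm(100, sd = 0.1)
  got <- stepwise_aic("y", c("x1", "x2"), d)
  expect_setequal(got$selected, c("x1", "x2"))
  expect_equal(max(got$aic_trace$step), 0)
  # AIC strictly decreases along any non-trivial trace
  d$y <- rnorm(100)
  got2 <- stepwise_aic("y", c("x1", "x2"), d)
  expect_true(all(diff(got2$aic_trace$aic) < 0))
  expect_lte(got2$aic, got2$aic_trace$aic[1])
})

test_that("the prediction suite recovers a composite-power-only effect", {
  set.seed(79)
  hits <- replicate(20, {
    cc <- cohort_sim_config(n_subjects = 120, outcome_effect = 0.45,
                            age_effect = 0,
                            missing_rate = list(eeg_6m = 0, eeg_12m = 0,
                                                outcome = 0))
    co <- simulate_cohort(cc)
    res <- run_prediction_suite(co)
    sel <- res$cognitive_index$selected
    c("composite_absolute_power_theta" %in% sel,
      any(grepl("relative|modulation", sel)))
  })
  expect_gt(mean(hits[1, ]), 0.8)          # true predictor retained
  expect_lt(mean(hits[2, ]), 0.5)          # spurious indices usually excluded
})

test_that("pure-noise outcomes usually select the intercept-only model", {
  set.seed(80)
  res <- replicate(30, {
    d <- data.frame(matrix(rnorm(90 * 3), 90, 3))
    names(d) <- paste0("x", 1:3)
    d$y <- rnorm(90)
    got <- stepwise_aic("y", paste0("x", 1:3), d)
    oracle <- exhaustive_aic_oracle("y", paste0("x", 1:3), d)
    c(length(got$selected) == 0, isTRUE(all.equal(got$aic, oracle$aic)))
  })
  expect_gt(mean(res[1, ]), 0.5)           # intercept-only modal choice
  expect_gte(mean(res[2, ]), 0.99)         # always the exhaustive optimum
})

test_that("missing outcome columns raise a configuration error by name", {
  co <- make_cohort(rnorm(30), rnorm(30))
  co$relative_power_theta <- rnorm(60)
  co$modulation_index_theta <- rnorm(60)
  r24 <- data.frame(subject_id = unique(co$subject_id), timepoint = "24m",
                    absolute_power_theta = NA, relative_power_theta = NA,
                    modulation_index_theta = NA, stringsAsFactors = FALSE)
  co2 <- as_cohort_table(rbind(as.data.frame(co), r24))
  expect_error(run_prediction_suite(co2, outcomes = "cognitive_index",
                                    covariates = character()),
               class = "thetamod_config_error")
  expect_error(run_prediction_suite(co2, outcomes = "cognitive_index",
                                    covariates = character()),
               "cognitive_index")
})
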