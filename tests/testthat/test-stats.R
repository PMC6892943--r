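test_that("back-transform maps log-scale estimates to percent change", {
  expect_equal(backTransform(0), 0)
  b <- seq(-0.5, 0.5, by = 0.05)
  expect_true(all(diff(backTransform(b)) > 0))   # monotone in the estimate
  expect_equal(backTransform(log(2)), 100)
})

test_that("zero between-subject variance reduces the model to pooled OLS", {
  cfg <- synthConfig(n_subjects = 4, n_trials = 60,
                     coupling = c(meanpower = 0.07),
                     subject_intercept_sd = 0, mep_noise_sd = 0.3, seed = 12)
  m <- simulateTrialMetrics(cfg)
  expect_warning(fit <- fitMetricModel(m, "mean_power"), "pooled")
  ols <- unname(coef(lm(log_mep ~ mean_power, data = m))[2])
  expect_lt(abs(fit$effects$estimate - ols), 1e-6)
  expect_true(fit$pooled)
})

test_that("likelihood-ratio tests behave at the null and under a true effect", {
  ## identical models: statistic 0, p = 1
  cfg <- synthConfig(n_subjects = 8, n_trials = 60,
                     coupling = c(meanpower = 0.07, number = 0.6), seed = 31)
  m <- simulateTrialMetrics(cfg)
  base <- fitMetricModel(m, "mean_power", trial_filter = "events",
                         p_method = "wald")
  expect_equal(likelihoodRatioTest(base, base)$statistic, 0, tolerance = 1e-8)
  expect_equal(likelihoodRatioTest(base, base)$p, 1)
  ## adding a strongly coupled regressor: p < 0.001
  both <- fitMetricModel(m, c("mean_power", "n_events"),
                         trial_filter = "events", p_method = "wald")
  expect_lt(likelihoodRatioTest(base, both)$p, 1e-3)
  ## non-nested or differing trial sets are refused
  all_mp <- fitMetricModel(m, "mean_power", trial_filter = "all",
                           p_method = "wald")
  expect_error(likelihoodRatioTest(all_mp, both), "different trial sets")
  expect_error(likelihoodRatioTest(both, base), "fewer parameters|not nested")
})

test_that("fixed-effect p-values are calibrated under the null coupling", {
  ## all couplings zero: fraction of p < 0.05 within binomial error of 0.05
  n_rep <- 200
  p <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- synthConfig(n_subjects = 6, n_trials = 30,
                       coupling = c(meanpower = 0),
                       subject_intercept_sd = 0.2, seed = 5000 + r)
    m <- simulateTrialMetrics(cfg)
    fit <- suppressWarnings(fitMetricModel(m, "mean_power",
                                           p_method = "wald"))
    p[r] <- fit$effects$p
  }
  frac <- mean(p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("cross-validation folds partition each subject's trials", {
  cfg <- synthConfig(n_subjects = 5, n_trials = 20,
                     coupling = c(meanpower = 0.07), seed = 77)
  m <- simulateTrialMetrics(cfg)
  cv <- crossValidate(m, "mean_power", k = 10, seed = 42)
  ## with 20 trials per subject and k = 10, every fold tests exactly 2 per subject
  counts <- table(cv$assignment$subject, cv$assignment$fold)
  expect_true(all(counts == 2))
  ## a partition: every retained trial appears in exactly one fold
  expect_identical(sort(cv$assignment$trial), sort(m$trial[!m$excluded]))
  expect_false(anyDuplicated(cv$assignment$trial) > 0)
  ## subjects with fewer than k trials are named in the error
  cfg2 <- synthConfig(n_subjects = 2, n_trials = 5,
                      coupling = c(meanpower = 0.07), seed = 78)
  expect_error(crossValidate(simulateTrialMetrics(cfg2), "mean_power", k = 10),
               "s01")
})

test_that("permuted MEP labels destroy cross-validated prediction", {
  cfg <- synthConfig(n_subjects = 8, n_trials = 60,
                     coupling = c(meanpower = 0.07), seed = 13)
  m <- simulateTrialMetrics(cfg)
  ## folds share training data, so average over independent permutations
  set.seed(99)
  rhos <- vapply(1:10, function(i) {
    m$log_mep <- sample(m$log_mep)
    suppressWarnings(crossValidate(m, "mean_power", k = 10,
                                   seed = 3 + i))$mean_rho
  }, numeric(1))
  se <- sd(rhos) / sqrt(length(rhos))
  expect_lt(abs(mean(rhos)), 3 * se)
})

test_that("AIC prefers the generating metric over a pure-noise regressor", {
  wins <- 0
  for (r in 1:20) {
    cfg <- synthConfig(n_subjects = 20, n_trials = 300,
                       coupling = c(meanpower = 0.07), seed = 8000 + r)
    m <- simulateTrialMetrics(cfg)
    ## overwrite an unused metric with pure noise on the same rows
    m$last_duration_s <- rnorm(nrow(m))
    m$event_present <- 1L          # same trial set for both fits
    f_true <- fitMetricModel(m, "mean_power", trial_filter = "all",
                             p_method = "wald")
    f_noise <- fitMetricModel(m, "last_duration_s", trial_filter = "events",
                              p_method = "wald")
    if (f_true$aic < f_noise$aic) wins <- wins + 1
  }
  expect_equal(wins, 20)
})

test_that("metric-power correlations recover designed relationships", {
  cfg <- synthConfig(n_subjects = 4, n_trials = 30,
                     coupling = c(meanpower = 0.07), seed = 55)
  m <- simulateTrialMetrics(cfg)
  ## a monotone function of mean power correlates perfectly
  m$last_amplitude <- exp(m$mean_power)
  ## the negation correlates at -1
  m$last_duration_s <- -m$mean_power
  ## an independent metric has group-mean rho near 0
  set.seed(1); m$n_events <- rnorm(nrow(m))
  res <- metricPowerCorrelations(m)
  amp <- res$per_subject[res$per_subject$metric == "last_amplitude", ]
  dur <- res$per_subject[res$per_subject$metric == "last_duration_s", ]
  expect_true(all(amp$rho == 1))
  expect_true(all(dur$rho == -1))
  ind <- res$summary[res$summary$metric == "n_events", ]
  expect_lt(abs(ind$mean_rho), 3 * ind$sem + 1e-9)
  ## constant metric: excluded with a warning
  m$n_events <- 1
  expect_warning(res2 <- metricPowerCorrelations(m), "constant")
  expect_false("n_events" %in% res2$per_subject$metric)
})
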