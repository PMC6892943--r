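## Mixed-effects metric -> MEP models, likelihood-ratio comparisons, and
## per-subject k-fold cross-validation.

metricCols <- c("event_present", "n_events", "last_duration_s",
                "last_amplitude", "last_timing_s", "mean_power")

## Event-specific metrics are modeled on event trials only; presence and
## mean power on all retained trials (the "auto" policy).
eventOnlyMetrics <- c("n_events", "last_duration_s", "last_amplitude",
                      "last_timing_s")

filterModelRows <- function(metrics, metric, trial_filter) {
  stopifnot(all(metric %in% metricCols))
  rows <- !metrics$excluded & is.finite(metrics$log_mep)
  event_only <- switch(trial_filter,
                       auto = any(metric %in% eventOnlyMetrics),
                       events = TRUE,
                       all = FALSE,
                       stop("unknown trial_filter: ", trial_filter))
  if (event_only) rows <- rows & metrics$event_present == 1
  for (m in metric) rows <- rows & is.finite(metrics[[m]])
  metrics[rows, , drop = FALSE]
}

## Fit the random-intercept model by ML with graceful degradation:
## "lmer" (normal case), "pooled" (singular fit, zero intercept variance:
## the fully-shrunk limit is ordinary pooled regression), or "fixed"
## (numerically degenerate fit, typically zero residual variance: the
## unshrunk limit is a per-subject fixed-intercept regression).
fitMixedML <- function(metric, d, p_method = "satterthwaite") {
  fml <- stats::as.formula(paste("log_mep ~", paste(metric, collapse = " + "),
                                 "+ (1 | subject)"))
  ctrl <- lme4::lmerControl(
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4),
    check.conv.grad = lme4::.makeCC(action = "ignore", tol = 2e-3),
    check.conv.hess = lme4::.makeCC(action = "ignore", tol = 1e-6))
  fitter <- if (p_method == "satterthwaite") lmerTest::lmer else lme4::lmer
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      fitter(fml, data = d, REML = FALSE, control = ctrl))),
    error = function(e) NULL)
  if (is.null(fit)) {
    fit <- stats::lm(stats::as.formula(
      paste("log_mep ~", paste(metric, collapse = " + "), "+ subject")),
      data = d)
    return(list(fit = fit, type = "fixed"))
  }
  if (lme4::isSingular(fit, tol = 1e-4)) {
    fit <- stats::lm(stats::as.formula(
      paste("log_mep ~", paste(metric, collapse = " + "))), data = d)
    return(list(fit = fit, type = "pooled"))
  }
  list(fit = fit, type = "lmer")
}

#' Fit a mixed-effects beta-metric model of log MEP amplitude
#'
#' Fits `log_mep ~ metric + (1 | subject)` by maximum likelihood (so that
#' likelihood-ratio tests and AIC comparisons between fits are valid), with
#' Satterthwaite p-values and Wald 95% confidence intervals. Models of
#' event-specific metrics (number, duration, amplitude, timing) are fit on
#' event trials only; presence and mean-power models on all retained trials.
#' If the random-intercept fit is singular (zero between-subject variance),
#' the function falls back to a pooled ordinary regression with a warning
#' and flags it; if the fit is numerically degenerate (zero residual
#' variance), it uses the unshrunk per-subject fixed-intercept limit.
#'
#' @param metrics TrialMetrics data frame (see [summarizeTrials()]).
#' @param metric character vector of one or more fixed-effect metric names
#'   from event_present, n_events, last_duration_s, last_amplitude,
#'   last_timing_s, mean_power.
#' @param trial_filter "auto" (default, policy above), "all", or "events".
#' @param p_method "satterthwaite" (default, via lmerTest) or "wald"
#'   (normal approximation; much faster for large fits).
#' @return an object of class `mepModel`: list with `effects` (data frame:
#'   term, estimate, se, ci_lo, ci_hi, p, percent_change, percent_lo,
#'   percent_hi), `aic`, `logLik`, `df`, `n`, `pooled`, `fallback`,
#'   `metric`, `trial_filter`, and the underlying `fit`.
#' @export
fitMetricModel <- function(metrics, metric, trial_filter = "auto",
                           p_method = c("satterthwaite", "wald")) {
  p_method <- match.arg(p_method)
  d <- filterModelRows(metrics, metric, trial_filter)
  if (length(unique(d$subject)) < 2)
    stop("mixed model requires >= 2 subjects")
  for (m in metric)
    if (stats::sd(d[[m]]) == 0) stop("predictor has no variance: ", m)
  mf <- fitMixedML(metric, d, p_method)
  fit <- mf$fit
  if (mf$type == "pooled")
    warning("singular random-intercept fit; falling back to pooled ",
            "ordinary regression")
  cf <- if (mf$type == "lmer") stats::coef(summary(fit)) else
    summary(fit)$coefficients
  est <- cf[metric, "Estimate"]
  se <- cf[metric, "Std. Error"]
  p <- if (mf$type == "lmer" && p_method == "wald")
    2 * stats::pnorm(-abs(est / se)) else cf[metric, ncol(cf)]
  z <- stats::qnorm(0.975)
  eff <- data.frame(term = metric, estimate = unname(est), se = unname(se),
                    ci_lo = unname(est - z * se), ci_hi = unname(est + z * se),
                    p = unname(p), stringsAsFactors = FALSE)
  eff$percent_change <- backTransform(eff$estimate)
  eff$percent_lo <- backTransform(eff$ci_lo)
  eff$percent_hi <- backTransform(eff$ci_hi)
  ll <- stats::logLik(fit)
  structure(list(effects = eff, aic = stats::AIC(fit),
                 logLik = as.numeric(ll), df = attr(ll, "df"),
                 n = nrow(d), pooled = mf$type != "lmer",
                 fallback = if (mf$type == "lmer") NA_character_ else mf$type,
                 metric = metric, trial_filter = trial_filter, fit = fit),
            class = "mepModel")
}

#' @export
print.mepModel <- function(x, ...) {
  cat("Mixed-effects MEP model (", if (x$pooled) "pooled fallback" else
      "random intercept per subject", ", ML), n = ", x$n, " trials\n",
      sep = "")
  eff <- x$effects
  for (i in seq_len(nrow(eff)))
    cat(sprintf("  %-16s b = %+.4f [%.4f, %.4f], p = %.3g, %%change = %.2f\n",
                eff$term[i], eff$estimate[i], eff$ci_lo[i], eff$ci_hi[i],
                eff$p[i], eff$percent_change[i]))
  cat(sprintf("  AIC = %.1f, logLik = %.2f\n", x$aic, x$logLik))
  invisible(x)
}

#' Back-transform a log-scale estimate to percent MEP change
#'
#' Converts a fixed-effect estimate `b` on natural-log MEP amplitude into
#' the percent change in raw amplitude per unit of the metric:
#' `(exp(b) - 1) * 100`.
#'
#' @param estimate numeric estimate(s) on the log scale.
#' @return percent change(s).
#' @export
backTransform <- function(estimate) (exp(estimate) - 1) * 100

#' Likelihood-ratio test between nested metric models
#'
#' Refers `2 * (logLik(complex) - logLik(simple))` to a chi-squared
#' distribution with degrees of freedom equal to the parameter difference.
#' Both models must be maximum-likelihood fits on identical trial sets, and
#' the simple model's fixed effects must be a subset of the complex model's.
#'
#' @param simple,complex `mepModel` objects from [fitMetricModel()].
#' @return list with `statistic`, `df`, `p`.
#' @export
likelihoodRatioTest <- function(simple, complex) {
  stopifnot(inherits(simple, "mepModel"), inherits(complex, "mepModel"))
  if (simple$n != complex$n)
    stop("models were fit on different trial sets (n = ", simple$n,
         " vs ", complex$n, ")")
  if (!all(simple$metric %in% complex$metric))
    stop("models are not nested: simple fixed effects must be a subset ",
         "of the complex model's")
  df <- complex$df - simple$df
  if (df < 0) stop("complex model has fewer parameters than simple model")
  stat <- max(0, 2 * (complex$logLik - simple$logLik))
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Per-subject k-fold cross-validation of a metric model
#'
#' Each subject's retained trials are shuffled (seeded) and dealt into k
#' folds, so every training set holds ~90% and every test set ~10% of each
#' subject's trials. The model is refit on each training set; test-trial
#' predictions use the fixed effects plus the subject's fitted random
#' intercept (subjects appear in both sets by design). Per fold, Spearman's
#' correlation between predicted and actual log MEP amplitude and the RMSE
#' are computed; the averaged RMSE is normalized by the observed range of
#' log MEP amplitude.
#'
#' @param metrics TrialMetrics data frame.
#' @param metric fixed-effect metric name(s).
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold shuffle.
#' @param include_random include the subject's random intercept in
#'   predictions (default TRUE); FALSE predicts from fixed effects only.
#' @param trial_filter as in [fitMetricModel()].
#' @return list with `folds` (data frame: fold, rho, p, rmse, n_test),
#'   `mean_rho`, `mean_rmse`, `nrmse`, `k`, `seed`, and `assignment`
#'   (data frame: subject, trial, fold).
#' @export
crossValidate <- function(metrics, metric, k = 10, seed = 1L,
                          include_random = TRUE, trial_filter = "auto") {
  d <- filterModelRows(metrics, metric, trial_filter)
  tab <- table(d$subject)
  short <- names(tab)[tab < k]
  if (length(short))
    stop("subject(s) with fewer than k = ", k, " trials: ",
         paste(short, collapse = ", "))
  fold <- integer(nrow(d))
  withSeed(seed, {
    for (s in unique(d$subject)) {
      rows <- which(d$subject == s)
      ord <- sample(length(rows))
      fold[rows[ord]] <- rep(seq_len(k), length.out = length(rows))
    }
  })
  folds <- data.frame(fold = seq_len(k), rho = NA_real_, p = NA_real_,
                      rmse = NA_real_, n_test = 0L)
  for (f in seq_len(k)) {
    train <- d[fold != f, , drop = FALSE]
    test <- d[fold == f, , drop = FALSE]
    mf <- fitMixedML(metric, train, p_method = "wald")
    pred <- if (mf$type == "lmer")
      stats::predict(mf$fit, newdata = test,
                     re.form = if (include_random) NULL else NA)
    else stats::predict(mf$fit, newdata = test)
    ct <- suppressWarnings(stats::cor.test(pred, test$log_mep,
                                           method = "spearman"))
    folds$rho[f] <- unname(ct$estimate)
    folds$p[f] <- ct$p.value
    folds$rmse[f] <- sqrt(mean((pred - test$log_mep)^2))
    folds$n_test[f] <- nrow(test)
  }
  rng <- diff(range(d$log_mep))
  list(folds = folds, mean_rho = mean(folds$rho), mean_rmse = mean(folds$rmse),
       nrmse = mean(folds$rmse) / rng, k = k, seed = seed,
       assignment = data.frame(subject = d$subject, trial = d$trial,
                               fold = fold, stringsAsFactors = FALSE))
}

#' Per-subject collinearity of event metrics with mean beta power
#'
#' Spearman correlations, per subject, between each event metric (number,
#' last-event duration, last-event amplitude) and the trial's mean beta
#' power; subjects with a constant metric are excluded with a warning.
#'
#' @param metrics TrialMetrics data frame.
#' @param cols metric columns to correlate with mean_power.
#' @return list with `per_subject` (data frame: subject, metric, rho, n) and
#'   `summary` (data frame: metric, mean_rho, sem, n_subjects).
#' @export
metricPowerCorrelations <- function(metrics,
                                    cols = c("n_events", "last_duration_s",
                                             "last_amplitude")) {
  d <- metrics[!metrics$excluded, , drop = FALSE]
  out <- list()
  dropped <- FALSE
  for (m in cols) {
    for (s in unique(d$subject)) {
      rows <- d[d$subject == s, , drop = FALSE]
      ok <- is.finite(rows[[m]]) & is.finite(rows$mean_power)
      rows <- rows[ok, , drop = FALSE]
      if (nrow(rows) < 3) next
      if (stats::sd(rows[[m]]) == 0 || stats::sd(rows$mean_power) == 0) {
        dropped <- TRUE
        next
      }
      rho <- stats::cor(rows[[m]], rows$mean_power, method = "spearman")
      out[[length(out) + 1]] <- data.frame(subject = s, metric = m,
                                           rho = rho, n = nrow(rows))
    }
  }
  if (dropped)
    warning("subject(s) with a constant metric excluded from correlations")
  per <- if (length(out)) do.call(rbind, out) else
    data.frame(subject = character(), metric = character(), rho = numeric(),
               n = integer())
  summ <- do.call(rbind, lapply(unique(per$metric), function(m) {
    r <- per$rho[per$metric == m]
    data.frame(metric = m, mean_rho = mean(r),
               sem = stats::sd(r) / sqrt(length(r)), n_subjects = length(r))
  }))
  list(per_subject = per, summary = summ)
}
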