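## MEP extraction from EMG epochs and trial-exclusion filters.

#' Peak-to-peak MEP amplitude
#'
#' Difference between the maximum and minimum EMG voltage within the MEP
#' window (+20 to +40 ms after the stimulus by default). Invariant to
#' constant offsets in the trace.
#'
#' @param trials a [TrialSet-class] with EMG data.
#' @param window MEP window (s), default c(0.020, 0.040).
#' @return numeric vector of amplitudes (mV), one per trial.
#' @export
mepAmplitude <- function(trials, window = c(0.020, 0.040)) {
  time <- timeAxis(trials)
  if (window[1] < time[1] - 1e-9 || window[2] > time[length(time)] + 1e-9)
    stop("MEP window lies outside the epoch")
  emg <- emgData(trials)
  if (!nrow(emg)) stop("TrialSet carries no EMG data")
  idx <- which(time >= window[1] - 1e-9 & time <= window[2] + 1e-9)
  unname(apply(emg[, idx, drop = FALSE], 1, function(x) max(x) - min(x)))
}

#' Flag trials with excessive pre-stimulus EMG activity
#'
#' Per-sample EMG power (squared deviation from the trial's epoch-wide mean
#' voltage, so a lone spike inside the short window cannot bias the
#' baseline) is pooled per subject across trials; the empirical upper limit
#' is Q75 + 3*IQR of that pool. Trials in which more than half of the window
#' samples exceed the limit are flagged as voluntary contraction.
#'
#' @param trials a [TrialSet-class] with EMG data.
#' @param window pre-stimulus window (s), default c(-0.025, -0.005).
#' @return data frame: trial, subject, prestim_power (mean power in the
#'   window), frac_over, flagged.
#' @export
prestimEMGFilter <- function(trials, window = c(-0.025, -0.005)) {
  time <- timeAxis(trials)
  if (window[1] < time[1] - 1e-9 || window[2] > time[length(time)] + 1e-9)
    stop("pre-stimulus window lies outside the epoch")
  idx <- which(time >= window[1] - 1e-9 & time <= window[2] + 1e-9)
  emg <- emgData(trials)
  subj <- subjectIds(trials)
  n <- nTrials(trials)
  pow <- matrix(0, n, length(idx))
  for (k in seq_len(n)) {
    pow[k, ] <- (emg[k, idx] - mean(emg[k, ]))^2
  }
  frac_over <- numeric(n)
  for (s in unique(subj)) {
    rows <- which(subj == s)
    pool <- as.vector(pow[rows, , drop = FALSE])
    limit <- stats::quantile(pool, 0.75, type = 7, names = FALSE) +
      3 * stats::IQR(pool, type = 7)
    frac_over[rows] <- rowMeans(pow[rows, , drop = FALSE] > limit)
  }
  data.frame(trial = trialIds(trials), subject = subj,
             prestim_power = rowMeans(pow), frac_over = frac_over,
             flagged = frac_over > 0.5, stringsAsFactors = FALSE)
}

#' Flag MEPs that do not match the subject's mean MEP waveform
#'
#' The subject template is the mean MEP-window waveform over trials not
#' already excluded; trials whose Pearson correlation with the template is
#' <= `r_min` (or undefined because the trial window has zero variance) are
#' flagged. Single pass: the template is not recomputed after flagging.
#'
#' @param trials a [TrialSet-class] with EMG data.
#' @param exclude logical vector: trials already excluded (these do not
#'   shape the template but are still scored).
#' @param window correlation window (s), default the MEP window.
#' @param r_min correlation threshold, default 0.40.
#' @return data frame: trial, subject, template_r, flagged, degenerate.
#' @export
templateCorrelationFilter <- function(trials, exclude = NULL,
                                      window = c(0.020, 0.040),
                                      r_min = 0.40) {
  time <- timeAxis(trials)
  idx <- which(time >= window[1] - 1e-9 & time <= window[2] + 1e-9)
  emg <- emgData(trials)
  subj <- subjectIds(trials)
  n <- nTrials(trials)
  if (is.null(exclude)) exclude <- rep(FALSE, n)
  r <- rep(NA_real_, n)
  for (s in unique(subj)) {
    rows <- which(subj == s)
    keep <- rows[!exclude[rows]]
    if (length(keep) < 2)
      stop("subject ", s, " has fewer than 2 retained trials for the ",
           "MEP template")
    tpl <- colMeans(emg[keep, idx, drop = FALSE])
    for (k in rows) {
      x <- emg[k, idx]
      if (stats::sd(x) == 0 || stats::sd(tpl) == 0) r[k] <- NA_real_
      else r[k] <- stats::cor(x, tpl)
    }
  }
  degenerate <- is.na(r)
  data.frame(trial = trialIds(trials), subject = subj, template_r = r,
             flagged = degenerate | (!is.na(r) & r <= r_min),
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Extract MEP records with exclusion filters and log transform
#'
#' Runs the EMG chain: peak-to-peak amplitude in the MEP window, the
#' pre-stimulus voluntary-activity filter, the template-correlation filter
#' (template built from trials passing the pre-stimulus filter), and the
#' natural-log transform (zero amplitudes are flagged, not transformed).
#'
#' @param trials a [TrialSet-class] with EMG data.
#' @param mep_window MEP window (s), default c(0.020, 0.040).
#' @param prestim_window pre-stimulus EMG window (s), default
#'   c(-0.025, -0.005).
#' @param r_min template correlation threshold, default 0.40.
#' @return MEPRecord data frame: subject, trial, peak_to_peak_mv,
#'   log_amplitude, prestim_power, template_r, excluded, reason.
#' @export
extractMEPs <- function(trials, mep_window = c(0.020, 0.040),
                        prestim_window = c(-0.025, -0.005), r_min = 0.40) {
  p2p <- mepAmplitude(trials, mep_window)
  pre <- prestimEMGFilter(trials, prestim_window)
  tc <- templateCorrelationFilter(trials, exclude = pre$flagged,
                                  window = mep_window, r_min = r_min)
  zero <- p2p <= 0
  excluded <- pre$flagged | tc$flagged | zero
  reason <- rep("", length(p2p))
  reason[tc$flagged] <- "template_r"
  reason[tc$degenerate] <- "degenerate"
  reason[pre$flagged] <- "prestim_emg"
  reason[zero] <- "zero_amplitude"
  data.frame(subject = subjectIds(trials), trial = trialIds(trials),
             peak_to_peak_mv = p2p,
             log_amplitude = ifelse(zero, NA_real_, log(p2p)),
             prestim_power = pre$prestim_power, template_r = tc$template_r,
             excluded = excluded, reason = reason, stringsAsFactors = FALSE)
}
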