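## Re-referencing, Hjorth spatial filtering, and pre-stimulus artifact
## rejection.

#' Common average reference
#'
#' Subtracts, at every trial and time point, the mean over channels from
#' each channel. The per-sample channel mean of the output is exactly zero.
#'
#' @param trials a [TrialSet-class] with at least two channels.
#' @return a re-referenced [TrialSet-class].
#' @export
commonAverageReference <- function(trials) {
  eeg <- eegData(trials)
  if (dim(eeg)[2] < 2)
    stop("common average reference requires at least 2 channels")
  m <- apply(eeg, c(1, 3), mean)          # trial x time
  for (ch in seq_len(dim(eeg)[2])) eeg[, ch, ] <- eeg[, ch, ] - m
  TrialSet(eeg, emgData(trials), samplingRate(trials), timeAxis(trials),
           channelNames(trials), subjectIds(trials), trialIds(trials))
}

#' Hjorth (local Laplacian) spatial filter
#'
#' Central electrode minus the mean of its surrounding electrodes, per
#' sample, emphasizing sources beneath the central site. The default montage
#' targets the right motor cortex: C4 referenced to FC2, FC6, CP2, CP6.
#' Because the Hjorth weights sum to zero, applying a common average
#' reference first does not change the result.
#'
#' @param trials a [TrialSet-class].
#' @param central central channel name (default "C4").
#' @param surround surrounding channel names.
#' @return a single-channel [TrialSet-class]; the channel is named
#'   `<central>-hjorth`.
#' @export
hjorthTransform <- function(trials, central = "C4",
                            surround = c("FC2", "FC6", "CP2", "CP6")) {
  chs <- channelNames(trials)
  missing <- setdiff(c(central, surround), chs)
  if (length(missing))
    stop("channel(s) not present: ", paste(missing, collapse = ", "))
  eeg <- eegData(trials)
  ci <- match(central, chs)
  si <- match(surround, chs)
  sur <- eeg[, si, , drop = FALSE]
  out <- eeg[, ci, ] - apply(sur, c(1, 3), mean)
  n <- nTrials(trials)
  arr <- array(out, dim = c(n, 1, length(timeAxis(trials))))
  TrialSet(arr, emgData(trials), samplingRate(trials), timeAxis(trials),
           paste0(central, "-hjorth"), subjectIds(trials), trialIds(trials))
}

#' Reject trials with pre-stimulus artifacts
#'
#' Flags trials whose analysis channel exceeds an absolute amplitude
#' threshold or a (Pearson) kurtosis threshold within the 1 s pre-stimulus
#' window, and drops them. The window is closed on the left and open at the
#' stimulus: `[window[1], 0)`.
#'
#' @param trials a [TrialSet-class]; if multi-channel, `channel` selects the
#'   channel evaluated (defaults to the single channel present).
#' @param window evaluation window (s), default c(-1, 0).
#' @param amp_thresh_uv amplitude threshold (uV), default 50.
#' @param kurt_thresh Pearson kurtosis threshold (normal ~ 3), default 4.
#' @param channel channel name to evaluate; required when several channels
#'   are present.
#' @return list with `trials` (retained [TrialSet-class]) and `report`
#'   (data frame: trial, subject, max_abs_uv, kurtosis, rejected, reason).
#' @export
rejectArtifacts <- function(trials, window = c(-1, 0), amp_thresh_uv = 50,
                            kurt_thresh = 4, channel = NULL) {
  time <- timeAxis(trials)
  if (window[1] < time[1] - 1e-9 || window[2] > time[length(time)] + 1e-9)
    stop("rejection window lies outside the epoch")
  chs <- channelNames(trials)
  if (is.null(channel)) {
    if (length(chs) != 1)
      stop("multi-channel TrialSet: specify `channel` to evaluate")
    channel <- chs
  }
  ci <- match(channel, chs)
  if (is.na(ci)) stop("channel not present: ", channel)
  idx <- which(time >= window[1] - 1e-9 & time < window[2])
  eeg <- eegData(trials)
  n <- nTrials(trials)
  maxabs <- kurt <- numeric(n)
  for (k in seq_len(n)) {
    x <- eeg[k, ci, idx]
    maxabs[k] <- max(abs(x))
    kurt[k] <- pearsonKurtosis(x)
  }
  amp_bad <- maxabs > amp_thresh_uv
  kurt_bad <- kurt > kurt_thresh
  rejected <- amp_bad | kurt_bad
  reason <- rep("", n)
  reason[amp_bad & !kurt_bad] <- "amplitude"
  reason[!amp_bad & kurt_bad] <- "kurtosis"
  reason[amp_bad & kurt_bad] <- "amplitude+kurtosis"
  report <- data.frame(trial = trialIds(trials), subject = subjectIds(trials),
                       max_abs_uv = maxabs, kurtosis = kurt,
                       rejected = rejected, reason = reason,
                       stringsAsFactors = FALSE)
  if (all(rejected)) stop("no trials survive artifact rejection")
  list(trials = trials[which(!rejected)], report = report)
}
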