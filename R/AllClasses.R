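#' @import methods
NULL

#' TrialSet: epoched multi-channel EEG and EMG trials
#'
#' Container for stimulus-locked trials: an EEG array (trial x channel x
#' time, microvolts), an EMG matrix (trial x time, millivolts), a common
#' time axis in seconds with the stimulus at 0, channel names, and a subject
#' label per trial.
#'
#' @slot eeg numeric array, trial x channel x time (uV).
#' @slot emg numeric matrix, trial x time (mV).
#' @slot fs sampling rate (Hz).
#' @slot time time axis (s), strictly increasing, spanning the stimulus at 0.
#' @slot channels channel names (unique).
#' @slot subject subject id per trial.
#' @slot trial trial id per trial (unique).
#' @exportClass TrialSet
setClass("TrialSet", slots = c(
  eeg = "array",
  emg = "matrix",
  fs = "numeric",
  time = "numeric",
  channels = "character",
  subject = "character",
  trial = "character"
))

setValidity("TrialSet", function(object) {
  msg <- character()
  d <- dim(object@eeg)
  if (length(d) != 3) msg <- c(msg, "eeg must be a trial x channel x time array")
  else {
    if (d[2] != length(object@channels))
      msg <- c(msg, "channel dimension does not match channel names")
    if (d[3] != length(object@time))
      msg <- c(msg, "time dimension does not match time axis")
    if (d[1] != length(object@subject))
      msg <- c(msg, "each trial needs exactly one subject label")
    if (d[1] != length(object@trial))
      msg <- c(msg, "each trial needs a trial id")
    if (nrow(object@emg) != d[1] && nrow(object@emg) != 0)
      msg <- c(msg, "emg trial dimension does not match eeg")
  }
  if (nrow(object@emg) > 0 && ncol(object@emg) != length(object@time))
    msg <- c(msg, "emg time dimension does not match time axis")
  if (anyDuplicated(object@channels)) msg <- c(msg, "channel names must be unique")
  if (anyDuplicated(object@trial)) msg <- c(msg, "trial ids must be unique")
  if (length(object@time) >= 2 && any(diff(object@time) <= 0))
    msg <- c(msg, "time axis must be strictly increasing")
  if (length(object@time) && (object@time[1] >= 0 ||
      object@time[length(object@time)] < 0))
    msg <- c(msg, "time axis must span the stimulus at t = 0")
  if (length(object@fs) != 1 || object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a TrialSet
#'
#' @param eeg trial x channel x time array (uV).
#' @param emg trial x time matrix (mV); may have zero rows if unavailable.
#' @param fs sampling rate (Hz).
#' @param time time axis (s) with the stimulus at 0.
#' @param channels channel names.
#' @param subject subject id per trial.
#' @param trial trial ids; defaults to `t0001...`.
#' @return a [TrialSet-class] object.
#' @export
TrialSet <- function(eeg, emg, fs, time, channels, subject,
                     trial = sprintf("t%04d", seq_len(dim(eeg)[1]))) {
  new("TrialSet", eeg = eeg, emg = emg, fs = fs, time = time,
      channels = as.character(channels), subject = as.character(subject),
      trial = as.character(trial))
}

#' BetaSeries: normalized beta-power time series per trial
#'
#' Per-trial power of the wavelet-transformed analysis channel at each
#' subject's individual beta frequency (IBF), divided by the subject's mean
#' pre-stimulus beta power, restricted to the analysis window.
#'
#' @slot power trial x time matrix of normalized power (>= 0).
#' @slot time time axis (s) of the analysis window.
#' @slot fs sampling rate (Hz).
#' @slot subject subject id per trial.
#' @slot trial trial id per trial.
#' @slot ibf named numeric: individual beta frequency per subject (Hz).
#' @slot normConst named numeric: normalization constant per subject (raw
#'   power units).
#' @exportClass BetaSeries
setClass("BetaSeries", slots = c(
  power = "matrix",
  time = "numeric",
  fs = "numeric",
  subject = "character",
  trial = "character",
  ibf = "numeric",
  normConst = "numeric"
))

setValidity("BetaSeries", function(object) {
  msg <- character()
  if (ncol(object@power) != length(object@time))
    msg <- c(msg, "power columns must match time axis")
  if (nrow(object@power) != length(object@subject))
    msg <- c(msg, "power rows must match subject labels")
  if (nrow(object@power) != length(object@trial))
    msg <- c(msg, "power rows must match trial ids")
  if (any(object@power < 0)) msg <- c(msg, "power must be non-negative")
  if (!all(unique(object@subject) %in% names(object@ibf)))
    msg <- c(msg, "every subject needs an IBF")
  if (length(msg)) msg else TRUE
})

#' Construct a BetaSeries
#'
#' @param power trial x time matrix of normalized power.
#' @param time time axis (s).
#' @param fs sampling rate (Hz).
#' @param subject subject id per trial.
#' @param trial trial ids.
#' @param ibf named IBF per subject (Hz).
#' @param normConst named normalization constant per subject.
#' @return a [BetaSeries-class] object.
#' @export
BetaSeries <- function(power, time, fs, subject, trial, ibf, normConst) {
  new("BetaSeries", power = power, time = time, fs = fs,
      subject = as.character(subject), trial = as.character(trial),
      ibf = ibf, normConst = normConst)
}

## ---- generics & accessors -------------------------------------------------

#' @rdname TrialSet-class
#' @param object,x a TrialSet or BetaSeries.
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))
#' @export
setGeneric("trialIds", function(x) standardGeneric("trialIds"))
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))
#' @export
setGeneric("emgData", function(x) standardGeneric("emgData"))
#' @export
setGeneric("powerMatrix", function(x) standardGeneric("powerMatrix"))
#' @export
setGeneric("subjectIBF", function(x) standardGeneric("subjectIBF"))
#' @export
setGeneric("normConstants", function(x) standardGeneric("normConstants"))

#' @export
setMethod("nTrials", "TrialSet", function(x) dim(x@eeg)[1])
#' @export
setMethod("samplingRate", "TrialSet", function(x) x@fs)
#' @export
setMethod("timeAxis", "TrialSet", function(x) x@time)
#' @export
setMethod("subjectIds", "TrialSet", function(x) x@subject)
#' @export
setMethod("trialIds", "TrialSet", function(x) x@trial)
#' @export
setMethod("channelNames", "TrialSet", function(x) x@channels)
#' @export
setMethod("eegData", "TrialSet", function(x) x@eeg)
#' @export
setMethod("emgData", "TrialSet", function(x) x@emg)

#' @export
setMethod("nTrials", "BetaSeries", function(x) nrow(x@power))
#' @export
setMethod("samplingRate", "BetaSeries", function(x) x@fs)
#' @export
setMethod("timeAxis", "BetaSeries", function(x) x@time)
#' @export
setMethod("subjectIds", "BetaSeries", function(x) x@subject)
#' @export
setMethod("trialIds", "BetaSeries", function(x) x@trial)
#' @export
setMethod("powerMatrix", "BetaSeries", function(x) x@power)
#' @export
setMethod("subjectIBF", "BetaSeries", function(x) x@ibf)
#' @export
setMethod("normConstants", "BetaSeries", function(x) x@normConst)

## Subset trials with `[`
#' @export
setMethod("[", "TrialSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@trial)
  emg <- if (nrow(x@emg)) x@emg[i, , drop = FALSE] else x@emg
  TrialSet(x@eeg[i, , , drop = FALSE], emg, x@fs, x@time, x@channels,
           x@subject[i], x@trial[i])
})

#' @export
setMethod("[", "BetaSeries", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@trial)
  BetaSeries(x@power[i, , drop = FALSE], x@time, x@fs, x@subject[i],
             x@trial[i], x@ibf, x@normConst)
})

setMethod("show", "TrialSet", function(object) {
  d <- dim(object@eeg)
  cat("TrialSet:", d[1], "trials,", d[2], "channels,", d[3], "samples @",
      object@fs, "Hz\n")
  cat("  epoch:", sprintf("[%.3f, %.3f] s", object@time[1],
      object@time[length(object@time)]), "\n")
  cat("  subjects:", length(unique(object@subject)),
      "| EMG:", if (nrow(object@emg)) "present" else "absent", "\n")
})

setMethod("show", "BetaSeries", function(object) {
  cat("BetaSeries:", nrow(object@power), "trials,", ncol(object@power),
      "samples @", object@fs, "Hz\n")
  cat("  window:", sprintf("[%.3f, %.3f] s", object@time[1],
      object@time[length(object@time)]), "\n")
  ibf <- object@ibf
  cat("  IBF (Hz):", paste(sprintf("%s=%g", names(ibf), ibf), collapse = ", "),
      "\n")
})
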