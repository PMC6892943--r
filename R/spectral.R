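## Multitaper spectra, individual beta frequency, and wavelet beta-power
## time series.

#' Spectral analysis configuration
#'
#' @param psd_band frequency band of the reported spectrum (Hz).
#' @param smoothing_bw multitaper half-bandwidth (Hz); with a 1 s segment
#'   this gives time-bandwidth product `smoothing_bw * T` and `2*NW - 1`
#'   tapers.
#' @param ibf_band band searched for the individual beta frequency (Hz).
#' @param wavelet_cycles Morlet cycles for the power time series (default 5).
#' @param trial_window pre-stimulus analysis window (s).
#' @param psd_window window used for spectral estimation (s), default the
#'   final pre-stimulus second.
#' @param resample_fs internal sampling rate (Hz) used for taper
#'   computation; the analysis band must lie well below `resample_fs / 2`.
#' @return a validated list of class `SpectralConfig`.
#' @export
spectralConfig <- function(psd_band = c(1, 30), smoothing_bw = 2,
                           ibf_band = c(15, 30), wavelet_cycles = 5,
                           trial_window = c(-1, -0.05),
                           psd_window = c(-1, 0), resample_fs = 200) {
  if (ibf_band[1] < psd_band[1] || ibf_band[2] > psd_band[2])
    stop("ibf_band must lie inside psd_band")
  if (wavelet_cycles < 3) stop("wavelet_cycles must be >= 3")
  if (trial_window[2] >= 0) stop("trial_window must be strictly pre-stimulus")
  if (resample_fs < 4 * psd_band[2]) stop("resample_fs too low for psd_band")
  structure(list(psd_band = psd_band, smoothing_bw = smoothing_bw,
                 ibf_band = ibf_band, wavelet_cycles = wavelet_cycles,
                 trial_window = trial_window, psd_window = psd_window,
                 resample_fs = resample_fs),
            class = "SpectralConfig")
}

#' Multitaper power spectral density per subject
#'
#' Slepian-tapered spectra of the analysis channel's pre-stimulus segment,
#' averaged over each subject's retained trials. The segment is
#' FFT-resampled to `resample_fs` (the band of interest is far below the
#' recording rate), tapered with `2*NW - 1` DPSS tapers at time-bandwidth
#' `NW = smoothing_bw * T`, and restricted to `psd_band`.
#'
#' @param trials a single-channel [TrialSet-class] (post-Hjorth).
#' @param config a [spectralConfig()].
#' @return data frame with columns subject, freq (Hz), power.
#' @export
estimatePSD <- function(trials, config = spectralConfig()) {
  time <- timeAxis(trials)
  win <- config$psd_window
  if (time[1] > win[1] + 1e-9)
    stop("trial shorter than the taper window: epoch must cover ",
         sprintf("%.2f s pre-stimulus", -win[1]))
  idx <- which(time >= win[1] - 1e-9 & time < win[2])
  T_len <- diff(win)
  n_out <- round(T_len * config$resample_fs)
  nw <- config$smoothing_bw * T_len
  k <- max(1L, floor(2 * nw - 1))
  tapers <- dpssTapers(n_out, nw, k)
  freqs <- (0:(n_out - 1)) / T_len
  keep <- which(freqs >= config$psd_band[1] & freqs <= config$psd_band[2])
  eeg <- eegData(trials)
  subj <- subjectIds(trials)
  out <- lapply(unique(subj), function(s) {
    rows <- which(subj == s)
    acc <- numeric(length(keep))
    for (r in rows) {
      x <- eeg[r, 1, idx]
      x <- fftResample(x - mean(x), n_out)
      for (j in seq_len(k)) {
        X <- stats::fft(x * tapers[, j])
        acc <- acc + Mod(X[keep])^2 / (k * config$resample_fs)
      }
    }
    data.frame(subject = s, freq = freqs[keep], power = acc / length(rows))
  })
  do.call(rbind, out)
}

#' Individual beta frequency (IBF)
#'
#' The frequency at which spectral power is maximal within the beta band.
#' If the maximum sits on a band edge (e.g. a monotone 1/f spectrum with no
#' interior beta peak), a warning is issued and the edge frequency is still
#' returned.
#'
#' @param psd data frame from [estimatePSD()] (one or several subjects).
#' @param band search band (Hz), default c(15, 30).
#' @return named numeric vector of IBFs (Hz), one per subject.
#' @export
findIBF <- function(psd, band = c(15, 30)) {
  stopifnot(all(c("subject", "freq", "power") %in% names(psd)))
  out <- vapply(unique(psd$subject), function(s) {
    d <- psd[psd$subject == s & psd$freq >= band[1] & psd$freq <= band[2], ]
    if (!nrow(d)) stop("spectrum does not cover the IBF band")
    f <- d$freq[which.max(d$power)]
    if (f == min(d$freq) || f == max(d$freq))
      warning("no interior beta peak for subject ", s,
              "; IBF set to band edge ", f, " Hz")
    f
  }, numeric(1))
  stats::setNames(out, unique(psd$subject))
}

#' Wavelet beta-power time series, normalized per subject
#'
#' Convolves each trial's pre-stimulus segment with a complex Morlet wavelet
#' at the subject's IBF. To avoid edge decay at the stimulus, the
#' pre-stimulus series is mirrored at t = 0 (time-reversed reflection)
#' before convolution. Squared magnitude is divided by the subject's mean
#' pre-stimulus beta power over retained trials, so the grand mean of the
#' normalized pre-stimulus power is 1 per subject.
#'
#' @param trials a single-channel [TrialSet-class].
#' @param ibf named numeric vector (per subject) or scalar IBF in Hz; must
#'   lie inside `config$ibf_band`.
#' @param config a [spectralConfig()].
#' @param crop if TRUE (default) restrict the series to the trial window;
#'   otherwise return the full pre-stimulus series.
#' @return a [BetaSeries-class].
#' @export
betaPowerSeries <- function(trials, ibf, config = spectralConfig(),
                            crop = TRUE) {
  time <- timeAxis(trials)
  subj <- subjectIds(trials)
  us <- unique(subj)
  if (length(ibf) == 1 && is.null(names(ibf)))
    ibf <- stats::setNames(rep(ibf, length(us)), us)
  if (!all(us %in% names(ibf))) stop("ibf missing for some subjects")
  bad <- ibf[us] < config$ibf_band[1] | ibf[us] > config$ibf_band[2]
  if (any(bad))
    stop("IBF outside ", config$ibf_band[1], "-", config$ibf_band[2],
         " Hz for subject(s): ", paste(us[bad], collapse = ", "))
  fs <- samplingRate(trials)
  pre <- which(time < 0)
  n_pre <- length(pre)
  eeg <- eegData(trials)
  n <- nTrials(trials)
  rawp <- matrix(0, n, n_pre)
  kernels <- lapply(us, function(s)
    morletKernel(ibf[[s]], fs, config$wavelet_cycles))
  names(kernels) <- us
  for (k in seq_len(n)) {
    x <- eeg[k, 1, pre]
    xm <- c(x, rev(x))                       # mirror at the stimulus
    y <- convSame(xm, kernels[[subj[k]]])
    rawp[k, ] <- Mod(y[seq_len(n_pre)])^2
  }
  norm <- vapply(us, function(s) mean(rawp[subj == s, , drop = FALSE]),
                 numeric(1))
  if (any(norm == 0))
    stop("zero normalization constant (no pre-stimulus beta power) for ",
         "subject(s): ", paste(us[norm == 0], collapse = ", "))
  names(norm) <- us
  normp <- rawp / norm[subj]
  t_pre <- time[pre]
  if (crop) {
    wi <- which(t_pre >= config$trial_window[1] - 1e-9 &
                t_pre <= config$trial_window[2] + 1e-9)
    normp <- normp[, wi, drop = FALSE]
    t_pre <- t_pre[wi]
  }
  BetaSeries(normp, t_pre, fs, subj, trialIds(trials), ibf[us], norm)
}
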