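## Synthetic EEG/EMG trial generator with ground-truth burst annotations.
## The generator provides the statistical structure the downstream analysis
## assumes: Poisson burst counts at a configurable rate, Hann-enveloped
## beta-frequency bursts on the motor channel over 1/f background, and a
## biphasic MEP whose log amplitude is a linear function of the injected
## burst metrics plus a per-subject random intercept.

## Fraction of a Hann envelope's support over which its *power* (squared
## envelope) exceeds half of the peak power. Used to translate a target
## half-maximum event duration into the envelope support.
hannPowerHalfFrac <- function() 1 - acos(1 - sqrt(2)) / pi

.default_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC5", "FC1", "FC2", "FC6",
    "T7", "C3", "Cz", "C4", "T8", "CP5", "CP1", "CP2", "CP6", "P7", "P3",
    "Pz", "P4", "P8", "PO9", "O1", "Oz", "O2", "PO10", "TP9", "TP10")
}

#' Configuration for the synthetic trial generator
#'
#' Defaults reproduce the statistical regime of pre-stimulus sensorimotor
#' recordings: bursts at 1.24 events/s with ~114 ms half-maximum duration,
#' individual beta frequencies inside 15-30 Hz, and Table-1-scale coupling
#' of burst metrics to log MEP amplitude.
#'
#' @param n_subjects,n_trials number of subjects and trials per subject.
#' @param fs sampling rate in Hz (default 5000).
#' @param epoch epoch limits in seconds relative to the stimulus at 0
#'   (default c(-3, 3)); must cover at least (-1, 0.05).
#' @param channels EEG channel names; must include C4, FC2, FC6, CP2, CP6.
#' @param ibf_range range (Hz) from which each subject's individual beta
#'   frequency is drawn (within 15-30).
#' @param burst_rate burst rate, events per second (default 1.24).
#' @param burst_duration_mean,burst_duration_sd mean and sd (s) of the
#'   half-maximum power duration of injected bursts (default 0.114).
#' @param burst_amplitude_meanlog,burst_amplitude_sdlog lognormal parameters
#'   of the burst envelope peak amplitude (uV).
#' @param burst_min_separation minimum distance between burst peaks (s);
#'   counts stay Poisson, placement is resampled to keep bursts resolvable.
#' @param background_sd sd (uV) of the 1/f background noise per channel.
#' @param emg_noise_sd sd (mV) of EMG baseline noise.
#' @param coupling named coefficients of the log-MEP model; names drawn from
#'   presence, number, amplitude, timing, meanpower.
#' @param subject_intercept_sd sd of per-subject random intercepts (log mV).
#' @param mep_noise_sd residual sd of log MEP amplitude.
#' @param artifact_fraction fraction of trials that receive an injected
#'   >50 uV pre-stimulus artifact.
#' @param trial_window pre-stimulus analysis window (s), default (-1, -0.05).
#' @param seed integer seed; fully determines the output.
#' @return a validated list of class `SynthConfig`.
#' @export
synthConfig <- function(n_subjects = 10, n_trials = 40, fs = 5000,
                        epoch = c(-3, 3), channels = .default_channels(),
                        ibf_range = c(18, 24),
                        burst_rate = 1.24,
                        burst_duration_mean = 0.114,
                        burst_duration_sd = 0.015,
                        burst_amplitude_meanlog = log(6),
                        burst_amplitude_sdlog = 0.25,
                        burst_min_separation = 0.15,
                        background_sd = 2,
                        emg_noise_sd = 0.005,
                        coupling = c(presence = 0.08, number = 0.05,
                                     amplitude = 0.01, timing = -0.10,
                                     meanpower = 0.07),
                        subject_intercept_sd = 0.2,
                        mep_noise_sd = 0.4,
                        artifact_fraction = 0,
                        trial_window = c(-1, -0.05),
                        seed = 1L) {
  cfg <- list(n_subjects = n_subjects, n_trials = n_trials, fs = fs,
              epoch = epoch, channels = channels, ibf_range = ibf_range,
              burst_rate = burst_rate,
              burst_duration_mean = burst_duration_mean,
              burst_duration_sd = burst_duration_sd,
              burst_amplitude_meanlog = burst_amplitude_meanlog,
              burst_amplitude_sdlog = burst_amplitude_sdlog,
              burst_min_separation = burst_min_separation,
              background_sd = background_sd, emg_noise_sd = emg_noise_sd,
              coupling = coupling,
              subject_intercept_sd = subject_intercept_sd,
              mep_noise_sd = mep_noise_sd,
              artifact_fraction = artifact_fraction,
              trial_window = trial_window, seed = as.integer(seed))
  known <- c("presence", "number", "amplitude", "timing", "meanpower")
  if (is.null(names(coupling)) || !all(names(coupling) %in% known))
    stop("configuration error: coupling names must be among ",
         paste(known, collapse = ", "))
  if (fs <= 0) stop("fs must be positive")
  if (epoch[1] > -1 + 1e-9 || epoch[2] < 0.05 - 1e-9)
    stop("epoch must cover at least (-1, 0.05) s")
  if (ibf_range[1] < 15 || ibf_range[2] > 30 || ibf_range[1] > ibf_range[2])
    stop("ibf_range must lie within 15-30 Hz")
  if (burst_rate < 0) stop("burst_rate must be non-negative")
  if (burst_duration_mean < 1.5 / ibf_range[1])
    stop("burst_duration_mean must be at least 1.5 cycles at the lowest IBF")
  if (artifact_fraction < 0 || artifact_fraction > 1)
    stop("artifact_fraction must lie in [0, 1]")
  req <- c("C4", "FC2", "FC6", "CP2", "CP6")
  if (!all(req %in% channels))
    stop("channels must include ", paste(req, collapse = ", "))
  class(cfg) <- "SynthConfig"
  cfg
}

## Draw burst events for one trial: Poisson count over the placement span,
## peaks resampled (up to 100 tries) to respect the minimum separation,
## lognormal peak amplitudes, truncated-normal half-max durations.
sampleTrialEvents <- function(cfg, span, min_dur) {
  len <- diff(span)
  n <- stats::rpois(1, cfg$burst_rate * len)
  if (n == 0)
    return(data.frame(peak = numeric(), amplitude = numeric(),
                      halfdur = numeric()))
  peaks <- numeric(n)
  for (i in seq_len(n)) {
    for (tries in 1:100) {
      p <- stats::runif(1, span[1], span[2])
      if (i == 1 || all(abs(p - peaks[seq_len(i - 1)]) >= cfg$burst_min_separation))
        break
    }
    peaks[i] <- p
  }
  peaks <- sort(peaks)
  amp <- stats::rlnorm(n, cfg$burst_amplitude_meanlog, cfg$burst_amplitude_sdlog)
  hd <- stats::rnorm(n, cfg$burst_duration_mean, cfg$burst_duration_sd)
  hd <- pmax(hd, min_dur * 1.05)
  data.frame(peak = peaks, amplitude = amp, halfdur = hd)
}

## Ground-truth trial metrics from an injected event table (events whose
## peak falls inside the analysis window), mirroring the events module's
## conventions: timing is the positive latency of the last event's peak.
truthMetrics <- function(ev, window) {
  inw <- ev$peak >= window[1] & ev$peak <= window[2]
  e <- ev[inw, , drop = FALSE]
  n <- nrow(e)
  if (n == 0) {
    return(list(event_present = 0L, n_events = 0L, last_duration_s = NA_real_,
                last_amplitude = NA_real_, last_timing_s = NA_real_,
                mean_power = 0))
  }
  last <- which.max(e$peak)
  list(event_present = 1L, n_events = n,
       last_duration_s = e$halfdur[last],
       last_amplitude = e$amplitude[last],
       last_timing_s = -e$peak[last],
       mean_power = sum(0.5 * e$amplitude^2 * e$halfdur) / diff(window))
}

couplingPredictor <- function(coupling, m) {
  cc <- function(nm) if (nm %in% names(coupling)) coupling[[nm]] else 0
  pres <- m$event_present
  cc("presence") * pres + cc("number") * m$n_events +
    pres * (cc("amplitude") * ifelse(pres == 1, m$last_amplitude, 0) +
            cc("timing") * ifelse(pres == 1, m$last_timing_s, 0)) +
    cc("meanpower") * m$mean_power
}

#' Normalized biphasic MEP template
#'
#' A fixed biphasic waveform supported on the +20 to +40 ms post-stimulus
#' window, scaled so its peak-to-peak amplitude on the supplied time grid is
#' exactly 1 (mV). Each trial's EMG adds this template times the trial's MEP
#' amplitude.
#'
#' @param time epoch time axis (s).
#' @param window MEP window (s), default c(0.020, 0.040).
#' @return numeric vector along `time`.
#' @export
mepTemplate <- function(time, window = c(0.020, 0.040)) {
  tpl <- numeric(length(time))
  idx <- which(time >= window[1] & time <= window[2])
  u <- (time[idx] - window[1]) / diff(window)
  tpl[idx] <- sin(2 * pi * u) * sin(pi * u)^2
  p2p <- max(tpl) - min(tpl)
  if (p2p > 0) tpl <- tpl / p2p
  tpl
}

#' Simulate an epoched EEG/EMG trial set with ground truth
#'
#' Generates `n_subjects * n_trials` stimulus-locked trials. Channel C4
#' carries Hann-enveloped bursts at the subject's individual beta frequency
#' over 1/f background noise; all other channels are background only. The
#' EMG epoch contains one biphasic MEP in the +20 to +40 ms window whose log
#' peak-to-peak amplitude is `subject intercept + sum(coupling * metric) +
#' noise`, with metrics computed from the injected (ground-truth) events.
#'
#' @param config a [synthConfig()] object.
#' @return a list with elements `trials` (a [TrialSet-class]) and `truth`
#'   (list of `subjects`, `events`, `metrics` data frames plus the coupling
#'   vector used).
#' @export
simulateTrialSet <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  withSeed(config$seed, {
    fs <- config$fs
    time <- seq(config$epoch[1], config$epoch[2], by = 1 / fs)
    nt <- length(time)
    nch <- length(config$channels)
    nS <- config$n_subjects
    nT <- config$n_trials
    n <- nS * nT
    frac <- hannPowerHalfFrac()
    span <- c(config$epoch[1] + 0.3, -0.02)

    subjects <- data.frame(
      subject = sprintf("s%02d", seq_len(nS)),
      ibf = round(stats::runif(nS, config$ibf_range[1], config$ibf_range[2])),
      intercept = stats::rnorm(nS, 0, config$subject_intercept_sd))

    eeg <- array(0, dim = c(n, nch, nt))
    emg <- matrix(0, n, nt)
    tpl <- mepTemplate(time)
    c4 <- match("C4", config$channels)
    ev_list <- vector("list", n)
    met_list <- vector("list", n)
    subj_of <- rep(subjects$subject, each = nT)
    trial_id <- sprintf("%s_t%03d", subj_of, rep(seq_len(nT), nS))

    for (k in seq_len(n)) {
      s <- (k - 1) %/% nT + 1
      ibf <- subjects$ibf[s]
      min_dur <- 1.5 / ibf
      ev <- sampleTrialEvents(config, span, min_dur)
      for (ch in seq_len(nch))
        eeg[k, ch, ] <- pinkNoise(nt, sd = config$background_sd)
      if (nrow(ev)) {
        for (j in seq_len(nrow(ev))) {
          support <- ev$halfdur[j] / frac
          sel <- which(abs(time - ev$peak[j]) <= support / 2)
          if (length(sel)) {
            env <- cos(pi * (time[sel] - ev$peak[j]) / support)^2
            phi <- stats::runif(1, 0, 2 * pi)
            eeg[k, c4, sel] <- eeg[k, c4, sel] +
              ev$amplitude[j] * env * cos(2 * pi * ibf * (time[sel] - ev$peak[j]) + phi)
          }
        }
      }
      m <- truthMetrics(ev, config$trial_window)
      lp <- subjects$intercept[s] + couplingPredictor(config$coupling, m)
      log_mep <- lp + stats::rnorm(1, 0, config$mep_noise_sd)
      emg[k, ] <- stats::rnorm(nt, 0, config$emg_noise_sd) + exp(log_mep) * tpl
      m$log_mep <- log_mep
      met_list[[k]] <- m
      if (nrow(ev)) {
        ev$subject <- subjects$subject[s]
        ev$trial <- trial_id[k]
        ev$onset <- ev$peak - (ev$halfdur / frac) / 2
        ev$offset <- ev$peak + (ev$halfdur / frac) / 2
        ev_list[[k]] <- ev
      }
    }
    metrics <- cbind(data.frame(subject = subj_of, trial = trial_id),
                     do.call(rbind, lapply(met_list, as.data.frame)))
    events <- do.call(rbind, ev_list)
    trials <- TrialSet(eeg, emg, fs, time, config$channels, subj_of, trial_id)
    out <- list(trials = trials,
                truth = list(subjects = subjects, events = events,
                             metrics = metrics, coupling = config$coupling))
    if (config$artifact_fraction > 0) {
      art <- injectArtifacts(trials, config$artifact_fraction,
                             seed = config$seed + 1000L)
      out$trials <- art$trials
      out$truth$contaminated <- art$contaminated
    }
    out
  })
}

#' Simulate ground-truth trial metrics without signals
#'
#' Fast path for statistical calibration: draws the same per-trial burst
#' statistics as [simulateTrialSet()] (Poisson counts with minimum-separation
#' placement inside the analysis window, lognormal amplitudes, truncated
#' normal durations) and generates log MEP amplitudes from the coupling
#' model directly, skipping signal synthesis. Amplitude and power metrics
#' are in normalized-power units (burst peak power ~ lognormal around 4,
#' background mean power around 0.85).
#'
#' @param config a [synthConfig()] object (signal-level fields are ignored).
#' @return a data frame with one row per trial: subject, trial, the six beta
#'   metrics, and log_mep; subject intercepts in `attr(, "subjects")`.
#' @export
simulateTrialMetrics <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  withSeed(config$seed, {
    nS <- config$n_subjects
    nT <- config$n_trials
    win <- config$trial_window
    subjects <- data.frame(
      subject = sprintf("s%02d", seq_len(nS)),
      ibf = round(stats::runif(nS, config$ibf_range[1], config$ibf_range[2])),
      intercept = stats::rnorm(nS, 0, config$subject_intercept_sd))
    N <- nS * nT
    len <- diff(win)
    s_of <- rep(seq_len(nS), each = nT)
    n_ev <- stats::rpois(N, config$burst_rate * len)
    pres <- as.integer(n_ev > 0)
    last_dur <- last_amp <- timing <- rep(NA_real_, N)
    contrib <- numeric(N)
    for (k in which(n_ev > 0)) {
      n <- n_ev[k]
      peaks <- numeric(n)
      for (i in seq_len(n)) {
        for (tries in 1:100) {
          p <- stats::runif(1, win[1], win[2])
          if (i == 1 ||
              all(abs(p - peaks[seq_len(i - 1)]) >= config$burst_min_separation))
            break
        }
        peaks[i] <- p
      }
      amp <- stats::rlnorm(n, log(4), config$burst_amplitude_sdlog)
      hd <- pmax(stats::rnorm(n, config$burst_duration_mean,
                              config$burst_duration_sd),
                 1.05 * 1.5 / subjects$ibf[s_of[k]])
      last <- which.max(peaks)
      last_dur[k] <- hd[last]
      last_amp[k] <- amp[last]
      timing[k] <- -peaks[last]
      contrib[k] <- sum(amp * hd) / len
    }
    ## normalized-power metric: background level plus burst contribution
    mean_power <- pmax(0.05, stats::rnorm(N, 0.85, 0.12)) + contrib
    m <- list(event_present = pres, n_events = n_ev,
              last_duration_s = last_dur, last_amplitude = last_amp,
              last_timing_s = timing, mean_power = mean_power)
    lp <- subjects$intercept[s_of] + couplingPredictor(config$coupling, m)
    out <- data.frame(subject = subjects$subject[s_of],
                      trial = sprintf("%s_t%03d", subjects$subject[s_of],
                                      rep(seq_len(nT), nS)),
                      event_present = pres, n_events = n_ev,
                      last_duration_s = last_dur, last_amplitude = last_amp,
                      last_timing_s = timing, mean_power = mean_power,
                      log_mep = lp + stats::rnorm(N, 0, config$mep_noise_sd),
                      stringsAsFactors = FALSE)
    out$excluded <- FALSE
    out$exclusion_reason <- ""
    attr(out, "subjects") <- subjects
    out
  })
}

#' Simulate normalized beta-power series with injected bursts
#'
#' Generates trial-window power series directly (background level plus
#' Hann-squared burst power envelopes), bypassing the wavelet stage. Used to
#' exercise the event detector against known injections.
#'
#' @param n_trials number of trials.
#' @param fs sampling rate of the power series (Hz).
#' @param window analysis window (s), default c(-1, -0.05).
#' @param burst_rate events per second (default 1.24).
#' @param burst_duration_mean,burst_duration_sd half-max power duration (s).
#' @param amp_meanlog,amp_sdlog lognormal parameters of burst peak power
#'   (normalized units).
#' @param bg_level,bg_noise background power level and fluctuation scale.
#' @param min_separation minimum burst peak separation (s).
#' @param ibf nominal beta frequency (Hz) for the minimum-duration rule.
#' @param subject subject label.
#' @param seed integer seed.
#' @return list with `series` (a [BetaSeries-class]) and `truth` (data frame
#'   of injected events: trial, peak, amplitude, halfdur, onset, offset).
#' @export
simulateBetaSeries <- function(n_trials = 100, fs = 1000,
                               window = c(-1, -0.05), burst_rate = 1.24,
                               burst_duration_mean = 0.114,
                               burst_duration_sd = 0.015,
                               amp_meanlog = log(4), amp_sdlog = 0.25,
                               bg_level = 0.3, bg_noise = 0.05,
                               min_separation = 0.15, ibf = 20,
                               subject = "s01", seed = 1L) {
  withSeed(seed, {
    cfg <- list(burst_rate = burst_rate, burst_min_separation = min_separation,
                burst_amplitude_meanlog = amp_meanlog,
                burst_amplitude_sdlog = amp_sdlog,
                burst_duration_mean = burst_duration_mean,
                burst_duration_sd = burst_duration_sd)
    frac <- hannPowerHalfFrac()
    time <- seq(window[1], window[2], by = 1 / fs)
    nt <- length(time)
    power <- matrix(0, n_trials, nt)
    ev_list <- vector("list", n_trials)
    min_dur <- 1.5 / ibf
    for (k in seq_len(n_trials)) {
      ev <- sampleTrialEvents(cfg, window, min_dur)
      p <- bg_level + abs(stats::rnorm(nt, 0, bg_noise))
      if (nrow(ev)) {
        for (j in seq_len(nrow(ev))) {
          support <- ev$halfdur[j] / frac
          sel <- which(abs(time - ev$peak[j]) <= support / 2)
          if (length(sel))
            p[sel] <- p[sel] +
              ev$amplitude[j] * cos(pi * (time[sel] - ev$peak[j]) / support)^4
        }
        ev$trial <- sprintf("t%04d", k)
        ev$onset <- ev$peak - (ev$halfdur / frac) / 2
        ev$offset <- ev$peak + (ev$halfdur / frac) / 2
        ev_list[[k]] <- ev
      }
      power[k, ] <- p
    }
    ibf_v <- stats::setNames(ibf, subject)
    series <- BetaSeries(power, time, fs, rep(subject, n_trials),
                         sprintf("t%04d", seq_len(n_trials)), ibf_v,
                         stats::setNames(1, subject))
    list(series = series, truth = do.call(rbind, ev_list))
  })
}

#' Inject high-amplitude pre-stimulus artifacts
#'
#' Adds a >50 uV Gaussian transient to channel C4 within the 1 s
#' pre-stimulus window of a deterministic fraction of trials (count =
#' `round(fraction * nTrials)`), to exercise the amplitude rejection rule.
#'
#' @param trials a [TrialSet-class].
#' @param fraction fraction of trials to contaminate, in [0, 1].
#' @param seed integer seed.
#' @param amplitude_uv artifact peak amplitude (default 80 uV).
#' @return list with `trials` (modified TrialSet) and `contaminated`
#'   (character vector of affected trial ids).
#' @export
injectArtifacts <- function(trials, fraction, seed = 1L, amplitude_uv = 80) {
  stopifnot(fraction >= 0, fraction <= 1)
  n <- nTrials(trials)
  n_sel <- round(fraction * n)
  if (n_sel == 0) return(list(trials = trials, contaminated = character()))
  withSeed(seed, {
    sel <- sort(sample.int(n, n_sel))
    time <- timeAxis(trials)
    ch <- match("C4", channelNames(trials))
    if (is.na(ch)) ch <- 1L
    eeg <- eegData(trials)
    for (k in sel) {
      t0 <- stats::runif(1, -0.9, -0.1)
      eeg[k, ch, ] <- eeg[k, ch, ] +
        amplitude_uv * exp(-(time - t0)^2 / (2 * 0.005^2))
    }
    out <- TrialSet(eeg, emgData(trials), samplingRate(trials), time,
                    channelNames(trials), subjectIds(trials), trialIds(trials))
    list(trials = out, contaminated = trialIds(trials)[sel])
  })
}
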