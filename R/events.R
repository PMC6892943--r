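## Beta event detection and per-trial morphology metrics.

#' Per-subject percentile power threshold
#'
#' Empirical percentile of the pooled normalized-power samples across all of
#' a subject's retained trial windows (linear interpolation between order
#' statistics, `stats::quantile` type 7).
#'
#' @param series a [BetaSeries-class].
#' @param percentile percentile in (0, 100); the event-definition search
#'   uses 50-98, with 75 and 82 as the standard choices.
#' @return named numeric vector of thresholds, one per subject.
#' @export
thresholdValue <- function(series, percentile) {
  stopifnot(percentile > 0, percentile < 100)
  subj <- subjectIds(series)
  pw <- powerMatrix(series)
  if (!length(pw)) stop("empty sample pool")
  us <- unique(subj)
  out <- vapply(us, function(s)
    stats::quantile(pw[subj == s, , drop = FALSE], percentile / 100,
                    type = 7, names = FALSE), numeric(1))
  stats::setNames(out, us)
}

#' Detect beta events in one power series
#'
#' Events are maximal runs of samples strictly above the threshold that last
#' at least `min_cycles / ibf` seconds. For each event the maximum
#' amplitude, peak time, and half-maximum duration (total time the run's
#' power exceeds half its maximum) are extracted. A run touching a window
#' edge counts as an event only if its power maximum is interior (power is
#' declining at the edge); such edge events are flagged and their duration
#' is estimated as twice the onset-to-peak time (stimulus-side edge) or
#' twice the peak-to-offset time (window-start edge).
#'
#' @param power numeric vector of normalized power (finite, >= 0).
#' @param time time axis (s), same length.
#' @param threshold power threshold (> 0).
#' @param ibf beta frequency (Hz) defining the minimum duration.
#' @param min_cycles minimum event length in cycles (default 1.5).
#' @return data frame with columns onset_s, offset_s, peak_time_s,
#'   max_amplitude, duration_s, is_edge (offset is exclusive: last
#'   supra-threshold sample time + 1/fs).
#' @export
detectEvents <- function(power, time, threshold, ibf, min_cycles = 1.5) {
  if (any(!is.finite(power))) stop("non-finite power values")
  stopifnot(length(power) == length(time), threshold > 0)
  dt <- time[2] - time[1]
  above <- power > threshold
  if (!any(above)) return(emptyEvents())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  min_dur <- min_cycles / ibf
  n_t <- length(power)
  out <- vector("list", length(runs))
  for (q in seq_along(runs)) {
    i <- starts[runs[q]]
    j <- ends[runs[q]]
    run_len <- (j - i + 1) * dt
    if (run_len < min_dur) next
    prof <- power[i:j]
    pk <- i + which.max(prof) - 1
    edge_left <- i == 1
    edge_right <- j == n_t
    if ((edge_left || edge_right) && (pk == 1 || pk == n_t)) next
    is_edge <- edge_left || edge_right
    if (is_edge) {
      dur <- if (edge_right) 2 * (time[pk] - time[i])
             else 2 * (time[j] + dt - time[pk])
    } else {
      dur <- sum(prof > max(prof) / 2) * dt
    }
    out[[q]] <- data.frame(onset_s = time[i], offset_s = time[j] + dt,
                           peak_time_s = time[pk],
                           max_amplitude = power[pk],
                           duration_s = dur, is_edge = is_edge)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(emptyEvents())
  do.call(rbind, out)
}

emptyEvents <- function() {
  data.frame(onset_s = numeric(), offset_s = numeric(),
             peak_time_s = numeric(), max_amplitude = numeric(),
             duration_s = numeric(), is_edge = logical())
}

#' Detect events in every trial of a BetaSeries
#'
#' @param series a [BetaSeries-class].
#' @param percentile percentile defining the per-subject threshold
#'   (default 75); ignored if `threshold` is given.
#' @param threshold optional explicit threshold(s): scalar or named per
#'   subject.
#' @param min_cycles minimum event length in cycles.
#' @return data frame of events with subject and trial columns; per-subject
#'   thresholds in `attr(, "thresholds")`.
#' @export
detectAllEvents <- function(series, percentile = 75, threshold = NULL,
                            min_cycles = 1.5) {
  subj <- subjectIds(series)
  us <- unique(subj)
  if (is.null(threshold)) {
    thr <- thresholdValue(series, percentile)
  } else if (length(threshold) == 1 && is.null(names(threshold))) {
    thr <- stats::setNames(rep(threshold, length(us)), us)
  } else thr <- threshold
  pw <- powerMatrix(series)
  time <- timeAxis(series)
  ibf <- subjectIBF(series)
  out <- vector("list", nrow(pw))
  for (k in seq_len(nrow(pw))) {
    ev <- detectEvents(pw[k, ], time, thr[[subj[k]]], ibf[[subj[k]]],
                       min_cycles)
    if (nrow(ev)) {
      ev <- cbind(data.frame(subject = subj[k],
                             trial = trialIds(series)[k]), ev)
      out[[k]] <- ev
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out)) do.call(rbind, out) else
    cbind(data.frame(subject = character(), trial = character()),
          emptyEvents())
  attr(res, "thresholds") <- thr
  res
}

#' Half-maximum duration of an event power profile
#'
#' Total time the profile exceeds half of its maximum (FWHM-style width;
#' for multi-lobed profiles, all time above half-max counts).
#'
#' @param profile numeric power profile.
#' @param dt sample step (s).
#' @return duration in seconds.
#' @export
eventDuration <- function(profile, dt) {
  stopifnot(length(profile) >= 1, dt > 0)
  sum(profile > max(profile) / 2) * dt
}

#' Per-trial beta metrics
#'
#' Summarizes detected events into one row per trial: event presence and
#' count, the last (most recent before the stimulus) event's duration,
#' maximum amplitude and timing, and the mean normalized power over the
#' trial window (computed for every trial, events or not). Timing is the
#' positive latency of the last event's power peak before the stimulus.
#'
#' @param series a [BetaSeries-class].
#' @param events event table from [detectAllEvents()].
#' @param meps optional MEP record table (from [extractMEPs()]); joins
#'   log_mep and exclusion flags by trial.
#' @return TrialMetrics data frame: subject, trial, event_present, n_events,
#'   last_duration_s, last_amplitude, last_timing_s, mean_power, log_mep,
#'   excluded, exclusion_reason.
#' @export
summarizeTrials <- function(series, events, meps = NULL) {
  subj <- subjectIds(series)
  tid <- trialIds(series)
  mp <- rowMeans(powerMatrix(series))
  n <- length(tid)
  out <- data.frame(subject = subj, trial = tid,
                    event_present = 0L, n_events = 0L,
                    last_duration_s = NA_real_, last_amplitude = NA_real_,
                    last_timing_s = NA_real_, mean_power = mp,
                    log_mep = NA_real_, excluded = FALSE,
                    exclusion_reason = "", stringsAsFactors = FALSE)
  if (nrow(events)) {
    sp <- split(events, events$trial)
    for (id in names(sp)) {
      k <- match(id, tid)
      if (is.na(k)) next
      ev <- sp[[id]]
      out$n_events[k] <- nrow(ev)
      out$event_present[k] <- 1L
      last <- which.max(ev$peak_time_s)
      out$last_duration_s[k] <- ev$duration_s[last]
      out$last_amplitude[k] <- ev$max_amplitude[last]
      out$last_timing_s[k] <- -ev$peak_time_s[last]
    }
  }
  if (!is.null(meps)) {
    mi <- match(out$trial, meps$trial)
    out$log_mep <- meps$log_amplitude[mi]
    out$excluded <- out$excluded | (!is.na(mi) & meps$excluded[mi])
    out$exclusion_reason <- ifelse(!is.na(mi), meps$reason[mi], "")
    out$excluded[is.na(mi)] <- TRUE
    out$exclusion_reason[is.na(mi)] <- "no MEP record"
  }
  out
}

#' Empirical event-definition threshold
#'
#' For every candidate percentile, computes per subject the Pearson
#' correlation across trials between the fraction of window samples falling
#' inside detected events and the trial's mean beta power, and returns the
#' percentile at which the subject-mean correlation curve is maximal.
#' Subjects with an undefined correlation (zero variance) at a given
#' percentile are excluded from that percentile's mean with a warning.
#'
#' @param series a [BetaSeries-class] with >= 2 subjects, >= 3 trials each.
#' @param range percentile search range, default c(50, 98).
#' @param step percentile step (default 1).
#' @param min_cycles minimum event length in cycles.
#' @return list with `percentile` (argmax) and `curve` (data frame:
#'   percentile, mean_r, n_subjects).
#' @export
empiricalThreshold <- function(series, range = c(50, 98), step = 1,
                               min_cycles = 1.5) {
  subj <- subjectIds(series)
  us <- unique(subj)
  tab <- table(subj)
  if (length(us) < 2) stop("empirical threshold needs >= 2 subjects")
  if (any(tab < 3)) stop("empirical threshold needs >= 3 trials per subject")
  pcts <- seq(range[1], range[2], by = step)
  pw <- powerMatrix(series)
  time <- timeAxis(series)
  ibf <- subjectIBF(series)
  mp <- rowMeans(pw)
  n_samp <- ncol(pw)
  dt <- time[2] - time[1]
  curve <- data.frame(percentile = pcts, mean_r = NA_real_, n_subjects = 0L)
  dropped <- FALSE
  for (pi in seq_along(pcts)) {
    thr <- thresholdValue(series, pcts[pi])
    rs <- vapply(us, function(s) {
      rows <- which(subj == s)
      frac <- vapply(rows, function(k) {
        ev <- detectEvents(pw[k, ], time, thr[[s]], ibf[[s]], min_cycles)
        if (!nrow(ev)) return(0)
        sum(ev$offset_s - ev$onset_s) / (n_samp * dt)
      }, numeric(1))
      if (stats::sd(frac) == 0 || stats::sd(mp[rows]) == 0) return(NA_real_)
      stats::cor(frac, mp[rows])
    }, numeric(1))
    if (anyNA(rs)) dropped <- TRUE
    curve$mean_r[pi] <- if (all(is.na(rs))) NA_real_ else mean(rs, na.rm = TRUE)
    curve$n_subjects[pi] <- sum(!is.na(rs))
  }
  if (dropped)
    warning("some subjects had undefined correlations at one or more ",
            "percentiles and were excluded there")
  if (all(is.na(curve$mean_r)))
    stop("correlation curve undefined for all percentiles ",
         "(no between-trial variance)")
  best <- curve$percentile[which.max(curve$mean_r)]
  list(percentile = best, curve = curve)
}
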