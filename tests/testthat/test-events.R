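mk_series <- function(power, fs = 1000, t0 = -1,
                      subject = rep("s01", nrow(power)), ibf = 20) {
  time <- seq(t0, by = 1 / fs, length.out = ncol(power))
  BetaSeries(power, time, fs, subject,
             sprintf("t%03d", seq_len(nrow(power))),
             setNames(rep(ibf, length(unique(subject))), unique(subject)),
             setNames(rep(1, length(unique(subject))), unique(subject)))
}

test_that("percentile thresholds use linear interpolation over the subject pool", {
  ## constant series: any percentile returns the constant
  s1 <- mk_series(matrix(2.5, 3, 50))
  expect_equal(unname(thresholdValue(s1, 60)), 2.5)
  ## pool 1..100: 75th percentile is 75.25 under the type-7 convention
  s2 <- mk_series(matrix(1:100, 1, 100))
  expect_equal(unname(thresholdValue(s2, 75)), 75.25)
  ## monotone in the percentile
  set.seed(2)
  s3 <- mk_series(matrix(abs(rnorm(500)), 5, 100))
  expect_gte(unname(thresholdValue(s3, 82)), unname(thresholdValue(s3, 75)))
})

test_that("event detection matches injections and discards short runs", {
  fs <- 1000
  time <- seq(-1, -0.05, by = 1 / fs)
  ## sub-threshold everywhere -> no events
  expect_identical(nrow(detectEvents(rep(0.5, length(time)), time, 1, 20)), 0L)
  ## two 150 ms Hann bursts at -0.7 and -0.3 s
  burst <- function(c0, w) {
    env <- numeric(length(time))
    sel <- abs(time - c0) <= w / 2
    env[sel] <- cos(pi * (time[sel] - c0) / w)^2
    env
  }
  p <- 0.2 + 3 * burst(-0.7, 0.15) + 3 * burst(-0.3, 0.15)
  ev <- detectEvents(p, time, 1, 20)
  expect_identical(nrow(ev), 2L)
  expect_lt(abs(ev$peak_time_s[1] + 0.7), 0.010)
  expect_lt(abs(ev$peak_time_s[2] + 0.3), 0.010)
  ## agreement with the brute-force oracle
  expect_equal(ev, oracleDetect(p, time, 1, 20), tolerance = 1e-12)
  ## a 60 ms run is shorter than 1.5 cycles at 20 Hz (75 ms) and is dropped
  p2 <- rep(0.2, length(time))
  run <- which(time >= -0.53 & time < -0.47)[1:60]
  p2[run] <- 2 + sin(seq(0, pi, length.out = 60))
  expect_identical(nrow(detectEvents(p2, time, 1, 20)), 0L)
  ## non-finite power is an error
  p2[3] <- NA
  expect_error(detectEvents(p2, time, 1, 20), "non-finite")
})

test_that("half-maximum duration has its closed forms", {
  fs <- 1000; dt <- 1 / fs
  ## rectangular pulse of width w -> w
  expect_equal(eventDuration(rep(2, 80), dt), 0.080)
  ## symmetric triangle with base b -> b/2
  tri <- c(seq(0, 1, length.out = 101), seq(1, 0, length.out = 101)[-1])
  b <- length(tri) * dt
  expect_lt(abs(eventDuration(tri, dt) - b / 2), 2 * dt)
  ## sampled Gaussian, sd sigma -> 2.355 sigma within one sample step
  sigma <- 0.04
  t <- seq(-0.5, 0.5, by = dt)
  g <- exp(-t^2 / (2 * sigma^2))
  expect_lt(abs(eventDuration(g, dt) - 2 * sqrt(2 * log(2)) * sigma), dt)
})

test_that("edge runs follow the declining-power rule and doubled duration", {
  fs <- 1000
  time <- seq(-1, -0.05, by = 1 / fs)
  n <- length(time)
  ## run touches the stimulus-side edge, maximum interior:
  ## event, edge-flagged, duration = 2 * (peak - onset)
  p <- rep(0.2, n)
  tail_idx <- which(time >= -0.25)
  p[tail_idx] <- 0.2 + 3 * exp(-(time[tail_idx] + 0.10)^2 / (2 * 0.05^2))
  ev <- detectEvents(p, time, 1, 20)
  expect_identical(nrow(ev), 1L)
  expect_true(ev$is_edge)
  expect_equal(ev$duration_s, 2 * (ev$peak_time_s - ev$onset_s))
  ## monotonically rising to the edge: maximum at the boundary, not an event
  p2 <- rep(0.2, n)
  p2[tail_idx] <- seq(1.5, 4, length.out = length(tail_idx))
  expect_identical(nrow(detectEvents(p2, time, 1, 20)), 0L)
  ## window-start edge uses the mirrored rule: 2 * (offset - peak)
  p3 <- rep(0.2, n)
  head_idx <- which(time <= -0.75)
  p3[head_idx] <- 0.2 + 3 * exp(-(time[head_idx] + 0.93)^2 / (2 * 0.05^2))
  ev3 <- detectEvents(p3, time, 1, 20)
  expect_identical(nrow(ev3), 1L)
  expect_true(ev3$is_edge)
  expect_equal(ev3$duration_s, 2 * (ev3$offset_s - ev3$peak_time_s))
})

test_that("trial summaries carry last-event metrics and mean power", {
  fs <- 500
  nt <- 476
  set.seed(4)
  ## trial 1: two bursts; trial 2: flat
  time <- seq(-1, by = 1 / fs, length.out = nt)
  mkb <- function(c0) 3 * exp(-(time - c0)^2 / (2 * 0.03^2))
  pw <- rbind(0.3 + mkb(-0.6) + mkb(-0.2), rep(0.3, nt))
  ser <- mk_series(pw, fs = fs)
  ev <- detectAllEvents(ser, threshold = 1)
  tm <- summarizeTrials(ser, ev)
  expect_equal(tm$event_present, c(1L, 0L))
  expect_equal(tm$n_events, c(2L, 0L))
  expect_true(is.na(tm$last_duration_s[2]))
  expect_equal(tm$last_timing_s[1], 0.2, tolerance = 0.01)
  expect_equal(tm$mean_power, rowMeans(pw))
  ## joining MEP records unions exclusions and fills log_mep
  meps <- data.frame(trial = tm$trial, log_amplitude = c(0.5, -0.2),
                     excluded = c(FALSE, TRUE), reason = c("", "prestim_emg"))
  tm2 <- summarizeTrials(ser, ev, meps)
  expect_equal(tm2$log_mep, c(0.5, -0.2))
  expect_equal(tm2$excluded, c(FALSE, TRUE))
  expect_equal(tm2$exclusion_reason[2], "prestim_emg")
})

test_that("detector equals the oracle on random series at both thresholds", {
  set.seed(31)
  for (i in 1:200) {
    s <- randomPowerSeries()
    for (pct in c(75, 82)) {
      thr <- unname(quantile(s$power, pct / 100, type = 7))
      got <- detectEvents(s$power, s$time, thr, 20)
      want <- oracleDetect(s$power, s$time, thr, 20)
      expect_identical(nrow(got), nrow(want))
      if (nrow(got)) expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("events nest and supra-threshold time shrinks as the threshold rises", {
  ## note: event *counts* need not fall monotonically with the threshold -
  ## a rising threshold can split one broad run into two - but every run at
  ## a higher threshold is contained in a run at a lower one, and the total
  ## supra-threshold time can only shrink
  set.seed(14)
  for (i in 1:25) {
    s <- randomPowerSeries()
    thr_seq <- quantile(s$power, c(0.5, 0.65, 0.8, 0.9), type = 7)
    ## every supra-threshold sample at a higher threshold is supra-threshold
    ## at a lower one, so each detected run sits inside one lower-threshold
    ## run of the raw indicator
    evs <- lapply(thr_seq, function(th)
      detectEvents(s$power, s$time, th, 20, min_cycles = 1e-9))
    for (q in 2:length(evs)) {
      hi <- evs[[q]]
      if (!nrow(hi)) next
      lo_above <- s$power > thr_seq[q - 1]
      for (r in seq_len(nrow(hi))) {
        idx <- which(s$time >= hi$onset_s[r] - 1e-12 &
                     s$time < hi$offset_s[r] - 1e-12)
        expect_true(all(lo_above[idx]))
      }
    }
    tt <- vapply(thr_seq, function(th) {
      ev <- detectEvents(s$power, s$time, th, 20)
      if (nrow(ev)) sum(ev$offset_s - ev$onset_s) else 0
    }, numeric(1))
    expect_true(all(diff(tt) <= 1e-12))
  }
})

test_that("well-separated injected bursts are recovered perfectly", {
  sb <- simulateBetaSeries(n_trials = 400, fs = 1000, min_separation = 0.4,
                           bg_level = 0.02, bg_noise = 0.005, seed = 44)
  ev <- detectAllEvents(sb$series, threshold = 0.5)
  truth <- sb$truth
  ## condition on trials whose injections are genuinely resolvable: pairwise
  ## peak separation >= 0.35 s (Poisson crowding can defeat the soft-core
  ## placement) and supports clear of the window edges
  sep_ok <- vapply(unique(truth$trial), function(id) {
    p <- sort(truth$peak[truth$trial == id])
    o <- truth[truth$trial == id, ]
    (length(p) < 2 || min(diff(p)) >= 0.35) &&
      all(o$onset > -1 + 0.01) && all(o$offset < -0.05 - 0.01)
  }, logical(1))
  ids <- unique(truth$trial)[sep_ok]
  expect_gt(length(ids), 50)
  n_checked <- 0
  for (id in ids) {
    tr_ev <- ev[ev$trial == id, ]
    tr_gt <- truth[truth$trial == id, ]
    ## recall and precision 1 on resolvable trials
    expect_identical(nrow(tr_ev), nrow(tr_gt))
    if (nrow(tr_ev) != nrow(tr_gt)) next
    o1 <- order(tr_ev$peak_time_s); o2 <- order(tr_gt$peak)
    expect_true(all(abs(tr_ev$peak_time_s[o1] - tr_gt$peak[o2]) < 0.01))
    ## recovered half-max durations within 2 sample steps of the envelope's
    expect_true(all(abs(tr_ev$duration_s[o1] - tr_gt$halfdur[o2]) <
                    2 / 1000 + 1e-9))
    n_checked <- n_checked + nrow(tr_gt)
  }
  expect_gt(n_checked, 50)
})

test_that("the empirical threshold search matches a brute-force curve", {
  sb <- simulateBetaSeries(n_trials = 40, fs = 250, seed = 9)
  ## split the one simulated pool into three pseudo-subjects
  pw <- powerMatrix(sb$series)
  subj <- rep(c("a", "b", "c"), length.out = nrow(pw))
  ser <- mk_series(pw, fs = 250, subject = subj)
  res <- empiricalThreshold(ser, range = c(50, 98), step = 4)
  ## oracle: exhaustive evaluation with the brute-force detector
  time <- timeAxis(ser)
  mp <- rowMeans(pw)
  curve <- vapply(seq(50, 98, by = 4), function(pct) {
    rs <- vapply(unique(subj), function(s) {
      rows <- which(subj == s)
      thr <- unname(quantile(pw[rows, ], pct / 100, type = 7))
      frac <- vapply(rows, function(k) {
        o <- oracleDetect(pw[k, ], time, thr, 20)
        if (nrow(o)) sum(o$offset_s - o$onset_s) / (ncol(pw) / 250) else 0
      }, numeric(1))
      if (sd(frac) == 0) NA_real_ else cor(frac, mp[rows])
    }, numeric(1))
    mean(rs, na.rm = TRUE)
  }, numeric(1))
  expect_equal(res$curve$mean_r, curve, tolerance = 1e-10)
  expect_equal(res$percentile, seq(50, 98, by = 4)[which.max(curve)])
  ## identical trials: correlation undefined everywhere -> error
  flat <- mk_series(matrix(rep(pw[1, ], 6), 6, byrow = TRUE), fs = 250,
                    subject = rep(c("a", "b"), each = 3))
  expect_error(suppressWarnings(empiricalThreshold(flat)), "undefined")
})
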