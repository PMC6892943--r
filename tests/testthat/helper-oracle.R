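## Independent brute-force event detector: explicit sample-by-sample scan,
## no vectorized run-length machinery. Serves as the oracle the package
## detector is checked against.
oracleDetect <- function(power, time, threshold, ibf, min_cycles = 1.5) {
  dt <- time[2] - time[1]
  n <- length(power)
  out <- data.frame(onset_s = numeric(), offset_s = numeric(),
                    peak_time_s = numeric(), max_amplitude = numeric(),
                    duration_s = numeric(), is_edge = logical())
  k <- 1
  while (k <= n) {
    if (power[k] > threshold) {
      j <- k
      while (j < n && power[j + 1] > threshold) j <- j + 1
      if ((j - k + 1) * dt >= min_cycles / ibf) {
        pk <- k
        for (q in k:j) if (power[q] > power[pk]) pk <- q
        touches <- (k == 1) || (j == n)
        if (!(touches && (pk == 1 || pk == n))) {
          if (touches) {
            dur <- if (j == n) 2 * (time[pk] - time[k])
                   else 2 * (time[j] + dt - time[pk])
          } else {
            cnt <- 0
            for (q in k:j) if (power[q] > power[pk] / 2) cnt <- cnt + 1
            dur <- cnt * dt
          }
          out <- rbind(out, data.frame(onset_s = time[k],
                                       offset_s = time[j] + dt,
                                       peak_time_s = time[pk],
                                       max_amplitude = power[pk],
                                       duration_s = dur,
                                       is_edge = touches))
        }
      }
      k <- j + 1
    } else k <- k + 1
  }
  out
}

## Random normalized-power-like series: rectified smoothed noise with
## occasional burst bumps, so runs of every kind (short, long, edge) occur.
randomPowerSeries <- function(n = 300, fs = 500) {
  x <- stats::filter(rnorm(n + 40), rep(1 / 8, 8), sides = 1)
  x <- abs(x[41:(n + 40)]) + 0.05
  nb <- rpois(1, 1.5)
  t <- seq(-1, by = 1 / fs, length.out = n)
  if (nb > 0) {
    for (b in seq_len(nb)) {
      c0 <- runif(1, t[1], t[n])
      w <- runif(1, 0.03, 0.2)
      x <- x + runif(1, 0.5, 4) * exp(-(t - c0)^2 / (2 * (w / 2.355)^2))
    }
  }
  list(power = as.numeric(x), time = t)
}

## Minimal single-channel TrialSet around a matrix of traces (trial x time).
toyTrials <- function(traces, fs, time, channel = "C4-hjorth",
                      subject = rep("s01", nrow(traces)),
                      emg = matrix(0, 0, 0)) {
  arr <- array(traces, dim = c(nrow(traces), 1, ncol(traces)))
  TrialSet(arr, emg, fs, time, channel, subject)
}

## Multi-channel TrialSet from a list of per-channel trial x time matrices.
toyTrialsMulti <- function(chan_list, fs, time,
                           subject = rep("s01", nrow(chan_list[[1]])),
                           emg = matrix(0, 0, 0)) {
  n <- nrow(chan_list[[1]])
  nt <- ncol(chan_list[[1]])
  arr <- array(0, dim = c(n, length(chan_list), nt))
  for (i in seq_along(chan_list)) arr[, i, ] <- chan_list[[i]]
  TrialSet(arr, emg, fs, time, names(chan_list), subject)
}
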