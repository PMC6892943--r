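## Low-level numerical helpers: coloured noise, FFT resampling, Slepian
## tapers, Morlet kernels, centred convolution, moment statistics.

#' Pearson kurtosis
#'
#' Fourth central moment divided by the squared variance (population
#' denominators), so a Gaussian sample scores approximately 3. This is the
#' convention under which the artifact-rejection rule "kurtosis > 4" marks a
#' meaningful exceedance above Gaussian.
#'
#' @param x numeric vector.
#' @return scalar kurtosis.
#' @export
pearsonKurtosis <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 == 0) return(NaN)
  mean(x^4) / m2^2
}

## 1/f^alpha ("pink") noise via spectral shaping, scaled to a target sd.
pinkNoise <- function(n, sd = 1, alpha = 1) {
  if (n < 2) return(stats::rnorm(n, sd = sd))
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1))            # avoid division by zero at DC
  f <- pmin(f, n - f + 1)              # fold to two-sided frequency index
  X <- X / f^(alpha / 2)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x <- x * (sd / s)
  x
}

## Fourier-domain resampling of a real vector to n_out samples (periodic
## sinc interpolation, as used before multitaper estimation to bring a 1 s
## pre-stimulus segment down to a tractable length for the 1-30 Hz band).
fftResample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  stopifnot(n_out >= 2, n_out < n)
  X <- stats::fft(x)
  Y <- complex(n_out)
  half <- floor(n_out / 2)
  Y[1] <- X[1]
  if (half >= 2) {
    Y[2:half] <- X[2:half]
    Y[n_out - (2:half) + 2] <- X[n - (2:half) + 2]
  }
  ## Nyquist bin of the shorter series collects the (real part of) the
  ## corresponding original bin pair
  Y[half + 1] <- if (n_out %% 2 == 0) complex(real = Re(X[half + 1])) else X[half + 1]
  if (n_out %% 2 == 1 && half >= 1) {
    Y[n_out - half + 1] <- X[n - half + 1]
  }
  ## divide by the original n so sinusoid amplitudes are preserved
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, via the symmetric tridiagonal eigenproblem whose
#' eigenvectors are the Slepian sequences. Tapers are unit-norm columns
#' ordered by decreasing spectral concentration.
#'
#' @param n taper length (samples).
#' @param nw time-bandwidth product (e.g. 2 for +/-2 Hz smoothing on a 1 s
#'   segment).
#' @param k number of tapers (at most `2*nw - 1` for well-concentrated ones).
#' @return an `n x k` matrix of tapers.
#' @export
dpssTapers <- function(n, nw, k = max(1L, floor(2 * nw - 1))) {
  stopifnot(n >= 2, nw > 0, k >= 1, k <= n)
  w <- nw / n
  i <- 0:(n - 1)
  A <- matrix(0, n, n)
  diag(A) <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  eg <- eigen(A, symmetric = TRUE)
  tapers <- eg$vectors[, seq_len(k), drop = FALSE]
  ## fix sign: each taper's mean (even) or first lag (odd) positive
  for (j in seq_len(k)) {
    s <- sum(tapers[, j])
    if (abs(s) < 1e-12) s <- tapers[2, j] - tapers[1, j]
    if (s < 0) tapers[, j] <- -tapers[, j]
  }
  tapers
}

#' Complex Morlet wavelet kernel
#'
#' Gaussian-windowed complex exponential at frequency `f`, with the envelope
#' sd set by the number of cycles: `sigma_t = cycles / (2 * pi * f)`. The
#' kernel is truncated at +/- 4 sigma and normalized to unit energy; it is
#' symmetric, so convolution is zero-phase and peak latencies are preserved.
#'
#' @param f centre frequency (Hz).
#' @param fs sampling rate (Hz).
#' @param cycles number of cycles (default 5).
#' @return complex vector of odd length.
#' @export
morletKernel <- function(f, fs, cycles = 5) {
  stopifnot(f > 0, fs > 2 * f, cycles >= 1)
  sigma <- cycles / (2 * pi * f)
  half <- ceiling(4 * sigma * fs)
  t <- (-half:half) / fs
  k <- exp(-t^2 / (2 * sigma^2)) * exp(2i * pi * f * t)
  k / sqrt(sum(Mod(k)^2))
}

## Centred ("same") convolution of a real signal with an odd-length complex
## kernel, via FFT.
convSame <- function(x, kern) {
  n <- length(x)
  m <- length(kern)
  stopifnot(m %% 2 == 1, m <= 2 * n)
  L <- stats::nextn(n + m - 1, 2)
  X <- stats::fft(c(x, rep(0, L - n)))
  K <- stats::fft(c(kern, rep(0, L - m)))
  y <- stats::fft(X * K, inverse = TRUE) / L
  h <- (m - 1) / 2
  y[(h + 1):(h + n)]
}

## Restore-on-exit seeded RNG scope.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
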