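---
title: "Detecting beta events and modeling corticospinal excitability"
author: "betaburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting beta events and modeling corticospinal excitability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betaburst)
```

# The problem

Sensorimotor beta activity (15–30 Hz) over motor cortex is dominated by
transient events — bursts lasting on the order of one to two cycles —
rather than a continuously waxing and waning rhythm. When a TMS pulse
probes the motor cortex, the motor-evoked potential (MEP) it elicits in the
contralateral hand muscle varies from trial to trial, and part of that
variability tracks the pre-stimulus beta state. This package detects beta
events in the final second before a stimulus, characterizes their
morphology (number, half-maximum duration, maximum amplitude, timing of the
last event), and models single-trial log MEP amplitude from these metrics
with mixed-effects regression, including likelihood-ratio model comparison
and per-subject cross-validation.

Because real paired EEG–TMS recordings are large and external, the package
ships a synthetic generator that reproduces the statistical structure the
analysis assumes. The generator is first-class, tested code: every
downstream stage is validated against its ground truth.

# Pipeline model and assumptions

**Spatial filtering.** The analysis channel is the Hjorth (local Laplacian)
derivation around the motor cortex: C4 minus the mean of FC2, FC6, CP2,
CP6. The Hjorth weights sum to zero, so a preceding common average
reference provably cancels; the test suite asserts this numerically. The
artifact criteria (max |deflection| > 50 µV, kurtosis > 4, evaluated on the
closed-left, open-right window [−1, 0) s) are applied to the
Hjorth-transformed channel. Whether the amplitude criterion should be
applied before or after spatial filtering is genuinely open; we default to
after — the analysis channel is what the rest of the pipeline consumes —
and the window and channel are arguments.

**Kurtosis convention.** "Kurtosis > 4" is only meaningful above the
Gaussian baseline if kurtosis is Pearson's \(m_4 / m_2^2\) (normal ≈ 3),
not excess kurtosis (normal ≈ 0). We use Pearson's, with population
moment denominators, and cross-check against an independent fourth-moment
computation in the tests.

**Spectra and the individual beta frequency (IBF).** Per-subject spectra
use Slepian (DPSS) multitapers on the final pre-stimulus second. With a 1 s
segment and ±2 Hz smoothing the time–bandwidth product is NW = 2, giving
2NW − 1 = 3 well-concentrated tapers and 1 Hz frequency resolution. Since
the band of interest ends at 30 Hz, the segment is first FFT-resampled
(periodic sinc interpolation) to 200 Hz, and the tapers are obtained from
the standard symmetric tridiagonal eigenproblem at that length — exact,
fast, and dependency-free. The IBF is the deterministic spectral argmax in
15–30 Hz; an argmax falling on a band edge (e.g. under a monotone 1/f
spectrum with no beta peak) is returned with an explicit warning rather
than silently. Visual identification, as a human rater would do it, is
deliberately replaced by the argmax for reproducibility.

**Beta-power series.** Power at the IBF comes from a 5-cycle complex
Morlet wavelet (envelope sd \( \sigma_t = \mathrm{cycles}/(2\pi f)\),
truncated at ±4σ, unit energy, zero-phase by symmetry). To avoid edge decay
at the stimulus, the pre-stimulus series is mirrored at t = 0
(time-reversed reflection), convolved, and cropped. A property test checks
that, more than one kernel half-length away from the edges, mirrored and
zero-padded convolutions agree to 10⁻⁶ relative error. The series is kept
at the full sampling rate — no decimation — so event timing is exact.

**Normalization pool.** "Dividing by the mean beta power during the
pre-stimulus period" admits per-trial or per-subject readings. We normalize
per subject across retained trials: per-trial normalization would force
every trial's mean toward one and erase exactly the between-trial power
differences the mean-power model needs. The invariant "subject-mean of
normalized pre-stimulus power = 1 ± 10⁻⁹" is asserted in the tests.

**Event definition.** Per subject, the threshold is an empirical percentile
(linear interpolation between order statistics — `quantile` type 7; the
convention is stated because it shifts thresholds slightly) of the pooled
normalized power over all retained trial windows. Pooling over trials, not
within them, is what makes a percentile stable and is the natural reading
of a "within individuals" threshold. Supra-threshold is strict (> the
threshold; ties break toward "below"). Events must last at least
1.5 cycles at the IBF. Duration is the total time the run's power exceeds
half of the run maximum (all lobes count, not just the widest). A run
touching a window edge is an event only if its maximum is interior (power
declining at the edge); its duration is twice the onset-to-peak time at the
stimulus-side edge and, symmetrically, twice the peak-to-offset time at the
window-start edge (a case the original rule does not address; offsets are
exclusive, one sample step past the last supra-threshold sample).

One caution surfaced by the property suite: event *counts* are not
monotone in the threshold even without the minimum-duration filter — a
higher threshold can split one broad run into two. The monotone quantities
are the supra-threshold indicator and total supra-threshold time, and those
are what the tests assert.

**Timing convention.** "Timing of the last event" is not pinned to onset,
peak, or offset by the verbal definition. We use the latency of the event's
power maximum before the stimulus, in positive seconds (larger = earlier).
Under this sign convention an event closer to the pulse predicting a larger
MEP appears as a negative model estimate. Onset/offset latencies are one
subtraction away for anyone preferring them.

**MEP extraction.** Peak-to-peak voltage in +20…+40 ms. EMG "power" per
sample is the squared deviation from the trial's epoch-wide mean voltage —
demeaning within the short 20 ms pre-stimulus window itself would let a
single spike bias the baseline and flag the whole trial. The voluntary
activity limit (Q75 + 3·IQR) is computed per subject from the pooled
pre-stimulus power samples: an "empirically-defined upper limit" has to
come from the subject's own distribution. The template-correlation filter
(flag r ≤ 0.40) builds each subject's mean MEP from trials that survived
the pre-stimulus filter, in a single pass — contaminated trials should not
shape the template, and iterating the filter is not supported by the
method's description. Trials with zero amplitude or a degenerate (zero
variance) MEP window are flagged, never log-transformed.

**Models.** All mixed models are fit by maximum likelihood, not REML, so
likelihood-ratio tests and AIC comparisons across fixed-effect structures
are valid. Confidence intervals are Wald (symmetric, matching how such
results are conventionally reported); p-values are Satterthwaite by
default with a fast Wald option for simulation studies. Models of
event-specific metrics (number, duration, amplitude, timing, and the
per-threshold mean-power model) are fit on event trials only; the presence
model and the threshold-independent mean-power model use all retained
trials. Degenerate fits degrade deliberately: a singular fit (zero
between-subject variance) falls back to pooled ordinary regression — the
fully-shrunk limit of the mixed model — with a warning and a flag; a
numerically degenerate fit (zero residual variance, as in noiseless
simulations) uses per-subject fixed intercepts, the unshrunk limit.

**Cross-validation.** Folds are per-subject: each subject's retained
trials are shuffled with a recorded seed and dealt into k = 10 folds, so
train/test splits are 90/10 within every subject. Test predictions include
the subject's fitted random intercept — subjects appear in both sets by
design, and the question is whether beta metrics predict *within-subject*
fluctuation; a fixed-effects-only prediction mode exists for the stricter
question. Per fold we report Spearman's ρ and RMSE; the fold-averaged RMSE
is normalized by the observed range of log MEP amplitude. Because folds
share 90% of their training data, fold-level ρ values are correlated;
null-calibration tests therefore average over independent permutations
rather than using the across-fold standard error.

# The synthetic generator

`simulateTrialSet()` emulates what the analysis assumes about the data:

* **Bursts.** Poisson counts at 1.24 events/s; Hann amplitude envelopes
  whose support is scaled so the *power* half-maximum width matches the
  configured duration (default 114 ms, so the detector's half-max rule
  recovers the configured value directly); peak amplitudes lognormal;
  carrier at the subject's IBF (drawn from 18–24 Hz by default and rounded
  to the 1 Hz spectral grid) with random phase; bursts injected on C4 only.
  Peaks are placed with a minimum separation (0.15 s) where feasible —
  counts stay Poisson, but placement is soft-core so injected events remain
  resolvable; under Poisson crowding overlaps still occur and merge, which
  is a property of the event process, not a detector defect.
* **Background.** 1/f noise on every channel (power ∝ 1/f), so IBF
  detection is exercised against a realistic spectral slope rather than a
  flat floor.
* **MEPs.** A fixed biphasic template in +20…+40 ms, normalized to unit
  peak-to-peak on the trial's sample grid and scaled per trial so that
  log amplitude = subject intercept + Σ coupling·metric + Gaussian noise,
  with metrics computed from the injected ground truth. Default couplings
  are at the scale such studies report (presence 0.08, number 0.05,
  amplitude 0.01, timing −0.10, mean power 0.07); intercept sd 0.2 and
  residual sd 0.4 give MEP variability in a realistic range.
* **Artifacts.** An optional fraction of trials receives an 80 µV Gaussian
  transient on C4 in the pre-stimulus second, to exercise the rejection
  rule.

Two lighter companions serve calibration work: `simulateTrialMetrics()`
draws the same per-trial event statistics and the coupling model without
synthesizing signals (used for parameter-recovery and null-calibration
studies at hundreds of replicates), and `simulateBetaSeries()` injects
Hann² power envelopes directly into trial-window power series (used to
test the detector against known injections without the wavelet stage).

What the generator does **not** emulate: volume conduction from a head
model (other channels carry independent noise, not mixed sources),
TMS pulse artifacts, mu or gamma bursts, non-stationary background power,
or realistic EMG baseline structure. Passing tests therefore validate the
pipeline's *mechanics and statistics* — detection, morphology, exclusion
rules, estimation, prediction — not its robustness to every pathology of
real recordings.

# Numerical choices and problem sizes

* Percentile convention: linear interpolation (type 7); stated because a
  different convention shifts thresholds by a fraction of a sample.
* Strict exceedance (`>`) defines supra-threshold samples; the threshold
  value itself is "below".
* Wavelet kernels are truncated at ±4σ and unit-energy normalized; the
  normalization cancels in the normalized power series (scaling the raw
  EEG by c scales raw power by c² and leaves normalized power unchanged —
  asserted).
* Seeds: every stochastic routine takes an explicit integer seed and
  restores the caller's RNG state; identical configuration and seed give
  bit-identical output end to end.
* The simulation studies in the tests and the acceptance script use
  scaled-down cohorts chosen to make their statistical targets decidable:
  20 subjects × 300 trials (metrics-level) for coverage of a 0.07
  coupling; 500 small replicates for likelihood-ratio null uniformity;
  ≥ 1000 trials for Poisson rate recovery; and a 10 × 80-trial full-signal
  cohort at 1 kHz (epoch −1.5…+0.1 s) for the end-to-end run. The 5 kHz,
  −3…+3 s default of `synthConfig()` reflects the recording conditions the
  generator emulates; the reduced rates and epochs used in simulation keep
  the same band-limited content since everything analyzed lives below
  30 Hz.

# Known limitations

* The empirical-threshold search maximizes the subject-mean Pearson
  correlation curve over integer percentiles; with few subjects the curve
  is flat near its maximum and the argmax can move by a few percentiles
  between seeds (the full curve is returned so users can see this).
* Detected durations are wavelet-smoothed: a 5-cycle kernel at 20 Hz has
  ≈ 40 ms envelope sd, so a 114 ms injected burst reads out at roughly
  150–170 ms half-max duration. Comparisons of durations are meaningful
  within an analysis, not against the generator's envelope width unless
  the wavelet stage is bypassed (as `simulateBetaSeries()` does).
* Mixed-model couplings estimated on synthetic cohorts with all couplings
  active are larger than the marginal coupling values because the metrics
  are collinear (number, amplitude, and mean power rise together); the
  per-subject Spearman collinearity report quantifies this.
* Real-data ingestion (BrainVision/FIF adapters) is out of scope here; the
  pipeline consumes `TrialSet` objects, and any reader that produces
  epoched arrays can feed it.
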