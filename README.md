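# betaburst

Sensorimotor beta-band activity is not a sustained rhythm but a train of
transient, burst-like *beta events*. In paired EEG–TMS experiments the state
of the motor cortex just before a TMS pulse shapes the size of the
motor-evoked potential (MEP) recorded from the hand, so the morphology of
pre-stimulus beta events — how many there were, how long and how large the
last one was, and how close to the pulse it occurred — carries information
about corticospinal excitability. This package implements that analysis as
a tested, reusable pipeline for trial-based EEG/EMG data, together with a
ground-truth-annotated synthetic generator so every stage can be validated
without any recordings.

It is aimed at researchers working on oscillatory burst analysis,
brain-state-dependent stimulation, or trial-by-trial neurophysiology
modeling.

## The analysis

Per trial (epoched −3…+3 s around the stimulus at *t* = 0):

1. **Spatial filtering.** Common average reference, then the Hjorth
   transform over the motor cortex: C4 minus the mean of FC2, FC6, CP2,
   CP6. Trials with pre-stimulus artifacts (max |deflection| > 50 µV or
   Pearson kurtosis > 4 within the last second) are rejected.
2. **Individual beta frequency (IBF).** Multitaper (Slepian) spectra,
   1–30 Hz with ±2 Hz smoothing, averaged per subject; the IBF is the
   spectral argmax in 15–30 Hz.
3. **Beta-power series.** A 5-cycle complex Morlet wavelet at the IBF is
   convolved with the pre-stimulus signal (mirrored at *t* = 0 against edge
   decay); squared magnitude is normalized by the subject's mean
   pre-stimulus beta power and restricted to the trial window
   (−1, −0.05) s.
4. **Event detection.** Beta events are maximal runs above a per-subject
   percentile threshold (75th, and an empirically selected threshold found
   by scanning 50–98%), lasting at least 1.5 cycles. Each event yields its
   maximum amplitude, peak time, and half-maximum duration; runs touching a
   window edge count only if power is declining at the edge, with duration
   estimated by doubling the peak-side half.
5. **MEP extraction.** Peak-to-peak EMG amplitude in +20…+40 ms, with
   exclusion of trials showing voluntary pre-stimulus activity
   (> half of the −25…−5 ms samples above Q75 + 3·IQR of the subject's EMG
   power pool) or atypical MEP shape (r ≤ 0.40 against the subject's mean
   MEP), then a natural-log transform.
6. **Modeling.** Linear mixed-effects models (ML) of
   `log MEP ~ metric + (1 | subject)` for each beta metric; estimates are
   back-transformed to percent MEP change via `(e^b − 1)·100`. Nested
   models are compared with likelihood-ratio tests, and predictive value is
   assessed by k-fold (k = 10) cross-validation with per-subject 90/10
   splits, scored by Spearman's ρ and range-normalized RMSE.

## Worked example

```r
library(betaburst)

cfg <- synthConfig(n_subjects = 4, n_trials = 40, fs = 1000,
                   epoch = c(-1.5, 0.1),
                   channels = c("C4", "FC2", "FC6", "CP2", "CP6", "Cz"),
                   seed = 42)
sim <- simulateTrialSet(cfg)

hj  <- hjorthTransform(commonAverageReference(sim$trials))
rej <- rejectArtifacts(hj)
ibf <- findIBF(estimatePSD(rej$trials))
#> s01 s02 s03 s04
#>  23  24  20  23

series <- betaPowerSeries(rej$trials, ibf)
events <- detectAllEvents(series, percentile = 75)
meps   <- extractMEPs(rej$trials)
tm     <- summarizeTrials(series, events, meps)

fit <- fitMetricModel(tm, "mean_power")
#> Mixed-effects MEP model (random intercept per subject, ML), n = 141 trials
#>   mean_power       b = +0.2410 [0.1857, 0.2964], p = 2.35e-14, %change = 27.26
#>   AIC = 148.7, logLik = -70.37

cv <- crossValidate(tm, "mean_power", k = 10, seed = 1)
#> CV: mean rho = 0.61, normalized RMSE = 0.13
```

The per-subject IBFs recover the generator's injected beta frequencies. The
fixed-effect estimate `b` says each unit of normalized mean beta power
multiplies the MEP amplitude by `e^b` (here +27% per unit); the
cross-validation summary says predictions of held-out trials correlate with
observed log MEP amplitudes at ρ ≈ 0.61, with an average error of 13% of
the observed log-amplitude range. `runPipeline()` chains all of the above,
at both event thresholds, into a single report table.

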