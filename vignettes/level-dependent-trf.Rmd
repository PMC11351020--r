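---
title: "Level-dependent subcortical TRFs: model, estimation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Level-dependent subcortical TRFs: model, estimation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The auditory brainstem response (ABR) to continuous speech can be described
by a linear temporal response function (TRF): the single-channel EEG `y` is
modelled as the convolution of a non-negative stimulus feature series `x`
(the *predictor*) with an impulse response `h`, plus noise.  Because the
brainstem response changes with stimulus intensity -- wave V grows and
arrives earlier as the sound gets louder -- a single time-invariant kernel
is misspecified when the stimulus level varies.  This package implements the
*level-dependent* extension:

    y = sum_l  h_l * x_l  +  n

where the predictor is partitioned into `L` intensity bins, `x_l` equals `x`
on the samples presented at level `l` and zero elsewhere, and each level
gets its own kernel `h_l`.  All `L` kernels are estimated **jointly** by
unregularized least squares: the design matrix `X` stacks lagged copies of
every binned predictor (lags -10..30 ms by default, zero padded at the
record edges), and

    beta = (X'X)^{-1} X'y

is unstacked into the per-level kernels.  The joint fit matters because the
binned predictors are mutually correlated through their lagged copies
(strongly so for the quantile-binned variant below); fitting each level
separately leaks response energy across levels, which the joint solve
resolves.  No ridge penalty is used: with 10-20 minutes of data per bin the
normal equations are well conditioned, and regularization would shrink and
bias exactly the level-dependent amplitude differences under study.  A
symmetric positive-definite factorization solves the system; if `X'X` is
singular (e.g. duplicated bins) the minimum-norm pseudo-inverse solution is
returned with a warning.

Internally `X'X` is never materialized from `X`: its entries are
cross-correlations of the binned predictors at lag differences, assembled in
compiled code over the non-zero runs of each bin, with explicit corrections
for the record boundaries so the result is *exactly* the dense
normal-equations matrix (tests verify agreement with a brute-force dense
solve to 1e-8 relative error).

## Two ways of binning intensity

* **Scheduled levels** (`bin_by_ground_truth`): the experiment presents
  speech at 72/60/48/36 dB in 1-min trials and in 5-s segments; every
  sample is assigned the level of its schedule segment.  Cosine-ramp
  crossfades (500 ms) at level changes are split at the segment boundary,
  so each bin's edge samples carry intermediate amplitudes.
* **Inherent intensity** (`bin_by_inherent_intensity`): the predictor is
  smoothed with a 300 ms Hamming window as a running intensity estimate and
  cut at equal-count quantiles (octiles by default), so every bin holds the
  same amount of data and estimation noise is comparable across bins.
  Linear-interpolation quantiles are used; ties fall to the lower bin in
  sample order.

After binning, each `x_l` is scaled so its r.m.s. **over its non-zero
support** equals one (`normalize_bins`).  This lets every level drive the
regression equally: without it, the softest level (36 dB is a factor 64 in
amplitude below 72 dB) would contribute almost nothing to the fit.  The
applied scales are recorded so the partition remains reversible
(`unbin_predictor`), and the package's synthetic generator uses the same
convention, making fitted kernels directly comparable to its ground truth.

## Predictors

Two predictors are built in: half-wave rectified speech (`rectified_speech`)
and the average magnitude of a fourth-order gammatone filterbank
(`gammatone_predictor`) with 31 filters spaced 1 ERB apart from 80 to
8000 Hz (`ERBn(f) = 21.4 log10(0.00437 f + 1)`).  Both are 1-homogeneous:
doubling the stimulus doubles the predictor.  That linearity is what
preserves level information -- periphery models that compress or adapt
(e.g. auditory-nerve models) remove the level dependence from the predictor
and therefore from the fitted TRFs; such models can be plugged in through
`predictor_adapter`, and the synthetic module ships a toy "adaptive"
transform (`make_adaptive_predictor`) that demonstrates the effect.  Band
"amplitude" is the magnitude of the complex band signal (not its power);
band magnitudes are averaged and then resampled.  Predictors computed by
external models are aligned to the rectified-speech predictor by the median
per-trial cross-correlation lag within +/-50 ms (`align_predictor`).

The analysis rate is 4096 Hz (configurable).  Subcortical responses carry
energy well beyond 100 Hz, and wave V latency differences of interest are
fractions of a millisecond; 4096 Hz keeps the lag grid at 0.24 ms while
halving the native 8192 Hz EEG rate for tractability.

## Preprocessing

The paper-faithful conditioning chain for real recordings: Cz referenced to
the mastoid average, zero-phase FIR highpass at 1 Hz, FIR notch combs of
width 5 Hz at every multiple of 50 Hz up to 1 kHz, a 30-1000 Hz zero-phase
bandpass before TRF estimation, and artifact zeroing: every sample beyond 5
SD from the recording mean zeroes a 1 s window around it in the EEG *and in
every predictor* (identical sample indices), with the excluded fraction
reported.  All FIRs are Hamming windowed-sinc designs (transition width 25%
of the cutoff; the notch comb is designed by frequency sampling), applied by
FFT convolution with the group delay removed.  Filter orders are chosen by
the transition-width rule rather than fixed, since the source experiment
reports no orders; tests pin the contracts that matter (>= 40 dB DC
rejection for the highpass, >= 30 dB at the line harmonics, <= 1 dB passband
ripple, zero phase).  Re-referencing precedes filtering.  Mean and SD for
rejection are computed once over the whole recording, without iteration.

## Wave V metrics and statistics

Fitted kernels are smoothed with a 4 ms moving Hamming window (edge windows
truncated and renormalized); the same smoothing is applied to click ERPs so
the two are comparable.  Wave V is the largest *local* maximum between 4 and
10 ms; windows without a local maximum return the edge maximum flagged
`no_clear_peak` rather than failing.  Its SNR is
`10 log10((S - N)/N)` with `S` the mean squared amplitude in a 5 ms window
around the peak and `N` the baseline power at -10..0 ms; `S = 2N` gives
0 dB, the conventional threshold for a meaningful peak.  The -5 dB floor is
applied only in the `snr_display` column, never in statistics.  Latency and
amplitude are summarized per recording by ordinary least-squares trends
against level in dB (`fit_level_trend`); across recordings, features are
compared by Pearson correlation with Holm-Sidak step-down correction
(`holm_sidak_correct`, `adjusted_i = 1 - (1 - p_i)^(m - i + 1)` on the
sorted p-values with enforced monotonicity).  `datalength_sweep` reruns the
whole chain on growing session prefixes to chart how much data
level-dependent TRFs need.

## The synthetic generator

No public recordings accompany the source experiment, so the package ships
a generative twin of the paradigm (`simulate_session`): a speech-like
predictor (half-wave rectified broadband noise, amplitude-modulated by a
log-normal syllable-rate envelope at ~4.5 Hz, gated by pauses covering 15%
of the time, over a ~1%-r.m.s. noise floor -- real filterbank predictors
never reach exact zero, and the floor keeps the intensity octiles
non-degenerate inside pauses), scheduled level gains with 500 ms cosine
ramps, and EEG formed
by the forward model `y = sum_l h_l * x_l + n` with gammatone-shaped
per-level kernels.  Defaults: latencies 5.7/6.3/6.9/7.5 ms and amplitudes
2.5/2.0/1.5/1.0 across 72/60/48/36 dB -- the qualitative wave V trend.
Noise is 1/f background (r.m.s. 60) plus white sensor noise (r.m.s. 15),
placing the single-sample response SNR near -20 dB, a realistic regime for
subcortical EEG; sparse 200 ms biphasic artifacts (one per minute, 15 SD)
exercise the rejection stage, which then excludes a fraction of data in the
low single digits of percent, matching practice.  The forward convolution
uses `stats::filter`, a code path fully independent of the compiled
estimator, so generator and estimator validate each other: at zero noise the
fit reproduces the kernels to solver precision.

What the generator does **not** emulate: cortical response components,
across-trial nonstationarity, electrode drift, real speech acoustics
(the predictor is synthesized directly at the analysis rate), and any
nonlinearity between predictor and response beyond the level binning
itself.  Passing recovery tests therefore demonstrates correctness of the
estimation machinery under the model's own assumptions, not performance on
real recordings.

### An identifiability note on amplitudes

Bins are re-normalized *after* artifact zeroing.  If a zeroed window
removes samples carrying a disproportionate share of a bin's energy -- the
soft bin's loud-adjacent ramp samples are the typical case -- that bin's
support r.m.s. drops, its normalized predictor grows, and the fitted kernel
shrinks by exactly the ratio of the support r.m.s. after/before zeroing.
This is a property of the method (shared by any pipeline that normalizes
after exclusion), not an estimation error; recovery tests score amplitudes
against this identifiable target and latencies, which are unaffected,
against the ground truth directly.  At the generator's realistic noise
level a single session's smoothed-peak amplitude carries several percent of
extraction noise, so amplitude-recovery tolerances are checked on the
per-level recovery aggregated across sessions (the estimator is unbiased),
while latency tolerances hold for every single session.

### The adaptation phenomenon

`make_adaptive_predictor` mimics a periphery model with adaptation:
per-level gain equalization plus a per-level pre-delay equal to each
level's latency excess over the loudest level.  Fitting TRFs with this
predictor moves the latency differences out of the kernels -- the fitted
latency-versus-level slope collapses into a permutation null band -- while
the unmodified predictor preserves the negative slope.  The null band is
mean +/- 2.576 SD of the slopes obtained by refitting under all
permutations of the level labels (a 99% band under normality), chosen a
priori.

## Problem sizes and numerical choices

* Parameter-recovery validation: 20 seeds of 40-min sessions (10 min per
  level) at 4096 Hz, the paradigm's full short+long session halved; the
  adaptation phenomenon uses 8-min sessions, where it is already decisive.
* Lag window -10..30 ms, matching the click-ERP epoch window and
  comfortably containing the 4-10 ms wave V search region; acausal lags
  provide the noise-floor baseline.
* Quantile ties in inherent binning fall to the lower bin; a constant
  predictor raises an error rather than returning degenerate bins.
* Zero-padded boundaries everywhere (records are treated as silence
  outside), and the compiled normal-equations assembly reproduces exactly
  that convention.
* Click trains: inter-click intervals are `min_ici + Exp(1/rate - min_ici)`
  with the stochastic parts rescaled by a common factor to place exactly
  `round(duration x rate)` clicks inside the duration -- both the click
  count and the 15 ms minimum interval hold exactly, which the stated
  pseudo-Poisson recipe alone would not guarantee.  The 5280 clicks of a
  2-min block are counted within the 120 s of stimulation, excluding
  breaks.
* The click forward model drives the kernel with unsigned click impulses:
  the brainstem response is polarity-insensitive, and rarefaction/
  condensation alternation exists to cancel stimulus artifact in the
  average, not the response.

## Limitations

* Single-channel analysis only; no ocular-artifact regression or ICA.
* The inherent-intensity analysis assumes the smoothed predictor is an
  adequate intensity proxy; alternative loudness measures are not
  implemented.
* Wave V detection is a local-maximum rule; pathological waveforms (e.g.
  monotone within the search window) are flagged, not resolved.
* Absolute dB(A) calibration is out of scope; levels are relative to the
  loudest presentation.
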