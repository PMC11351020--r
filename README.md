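# ldtrf — level-dependent subcortical TRFs from continuous speech EEG

The auditory brainstem responds to sound within about 10 ms, and its most
prominent feature — wave V — changes lawfully with stimulus intensity: the
peak grows and arrives earlier as the sound gets louder. Classically this is
measured with clicks. `ldtrf` measures it from **continuous speech** instead:
it estimates intensity-resolved temporal response functions (TRFs) from a
single EEG channel, recovering a wave V per intensity level.

The package is for auditory-EEG researchers (and, prospectively, objective
audiometry) who want level-resolved subcortical responses without
interrupting natural listening.

## The method

The EEG is modelled as a sum of per-level convolutions,

```
y = Σ_l  h_l * x_l + n ,
```

where `x` is a non-negative stimulus predictor — half-wave rectified speech
(RS) or the averaged magnitude of a 31-channel, 1-ERB-spaced gammatone
filterbank (GT) — and `x_l` is `x` restricted to the samples presented at
intensity level `l` (zero elsewhere). The bins come either from the
experimental level schedule (72/60/48/36 dB) or from equal-count quantiles
of the 300 ms-smoothed predictor ("inherent intensity", octiles). Each bin
is normalized to unit r.m.s. over its non-zero support so all levels drive
the fit equally, and all kernels `h_l` are estimated **jointly** by
unregularized least squares,

```
β = (XᵀX)⁻¹ Xᵀ y ,
```

with `X` the concatenated matrix of lagged copies (−10..30 ms) of every
binned predictor. Wave V is extracted per level as the largest local maximum
at 4–10 ms of the 4 ms-Hamming-smoothed kernel, with
`SNR = 10·log10((S−N)/N)` against the −10..0 ms baseline, and summarized by
linear latency/amplitude trends over level.

Because no public recordings accompany the paradigm, the package includes a
first-class synthetic-session generator (speech-like predictor, scheduled
gains with cosine ramps, wave-V-like per-level kernels, 1/f noise, sparse
artifacts) used for end-to-end parameter recovery; see the methods vignette
(`vignettes/level-dependent-trf.Rmd`).

## Worked example

```r
library(ldtrf)

# a 12-minute synthetic session: 4 levels, long + short trials
schedule <- build_trial_schedule(n_long = 8, n_short = 4,
                                 levels = c(72, 60, 48, 36), seed = 1)
session <- simulate_session(schedule, seed = 2)

# artifact rejection, level binning, joint TRF fit
clean <- reject_artifacts(session$eeg, list(session$predictor))
bins <- normalize_bins(bin_by_ground_truth(clean$predictors[[1]], schedule))
fit <- estimate_trf(clean$eeg, bins)
summary(fit)
```

```
Level-dependent TRF fit (ground_truth bins)
  4 levels x 165 lags (-10.0 to 30.0 ms) @ 4096 Hz
  levels: 72, 60, 48, 36

Wave V features per level:
 level latency amplitude    snr snr_display no_clear_peak
    72   5.859    2.1093 23.391      23.391         FALSE
    60   6.592    1.6826 22.089      22.089         FALSE
    48   7.080    1.0182  9.732       9.732         FALSE
    36   7.568    0.7227 28.015      28.015         FALSE

Latency trend:  -0.0468 ms/dB (intercept 9.30 ms)
Amplitude trend: +0.0402 per dB (intercept -0.788)
```

Reading it: one kernel per level on a common lag axis; wave V latency
shortens from 7.6 ms at 36 dB to 5.9 ms at 72 dB (negative trend,
−0.047 ms/dB) while its amplitude grows (positive trend) — the generator's
ground truth for this session places the peaks at 7.5→5.7 ms with
amplitudes 1.0→2.5 (the 4 ms smoothing lowers every peak by a common
factor), so the fit recovers both orderings from 3 min of data per level.
All SNRs exceed the 0 dB threshold for a meaningful peak. `plot(fit)` overlays the
kernels; `wave_v_features()`, `fit_level_trend()`, `datalength_sweep()` and
`run_pipeline()` expose the rest of the chain, and `estimate_click_erp()`
provides the click-ABR reference path.

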