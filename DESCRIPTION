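Package: ldtrf
Title: Level-Dependent Subcortical Temporal Response Functions from Continuous Speech EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates level-dependent subcortical temporal response functions
    (TRFs) from single-channel EEG recorded during continuous speech.  The
    stimulus feature (half-wave rectified speech or an averaged gammatone
    filterbank envelope) is partitioned into intensity bins -- either from the
    experimental level schedule or from quantiles of the smoothed feature
    itself -- normalized per bin, and jointly deconvolved against the EEG by
    unregularized lagged least squares, yielding one impulse response per
    intensity level.  Wave V peak latency, amplitude and SNR are extracted
    per level and summarized by linear level trends.  Includes click-train
    and level-scheduled stimulus construction, EEG preprocessing (mastoid
    re-referencing, zero-phase FIR filtering, power-line notch combs,
    artifact zeroing), a click ERP estimator, and a seeded synthetic-session
    generator for end-to-end parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
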