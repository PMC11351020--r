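# shared fixtures: dense least-squares oracle and small synthetic sessions

# brute-force dense design-matrix least squares; the independent oracle for
# estimate_trf (never shares code with the package's solver)
dense_trf_oracle <- function(preds, y, kmin, kmax) {
  shift0 <- function(x, k) {
    n <- length(x)
    if (k == 0) x
    else if (k > 0) c(numeric(k), x[seq_len(n - k)])
    else c(x[(1 - k):n], numeric(-k))
  }
  X <- do.call(cbind, lapply(preds, function(p)
    sapply(kmin:kmax, function(k) shift0(p, k))))
  qr.solve(qr(X, LAPACK = TRUE), y)
}

# small speech session (all short trials, one per minute) for unit tests
small_session <- function(minutes = 4, seed = 101, noise = noise_spec(),
                          levels = c(72, 60, 48, 36)) {
  sched <- build_trial_schedule(0, minutes, levels, seed = seed)
  simulate_session(sched, noise = noise, seed = seed + 1)
}

# sine attenuation (dB) of a zero-phase filter op applied to an eeg_recording
probe_attenuation_db <- function(filter_fun, freq, fs, dur = 8) {
  t <- seq(0, dur, by = 1 / fs)
  x <- sin(2 * pi * freq * t)
  out <- filter_fun(eeg_recording(x, fs))$series
  mid <- seq(round(length(x) * 0.4), round(length(x) * 0.6))
  20 * log10(max(1e-12, sqrt(mean(out[mid]^2)) / sqrt(mean(x[mid]^2))))
}
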