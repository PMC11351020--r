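# Synthetic sessions: a speech-like predictor, level-specific wave-V-like
# kernels, and EEG generated by the forward model y = sum_l h_l * x_l + n.
# The forward convolution uses stats::filter, a code path independent of the
# compiled cross-correlation assembly used by the estimator, so forward and
# inverse directions check each other.

#' Ground-truth kernel parameters for synthetic sessions
#'
#' Per-level wave-V-like kernels.  Defaults follow the physiological trend:
#' latency strictly decreasing and amplitude strictly increasing with level,
#' latencies inside the 4-10 ms wave V search window.
#'
#' @param levels Level set in dB (loudest last not required; rows are sorted
#'   loudest first).
#' @param latencies Peak latencies in ms, one per level.
#' @param amplitudes Peak amplitudes in waveform units, one per level.
#' @param widths Kernel width parameter in ms (scalar or per level).
#' @param family `"gammatone"` (asymmetric fourth-order-envelope bump) or
#'   `"gaussian"`.
#' @return An object of class `ground_truth_kernels`: data frame `params`
#'   (level, latency, amplitude, width) sorted loudest first, plus `family`.
#' @export
ground_truth_kernels <- function(levels = c(72, 60, 48, 36),
                                 latencies = c(5.7, 6.3, 6.9, 7.5),
                                 amplitudes = c(2.5, 2.0, 1.5, 1.0),
                                 widths = 4,
                                 family = c("gammatone", "gaussian")) {
  family <- match.arg(family)
  stopifnot(length(latencies) == length(levels),
            length(amplitudes) == length(levels))
  params <- data.frame(level = levels, latency = latencies,
                       amplitude = amplitudes,
                       width = rep_len(widths, length(levels)))
  params <- params[order(params$level, decreasing = TRUE), ]
  if (any(diff(params$latency) <= 0))
    stop("latencies must strictly decrease with level")
  if (any(diff(params$amplitude) >= 0))
    stop("amplitudes must strictly increase with level")
  if (any(params$latency < 4 | params$latency > 10))
    stop("latencies must lie within the 4-10 ms wave V window")
  structure(list(params = params, family = family),
            class = "ground_truth_kernels")
}

#' @export
print.ground_truth_kernels <- function(x, ...) {
  cat(sprintf("<ground_truth_kernels> %s family\n", x$family))
  print(x$params, row.names = FALSE)
  invisible(x)
}

# one kernel sampled on lags 0..max_lag_ms
kernel_waveform <- function(latency, amplitude, width, family, rate,
                            max_lag_ms = 30) {
  t <- (0:round(max_lag_ms / 1000 * rate)) / rate * 1000
  if (family == "gammatone") {
    tau <- width / 4
    t0 <- latency - 3 * tau
    u <- pmax(t - t0, 0) / tau
    amplitude * (u / 3)^3 * exp(3 - u)
  } else {
    sigma <- width / 2.355
    amplitude * exp(-(t - latency)^2 / (2 * sigma^2))
  }
}

#' Sample the ground-truth kernels on a lag axis
#'
#' @param kernels A [ground_truth_kernels()] object.
#' @param rate Sampling rate in Hz.
#' @param max_lag_ms Last lag in ms (30).
#' @return Matrix (lags x levels, loudest first) with a `lags_ms` attribute.
#' @export
kernel_waveforms <- function(kernels, rate = 4096, max_lag_ms = 30) {
  p <- kernels$params
  m <- sapply(seq_len(nrow(p)), function(i) {
    kernel_waveform(p$latency[i], p$amplitude[i], p$width[i],
                    kernels$family, rate, max_lag_ms)
  })
  colnames(m) <- format(p$level)
  attr(m, "lags_ms") <- (0:(nrow(m) - 1)) / rate * 1000
  m
}

#' Noise model for synthetic EEG
#'
#' @param alpha Spectral exponent of the 1/f^alpha background (1).
#' @param rms Background r.m.s. in the same units as the kernels (60).
#' @param white_rms Additional white sensor-noise r.m.s. (15).
#' @param artifact_rate Sparse artifact events per minute (1).
#' @param artifact_amplitude Artifact peak in multiples of the background SD
#'   (15).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(alpha = 1, rms = 60, white_rms = 15,
                       artifact_rate = 1, artifact_amplitude = 15) {
  stopifnot(alpha >= 0, rms >= 0, white_rms >= 0, artifact_rate >= 0,
            artifact_amplitude >= 0)
  structure(list(alpha = alpha, rms = rms, white_rms = white_rms,
                 artifact_rate = artifact_rate,
                 artifact_amplitude = artifact_amplitude),
            class = "noise_spec")
}

# fast double-boxcar lowpass of white noise (approximately triangular
# frequency response with the -3 dB point near cutoff), standardized
smooth_gaussian_noise <- function(n, rate, cutoff) {
  w <- max(2L, round(rate / cutoff))
  m <- n + 2L * w
  x <- rnorm(m)
  cs <- c(0, cumsum(x))
  box <- (cs[(1 + w):(m + 1)] - cs[1:(m + 1 - w)]) / w
  m2 <- length(box)
  cs2 <- c(0, cumsum(box))
  y <- (cs2[(1 + w):(m2 + 1)] - cs2[1:(m2 + 1 - w)]) / w
  y <- y[seq_len(n)]
  (y - mean(y)) / sd(y)
}

# unseeded speech-like series core
speech_like_series <- function(n, rate, pause_fraction = 0.15,
                               syllable_rate = 4.5, tail_sigma = 0.5) {
  env <- exp(tail_sigma * smooth_gaussian_noise(n, rate, syllable_rate))
  gate_sig <- smooth_gaussian_noise(n, rate, 0.7)
  # threshold from a subsample: cheaper than a full-length quantile and
  # accurate to a fraction of a percent of session time
  sub <- gate_sig[seq(1, n, length.out = min(n, 100000))]
  gate <- gate_sig > quantile(sub, pause_fraction)
  carrier <- pmax(rnorm(n), 0)
  x <- env * gate * carrier
  # recording noise floor (~1% of the speech r.m.s.): real filterbank
  # predictors never reach exact zero, which keeps intensity octiles
  # non-degenerate even inside pauses
  x + 0.01 * sqrt(mean(x^2)) * abs(rnorm(n))
}

#' Speech-like synthetic predictor
#'
#' Non-negative series emulating a speech envelope predictor: half-wave
#' rectified broadband noise, amplitude-modulated by a log-normal
#' syllable-rate (3-6 Hz) envelope, gated by slow pauses.  The heavy-tailed
#' amplitude distribution keeps inherent-intensity octiles non-degenerate.
#'
#' @param duration Duration in seconds.
#' @param rate Analysis rate in Hz (4096).
#' @param seed Integer seed.
#' @param pause_fraction Fraction of time spent in pauses (0.15).
#' @return A [predictor()] named `"synthetic"`.
#' @export
make_speech_like_predictor <- function(duration, rate = 4096, seed,
                                       pause_fraction = 0.15) {
  stopifnot(duration > 0)
  n <- round(duration * rate)
  x <- with_seed(seed, speech_like_series(n, rate, pause_fraction))
  predictor(x, rate, name = "synthetic")
}

# 1/f^alpha background noise: random Gaussian spectrum with |f|^(-alpha/2)
# magnitudes, one inverse FFT, real part taken, scaled to target rms
pink_noise <- function(n, alpha, target_rms) {
  if (target_rms == 0) return(numeric(n))
  n2 <- stats::nextn(n, c(2, 3, 5))
  f <- c(1, seq_len(n2 - 1))
  f <- pmin(f, n2 - f + 1)                 # mirrored frequency index
  mag <- 1 / f^(alpha / 2)
  z <- complex(real = rnorm(n2) * mag, imaginary = rnorm(n2) * mag)
  shaped <- Re(fft(z, inverse = TRUE)) / n2
  shaped <- shaped[seq_len(n)]
  shaped * target_rms / rms(shaped)
}

# sparse biphasic artifact transients (one cycle of a windowed sine, 200 ms)
add_artifacts <- function(x, rate, n_events, amplitude_sd) {
  if (n_events == 0) return(x)
  width <- round(0.2 * rate)
  shape <- sin(2 * pi * seq_len(width) / width) *
    (0.5 - 0.5 * cos(2 * pi * seq_len(width) / width))
  s <- sd(x)
  centers <- sort(round(runif(n_events, 1, length(x) - width)))
  for (c0 in centers) {
    idx <- c0:(c0 + width - 1)
    x[idx] <- x[idx] + amplitude_sd * s * shape
  }
  x
}

#' Simulate a complete synthetic speech session
#'
#' Builds a speech-like predictor, applies the scheduled level gains
#' (cosine-ramped), and generates EEG as the sum over levels of the
#' ground-truth kernel convolved with that level's support-normalized binned
#' predictor, plus 1/f background noise, white sensor noise and sparse
#' high-amplitude artifacts.  Because the generator normalizes its binned
#' predictors by their support r.m.s. -- the estimator's convention -- the
#' fitted kernels recover the ground-truth kernels directly.
#'
#' @param schedule A `trial_schedule`.
#' @param kernels A [ground_truth_kernels()] covering the schedule's levels.
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @param rate Analysis rate in Hz (4096).
#' @return List with `eeg` ([eeg_recording()]), `predictor` ([predictor()],
#'   level gains applied), `kernels` (the ground truth), `schedule`.
#' @export
simulate_session <- function(schedule, kernels = ground_truth_kernels(),
                             noise = noise_spec(), seed, rate = 4096) {
  stopifnot(inherits(schedule, "trial_schedule"),
            inherits(kernels, "ground_truth_kernels"))
  p <- kernels$params
  if (!all(schedule$level %in% p$level))
    stop("schedule contains levels without ground-truth kernels")
  duration <- max(schedule$end)
  n <- round(duration * rate)
  with_seed(seed, {
    x <- speech_like_series(n, rate)
    x <- x * level_gain_profile(schedule, n, rate, max(p$level), ramp = 0.5)
    idx <- schedule_bin_index(schedule, n, rate, p$level)
    sig <- numeric(n)
    max_lag_ms <- 30
    for (l in seq_len(nrow(p))) {
      h <- kernel_waveform(p$latency[l], p$amplitude[l], p$width[l],
                           kernels$family, rate, max_lag_ms)
      sel <- idx == l & x != 0
      xl <- numeric(n)
      xl[sel] <- x[sel]
      r <- if (any(sel)) rms(xl[sel]) else 0
      rows <- which(schedule$level == p$level[l])
      ranges <- cbind(pmax(1L, floor(schedule$start[rows] * rate) + 1L),
                      pmin(n, floor(schedule$end[rows] * rate)))
      if (r > 0) sig <- sig + causal_conv_segments(xl / r, h, ranges)
    }
    bg <- pink_noise(n, noise$alpha, noise$rms)
    wn <- if (noise$white_rms > 0) rnorm(n, sd = noise$white_rms) else 0
    y <- sig + bg + wn
    n_events <- round(noise$artifact_rate * duration / 60)
    y <- add_artifacts(y, rate, n_events, noise$artifact_amplitude)
    list(eeg = eeg_recording(y, rate),
         predictor = predictor(x, rate, name = "synthetic"),
         kernels = kernels, schedule = schedule)
  })
}

# causal FIR convolution via stats::filter (C implementation, independent of
# the compiled estimator path); h[1] is the zero-lag tap
causal_conv <- function(x, h) {
  p <- length(h)
  y <- stats::filter(c(numeric(p - 1), x), h, method = "convolution",
                     sides = 1)
  as.numeric(y[p:(p + length(x) - 1)])
}

# causal convolution of a series that is nonzero only inside the given
# sample ranges (matrix with columns a, b): convolve each span separately
# and add the kernel tails, skipping the zero gaps
causal_conv_segments <- function(x, h, ranges) {
  n <- length(x)
  p <- length(h)
  out <- numeric(n)
  for (i in seq_len(nrow(ranges))) {
    a <- ranges[i, 1]; b <- ranges[i, 2]
    tail_len <- min(p - 1L, n - b)
    seg <- causal_conv(c(x[a:b], numeric(tail_len)), h)
    idx <- a:(b + tail_len)
    out[idx] <- out[idx] + seg
  }
  out
}

#' Toy adaptive predictor
#'
#' Mimics an auditory-periphery model with adaptation: equalizes the
#' per-level r.m.s. of the predictor (gain adaptation) and advances the
#' fitted response of each level by pre-delaying its predictor samples by
#' that level's latency excess over the loudest level (latency adaptation).
#' Fitting TRFs with this predictor abolishes the wave V latency-versus-level
#' slope while the unmodified predictor preserves it.
#'
#' @param pred The session [predictor()] (level gains applied).
#' @param schedule The session `trial_schedule`.
#' @param kernels The [ground_truth_kernels()] used to generate the EEG.
#' @return A [predictor()] named `"adaptive"`.
#' @export
make_adaptive_predictor <- function(pred, schedule, kernels) {
  stopifnot(inherits(pred, "predictor"), inherits(schedule, "trial_schedule"),
            inherits(kernels, "ground_truth_kernels"))
  p <- kernels$params
  rate <- pred$rate
  n <- length(pred$series)
  idx <- schedule_bin_index(schedule, n, rate, p$level)
  ref_rms <- NULL
  out <- numeric(n)
  lat_min <- min(p$latency)
  for (l in seq_len(nrow(p))) {
    sel <- idx == l & pred$series != 0
    if (!any(sel)) next
    xl <- numeric(n)
    xl[sel] <- pred$series[sel]
    r <- rms(xl[sel])
    if (is.null(ref_rms)) ref_rms <- r       # loudest level (rows sorted)
    gain <- if (r > 0) ref_rms / r else 1
    d <- round((p$latency[l] - lat_min) / 1000 * rate)
    out <- out + shift_series(xl * gain, d)
  }
  predictor(pmax(out, 0), rate, name = "adaptive")
}

#' Simulate a synthetic click session
#'
#' One 2-min block per level (loudest first), clicks at 44/s; the EEG is the
#' level's kernel convolved with the click impulse train (the brainstem
#' response is polarity-insensitive, so rarefaction and condensation clicks
#' drive the same kernel) plus background noise.
#'
#' @param kernels A [ground_truth_kernels()]; use click levels, e.g.
#'   `ground_truth_kernels(levels = c(66, 60, 48, 36))`.
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @param rate Analysis rate in Hz (4096).
#' @param block_duration Seconds of clicks per level (120).
#' @param click_rate Clicks per second (44).
#' @return List with `eeg` (all blocks concatenated), `trains` (one
#'   `click_train` per level, onsets in session time) and `levels`.
#' @export
simulate_click_session <- function(kernels = ground_truth_kernels(
                                     levels = c(66, 60, 48, 36)),
                                   noise = noise_spec(), seed, rate = 4096,
                                   block_duration = 120, click_rate = 44) {
  p <- kernels$params
  n_block <- round(block_duration * rate)
  n <- n_block * nrow(p)
  sig <- numeric(n)
  trains <- vector("list", nrow(p))
  for (l in seq_len(nrow(p))) {
    tr <- generate_click_train(block_duration, click_rate,
                               sample_rate = rate, seed = seed + 977L * l)
    h <- kernel_waveform(p$latency[l], p$amplitude[l], p$width[l],
                         kernels$family, rate)
    impulses <- numeric(n_block)
    impulses[pmin(round(tr$onsets * rate) + 1L, n_block)] <- 1
    block <- causal_conv(impulses, h)
    sig[((l - 1) * n_block + 1):(l * n_block)] <- block
    tr$onsets <- tr$onsets + (l - 1) * block_duration
    trains[[l]] <- tr
  }
  y <- with_seed(seed, {
    sig + pink_noise(n, noise$alpha, noise$rms) +
      rnorm(n, sd = noise$white_rms)
  })
  list(eeg = eeg_recording(y, rate), trains = trains, levels = p$level)
}

#' Write a synthetic session to disk
#'
#' Serializes the schedule as structured text, the predictor and EEG as RDS
#' containers, and the ground-truth kernel parameters as JSON.
#'
#' @param session A list from [simulate_session()].
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_session <- function(session, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(schedule = file.path(out_dir, "schedule.tsv"),
             predictor = file.path(out_dir, "predictor.rds"),
             eeg = file.path(out_dir, "eeg.rds"),
             kernels = file.path(out_dir, "ground_truth.json"))
  write_schedule(session$schedule, paths["schedule"])
  saveRDS(session$predictor, paths["predictor"])
  saveRDS(session$eeg, paths["eeg"])
  jsonlite::write_json(list(family = session$kernels$family,
                            params = session$kernels$params),
                       paths["kernels"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
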