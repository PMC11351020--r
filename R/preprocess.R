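# EEG conditioning: mastoid re-referencing, zero-phase FIR filtering,
# power-line notch combs, threshold artifact zeroing, decimation.

#' Single-channel EEG container
#'
#' @param series Voltage series (uV).
#' @param rate Sampling rate in Hz (8192 native for the BioSemi system).
#' @param zeroed_segments Data frame of zeroed spans with columns `start`,
#'   `end` in seconds.
#' @param reference Reference label.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(series, rate,
                          zeroed_segments = data.frame(start = numeric(0),
                                                       end = numeric(0)),
                          reference = "Cz-mastoids") {
  stopifnot(all(is.finite(series)), rate > 0)
  structure(list(series = as.numeric(series), rate = rate,
                 zeroed_segments = zeroed_segments, reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  zf <- if (nrow(x$zeroed_segments))
    sum(x$zeroed_segments$end - x$zeroed_segments$start) /
      (length(x$series) / x$rate) else 0
  cat(sprintf("<eeg_recording> %d samples @ %g Hz (%s), %.1f%% zeroed\n",
              length(x$series), x$rate, x$reference, 100 * zf))
  invisible(x)
}

#' Re-reference Cz to the mastoid average
#'
#' @param cz,mastoid_left,mastoid_right Equal-length voltage series.
#' @param rate Sampling rate in Hz.
#' @return An [eeg_recording()] holding `cz - (left + right)/2`.
#' @export
rereference <- function(cz, mastoid_left, mastoid_right, rate = 8192) {
  if (length(cz) != length(mastoid_left) ||
      length(cz) != length(mastoid_right))
    stop("channel lengths differ")
  eeg_recording(cz - (mastoid_left + mastoid_right) / 2, rate,
                reference = "Cz-mastoids")
}

# odd-length Hamming windowed-sinc length for a given transition width (Hz)
fir_length <- function(fs, transition, max_taps = 262145L) {
  n <- ceiling(3.3 * fs / transition)
  n <- min(n + (1 - n %% 2), max_taps)
  as.integer(n)
}

#' Zero-phase FIR highpass filter
#'
#' Hamming windowed-sinc design with transition width 25% of the cutoff,
#' applied with the group delay compensated (zero phase).
#'
#' @param eeg An [eeg_recording()].
#' @param cutoff Cutoff in Hz (1).
#' @param transition Transition width in Hz; defaults to `0.25 * cutoff`.
#' @return The filtered [eeg_recording()].
#' @export
filter_highpass <- function(eeg, cutoff = 1, transition = 0.25 * cutoff) {
  stopifnot(inherits(eeg, "eeg_recording"))
  if (cutoff >= eeg$rate / 2) stop("cutoff must be below the Nyquist frequency")
  n <- fir_length(eeg$rate, transition)
  h <- signal::fir1(n - 1L, 2 * cutoff / eeg$rate, type = "high")
  eeg$series <- fir_filter_zerophase(eeg$series, h)
  eeg
}

#' Zero-phase FIR bandpass filter for subcortical analysis
#'
#' @param eeg An [eeg_recording()].
#' @param low,high Band edges in Hz (30 and 1000).
#' @return The filtered [eeg_recording()].
#' @export
bandpass_subcortical <- function(eeg, low = 30, high = 1000) {
  stopifnot(inherits(eeg, "eeg_recording"))
  if (!(0 < low && low < high && high < eeg$rate / 2))
    stop("invalid band edges for rate ", eeg$rate)
  n <- fir_length(eeg$rate, 0.25 * low)
  h <- signal::fir1(n - 1L, c(2 * low / eeg$rate, 2 * high / eeg$rate),
                    type = "pass")
  eeg$series <- fir_filter_zerophase(eeg$series, h)
  eeg
}

#' Power-line notch comb
#'
#' Zero-phase FIR filter with notches of the given width at every multiple of
#' `base` up to `max_freq`, designed by frequency sampling with a Hamming
#' window.
#'
#' @param eeg An [eeg_recording()].
#' @param base Line frequency in Hz (50).
#' @param width Notch width in Hz (5).
#' @param max_freq Highest notched multiple in Hz (1000).
#' @return The filtered [eeg_recording()].
#' @export
notch_comb <- function(eeg, base = 50, width = 5, max_freq = 1000) {
  stopifnot(inherits(eeg, "eeg_recording"))
  fs <- eeg$rate
  if (!(base <= max_freq && max_freq < fs / 2))
    stop("need base <= max_freq < Nyquist")
  h <- design_notch_comb(fs, base, width, max_freq)
  eeg$series <- fir_filter_zerophase(eeg$series, h)
  eeg
}

# frequency-sampling design of the notch comb; returns an odd-length
# linear-phase FIR
design_notch_comb <- function(fs, base, width, max_freq) {
  n <- fir_length(fs, width / 2.5)
  f <- (0:(n - 1)) * fs / n
  f_mirror <- pmin(f, fs - f)
  centers <- seq(base, max_freq, by = base)
  d <- rep(1, n)
  for (fc in centers) d[abs(f_mirror - fc) <= width / 2] <- 0
  h0 <- Re(fft(d, inverse = TRUE)) / n
  # rotate so the impulse response is centred, then window
  m <- (n - 1L) %/% 2L
  h <- c(h0[(n - m + 1L):n], h0[1:(m + 1L)])
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  h * w
}

#' Zero out high-amplitude artifacts
#'
#' Samples beyond `n_sd` standard deviations from the recording mean trigger
#' zeroing of a window of `+/- zero_halfwidth` seconds (1 s total by default)
#' in the EEG and, at identical sample indices, in every supplied predictor.
#' Overlapping windows are merged.
#'
#' @param eeg An [eeg_recording()].
#' @param predictors List of [predictor()]s with the same rate and length.
#' @param n_sd Threshold in standard deviations (5).
#' @param zero_halfwidth Half-width of the zeroed window in seconds (0.5).
#' @return List with elements `eeg`, `predictors` and `fraction_excluded`.
#' @export
reject_artifacts <- function(eeg, predictors = list(), n_sd = 5,
                             zero_halfwidth = 0.5) {
  stopifnot(inherits(eeg, "eeg_recording"))
  for (p in predictors)
    stopifnot(inherits(p, "predictor"), p$rate == eeg$rate,
              length(p$series) == length(eeg$series))
  x <- eeg$series
  n <- length(x)
  m <- mean(x); s <- sd(x)
  bad <- which(abs(x - m) > n_sd * s)
  if (!length(bad))
    return(list(eeg = eeg, predictors = predictors, fraction_excluded = 0))
  hw <- round(zero_halfwidth * eeg$rate)
  starts <- pmax(bad - hw, 1L)
  ends <- pmin(bad + hw, n)
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  ms <- starts[1]; me <- ends[1]
  seg_s <- integer(0); seg_e <- integer(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me + 1L) me <- max(me, ends[i])
    else { seg_s <- c(seg_s, ms); seg_e <- c(seg_e, me); ms <- starts[i]; me <- ends[i] }
  }
  seg_s <- c(seg_s, ms); seg_e <- c(seg_e, me)
  n_zeroed <- 0L
  for (i in seq_along(seg_s)) {
    idx <- seg_s[i]:seg_e[i]
    x[idx] <- 0
    for (j in seq_along(predictors)) predictors[[j]]$series[idx] <- 0
    n_zeroed <- n_zeroed + length(idx)
  }
  eeg$series <- x
  eeg$zeroed_segments <- rbind(eeg$zeroed_segments,
                               data.frame(start = (seg_s - 1) / eeg$rate,
                                          end = seg_e / eeg$rate))
  list(eeg = eeg, predictors = predictors,
       fraction_excluded = n_zeroed / n)
}

#' Decimate EEG to the analysis rate
#'
#' Anti-aliased resampling (see [resample_series()]); zeroed-segment
#' bookkeeping is carried over unchanged (times are in seconds).
#'
#' @param eeg An [eeg_recording()].
#' @param to Target rate in Hz (4096).
#' @return An [eeg_recording()] at the new rate.
#' @export
decimate_eeg <- function(eeg, to = 4096) {
  stopifnot(inherits(eeg, "eeg_recording"))
  eeg_recording(resample_series(eeg$series, eeg$rate, to), to,
                zeroed_segments = eeg$zeroed_segments,
                reference = eeg$reference)
}
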