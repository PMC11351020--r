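# Stimulus predictors: the non-negative feature series regressed against the
# EEG.  Two built-in predictors: half-wave rectified speech (RS) and the
# average magnitude of a 1-ERB-spaced gammatone filterbank (GT).

#' Predictor container
#'
#' @param series Non-negative finite feature values at the analysis rate.
#' @param rate Analysis rate in Hz.
#' @param name Predictor name (`"RS"`, `"GT"`, or custom).
#' @param applied_lag Lag already applied to the series, seconds.
#' @return An object of class `predictor`.
#' @export
predictor <- function(series, rate, name = "custom", applied_lag = 0) {
  stopifnot(all(is.finite(series)), all(series >= 0), rate > 0)
  structure(list(series = as.numeric(series), rate = rate, name = name,
                 applied_lag = applied_lag),
            class = "predictor")
}

#' @export
print.predictor <- function(x, ...) {
  cat(sprintf("<predictor> %s: %d samples @ %g Hz, applied lag %.2f ms\n",
              x$name, length(x$series), x$rate, 1000 * x$applied_lag))
  invisible(x)
}

#' Gammatone filterbank specification
#'
#' Filter centres are spaced `spacing` units apart on the ERB-number scale
#' `ERBn(f) = 21.4 log10(0.00437 f + 1)`, starting at `f_low` and not
#' exceeding `f_high`.
#'
#' @param f_low,f_high Corner frequencies in Hz (defaults 80 and 8000, which
#'   give 31 filters at 1-ERB spacing).
#' @param spacing Centre spacing in ERB-number units.
#' @return An object of class `filterbank_spec` with the computed
#'   `n_filters`.
#' @export
filterbank_spec <- function(f_low = 80, f_high = 8000, spacing = 1) {
  if (f_low > f_high) stop("f_low must not exceed f_high")
  spec <- structure(list(f_low = f_low, f_high = f_high, spacing = spacing),
                    class = "filterbank_spec")
  spec$n_filters <- length(erb_center_frequencies(spec))
  spec
}

erb_number <- function(f) 21.4 * log10(0.00437 * f + 1)
erb_number_inverse <- function(e) (10^(e / 21.4) - 1) / 0.00437
erb_bandwidth <- function(f) 24.7 * (0.00437 * f + 1)

#' ERB-spaced filter centre frequencies
#'
#' @param spec A [filterbank_spec()].
#' @return Increasing vector of centre frequencies in Hz.
#' @export
erb_center_frequencies <- function(spec) {
  stopifnot(inherits(spec, "filterbank_spec"))
  e_low <- erb_number(spec$f_low)
  e_high <- erb_number(spec$f_high)
  steps <- seq(e_low, e_high + 1e-9, by = spec$spacing)
  erb_number_inverse(steps)
}

#' Half-wave rectified speech predictor (RS)
#'
#' Half-wave rectifies the stimulus waveform, then anti-alias filters and
#' resamples it to the analysis rate.
#'
#' @param audio An [audio_signal()].
#' @param rate Analysis rate in Hz (4096).
#' @return A [predictor()] named `"RS"`.
#' @export
rectified_speech <- function(audio, rate = 4096) {
  stopifnot(inherits(audio, "audio_signal"), length(audio$samples) > 0)
  x <- pmax(audio$samples, 0)
  x <- resample_series(x, audio$sample_rate, rate)
  predictor(pmax(x, 0), rate, name = "RS")
}

#' Averaged gammatone filterbank predictor (GT)
#'
#' Passes the stimulus through a fourth-order gammatone filterbank (one
#' filter per ERB-spaced centre), takes the magnitude of each band's complex
#' output, averages the bands, and resamples to the analysis rate.  The
#' transform is 1-homogeneous: scaling the stimulus scales the predictor by
#' the same factor, which is what preserves level information in the
#' downstream regression.
#'
#' @param audio An [audio_signal()] with sample rate at least `2 * f_high`.
#' @param spec A [filterbank_spec()].
#' @param rate Analysis rate in Hz (4096).
#' @return A [predictor()] named `"GT"`.
#' @export
gammatone_predictor <- function(audio, spec = filterbank_spec(), rate = 4096) {
  stopifnot(inherits(audio, "audio_signal"), inherits(spec, "filterbank_spec"))
  fs <- audio$sample_rate
  if (spec$f_high > fs / 2)
    stop("f_high exceeds the Nyquist frequency of the audio")
  centers <- erb_center_frequencies(spec)
  acc <- numeric(length(audio$samples))
  for (fc in centers)
    acc <- acc + cpp_gammatone_env(audio$samples, fs, fc,
                                   1.019 * erb_bandwidth(fc))
  acc <- acc / length(centers)
  x <- resample_series(acc, fs, rate)
  predictor(pmax(x, 0), rate, name = "GT")
}

#' Band energies of the gammatone filterbank
#'
#' Mean squared band envelope per centre frequency; used to inspect how
#' stimulus energy distributes over the filterbank.
#'
#' @inheritParams gammatone_predictor
#' @return Named numeric vector of per-band mean squared envelopes.
#' @export
gammatone_band_energies <- function(audio, spec = filterbank_spec()) {
  centers <- erb_center_frequencies(spec)
  fs <- audio$sample_rate
  e <- vapply(centers, function(fc) {
    mean(cpp_gammatone_env(audio$samples, fs, fc, 1.019 * erb_bandwidth(fc))^2)
  }, numeric(1))
  setNames(e, sprintf("%.0f", centers))
}

#' Align a predictor to a reference predictor
#'
#' Finds, for every trial, the lag (within `+/-max_lag`) maximizing the
#' cross-correlation with the reference, takes the median lag across trials,
#' and shifts the predictor by that amount (recorded in `applied_lag`).
#' All-zero trials are excluded from the median.
#'
#' @param pred,reference [predictor()]s of equal rate and length.
#' @param trial_bounds Trial start times in seconds (the final trial runs to
#'   the end of the series).
#' @param max_lag Search bound in seconds (0.05).
#' @return The shifted [predictor()].
#' @export
align_predictor <- function(pred, reference, trial_bounds, max_lag = 0.05) {
  stopifnot(inherits(pred, "predictor"), inherits(reference, "predictor"),
            pred$rate == reference$rate,
            length(pred$series) == length(reference$series),
            length(trial_bounds) >= 1)
  rate <- pred$rate
  n <- length(pred$series)
  M <- round(max_lag * rate)
  starts <- pmax(1L, floor(trial_bounds * rate) + 1L)
  ends <- c(starts[-1] - 1L, n)
  lags <- c()
  for (i in seq_along(starts)) {
    x <- pred$series[starts[i]:ends[i]]
    r <- reference$series[starts[i]:ends[i]]
    if (all(x == 0) || all(r == 0)) next
    nn <- length(x)
    cc <- vapply(-M:M, function(l) {
      if (l >= 0) sum(x[seq_len(nn - l)] * r[(1 + l):nn])
      else sum(x[(1 - l):nn] * r[seq_len(nn + l)])
    }, numeric(1))
    lags <- c(lags, (-M:M)[which.max(cc)])
  }
  if (!length(lags)) stop("alignment failed: all trials are zero")
  lag <- round(median(lags))
  out <- shift_series(pred$series, lag)
  predictor(pmax(out, 0), rate, name = pred$name,
            applied_lag = pred$applied_lag + lag / rate)
}

# integer shift with zero padding; positive lag delays the series
shift_series <- function(x, lag) {
  n <- length(x)
  if (lag == 0) return(x)
  if (lag > 0) c(numeric(min(lag, n)), x[seq_len(max(0, n - lag))])
  else c(x[(1 - lag):n], numeric(min(-lag, n)))
}

#' Wrap an external auditory-periphery model as a predictor
#'
#' Adapter hook for periphery models (e.g. published cochlear models) that
#' map audio to a feature series.  The callable receives the audio samples
#' and sample rate and must return a series at the requested analysis rate.
#'
#' @param fun `function(samples, sample_rate, rate)` returning a numeric
#'   series at `rate`.
#' @param name Predictor name.
#' @return `function(audio, rate)` producing a [predictor()].
#' @export
predictor_adapter <- function(fun, name = "custom") {
  force(fun); force(name)
  function(audio, rate = 4096) {
    stopifnot(inherits(audio, "audio_signal"))
    series <- fun(audio$samples, audio$sample_rate, rate)
    predictor(pmax(as.numeric(series), 0), rate, name = name)
  }
}
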