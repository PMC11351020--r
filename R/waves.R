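# Wave V feature extraction and level-trend statistics: the largest peak
# between 4 and 10 ms, its SNR against the pre-stimulus baseline, ordinary
# least-squares latency/amplitude trends over level, Pearson correlations
# with Holm-Sidak correction, and the data-length sweep.

# moving weighted average with Hamming weights summing to one; edge windows
# are truncated and re-normalized, so a constant series is unchanged.
# The window length is forced odd so the window is centred on each sample
# (an even window would delay every feature by half a sample).
smooth_hamming <- function(x, width) {
  if (width < 2) return(x)
  if (width %% 2 == 0) width <- width + 1
  if (width >= length(x)) stop("smoothing window must be shorter than the series")
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(width - 1)) / (width - 1))
  num <- conv_fft(x, w)
  den <- conv_fft(rep(1, length(x)), w)
  d <- (width - 1) %/% 2
  (num / den)[(d + 1):(d + length(x))]
}

#' Smooth a waveform with a moving Hamming window
#'
#' @param w Numeric waveform.
#' @param window_width Window width in ms (4).
#' @param rate Sampling rate of the waveform in Hz.
#' @return Smoothed waveform of the same length.
#' @export
smooth_waveform <- function(w, window_width = 4, rate = 4096) {
  smooth_hamming(w, round(window_width / 1000 * rate))
}

#' Detect the wave V peak
#'
#' The local maximum with the largest amplitude inside the search window
#' (4-10 ms by default).  If the window contains no local maximum, the
#' maximum at the window edge is returned with `no_clear_peak = TRUE`.
#'
#' @param w Numeric waveform.
#' @param lags_ms Lag axis in ms, same length as `w`.
#' @param search Search window in ms, default `c(4, 10)`.
#' @return List with `latency` (ms), `amplitude`, `no_clear_peak`.
#' @export
detect_wave_v <- function(w, lags_ms, search = c(4, 10)) {
  stopifnot(length(w) == length(lags_ms),
            min(lags_ms) <= search[1], max(lags_ms) >= search[2])
  win <- which(lags_ms >= search[1] & lags_ms <= search[2])
  interior <- win[win > 1 & win < length(w)]
  is_max <- w[interior] >= w[interior - 1] & w[interior] >= w[interior + 1] &
    (w[interior] > w[interior - 1] | w[interior] > w[interior + 1])
  peaks <- interior[is_max]
  if (length(peaks)) {
    i <- peaks[which.max(w[peaks])]
    list(latency = lags_ms[i], amplitude = w[i], no_clear_peak = FALSE)
  } else {
    i <- win[which.max(w[win])]
    list(latency = lags_ms[i], amplitude = w[i], no_clear_peak = TRUE)
  }
}

#' Wave V signal-to-noise ratio
#'
#' `SNR = 10 log10((S - N) / N)` with `S` the mean squared amplitude in a
#' 5 ms window centred on the wave V peak and `N` the mean squared amplitude
#' over the baseline window (-10 to 0 ms).  `S = 2N` gives 0 dB.  If the
#' signal power does not exceed the noise power the SNR is `-Inf` (reported
#' below any display floor).
#'
#' @param w Numeric waveform.
#' @param lags_ms Lag axis in ms.
#' @param peak_latency Wave V latency in ms.
#' @param signal_halfwidth Signal window half-width in ms (2.5).
#' @param noise_window Baseline window in ms, default `c(-10, 0)`.
#' @return SNR in dB (possibly `-Inf`).
#' @export
compute_snr <- function(w, lags_ms, peak_latency, signal_halfwidth = 2.5,
                        noise_window = c(-10, 0)) {
  sig <- lags_ms >= peak_latency - signal_halfwidth &
    lags_ms <= peak_latency + signal_halfwidth
  noi <- lags_ms >= noise_window[1] & lags_ms <= noise_window[2]
  stopifnot(any(sig), any(noi))
  S <- mean(w[sig]^2)
  N <- mean(w[noi]^2)
  if (N == 0) stop("zero noise power in the baseline window")
  if (S <= N) return(-Inf)
  10 * log10((S - N) / N)
}

#' Wave V features for every level of a fit
#'
#' Smooths the kernels (if not already smoothed), detects the wave V peak per
#' level and computes its SNR.  The -5 dB display floor is reported in
#' `snr_display` only; `snr` keeps the raw value for statistics.
#'
#' @param object An `ldtrf` fit or a `click_erp`.
#' @param smooth_width Hamming smoothing width in ms (4).
#' @param search Wave V search window in ms.
#' @param snr_floor Display floor in dB (-5).
#' @param ... Unused.
#' @return Data frame with one row per level: `level`, `latency`,
#'   `amplitude`, `snr`, `snr_display`, `no_clear_peak`.
#' @export
wave_v_features <- function(object, smooth_width = 4, search = c(4, 10),
                            snr_floor = -5, ...) {
  UseMethod("wave_v_features")
}

#' @export
wave_v_features.ldtrf <- function(object, smooth_width = 4, search = c(4, 10),
                                  snr_floor = -5, ...) {
  if (!object$smoothed && smooth_width > 0)
    object <- smooth_trf(object, smooth_width)
  rows <- lapply(seq_len(ncol(object$kernels)), function(l) {
    w <- object$kernels[, l]
    pk <- detect_wave_v(w, object$lags, search)
    snr <- compute_snr(w, object$lags, pk$latency)
    data.frame(level = object$labels[l], latency = pk$latency,
               amplitude = pk$amplitude, snr = snr,
               snr_display = max(snr, snr_floor),
               no_clear_peak = pk$no_clear_peak)
  })
  do.call(rbind, rows)
}

#' @export
wave_v_features.click_erp <- function(object, smooth_width = 4,
                                      search = c(4, 10), snr_floor = -5, ...) {
  w <- if (smooth_width > 0)
    smooth_waveform(object$waveform, smooth_width, object$rate)
  else object$waveform
  pk <- detect_wave_v(w, object$times, search)
  snr <- compute_snr(w, object$times, pk$latency)
  data.frame(level = object$level, latency = pk$latency,
             amplitude = pk$amplitude, snr = snr,
             snr_display = max(snr, snr_floor),
             no_clear_peak = pk$no_clear_peak)
}

#' Scale TRFs to the click-ERP r.m.s.
#'
#' One common scalar -- the r.m.s. of the grand-average click ERP waveform
#' divided by the r.m.s. of the grand-average TRF kernel -- applied to every
#' kernel of every fit, enabling morphology comparison between TRFs and
#' click ERPs.
#'
#' @param trfs List of `ldtrf` fits.
#' @param erps List of `click_erp` objects.
#' @return The list of fits, rescaled, each with `scale_factor` recorded.
#' @export
scale_to_erp <- function(trfs, erps) {
  stopifnot(length(trfs) > 0, length(erps) > 0)
  erp_mean <- rowMeans(sapply(erps, function(e) e$waveform))
  trf_mean <- rowMeans(do.call(cbind, lapply(trfs, function(t) t$kernels)))
  r_trf <- rms(trf_mean)
  if (r_trf == 0) stop("zero TRF r.m.s.; cannot scale")
  factor <- rms(erp_mean) / r_trf
  lapply(trfs, function(t) {
    t$kernels <- t$kernels * factor
    t$scale_factor <- t$scale_factor * factor
    t
  })
}

#' Linear trend of a wave V metric over level
#'
#' Ordinary least squares of latency or amplitude against level (dB or bin
#' index).
#'
#' @param features Data frame from [wave_v_features()].
#' @param metric `"latency"` or `"amplitude"`.
#' @return A `level_trend`: `metric`, `slope` (units/dB), `intercept`,
#'   `levels_used`.
#' @export
fit_level_trend <- function(features, metric = c("latency", "amplitude")) {
  metric <- match.arg(metric)
  ok <- is.finite(features[[metric]])
  if (length(unique(features$level[ok])) < 2)
    stop("need features at >= 2 levels for a trend fit")
  fit <- lm(features[[metric]][ok] ~ features$level[ok])
  structure(list(metric = metric, slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 levels_used = features$level[ok]),
            class = "level_trend")
}

#' @export
print.level_trend <- function(x, ...) {
  cat(sprintf("<level_trend> %s: slope %+.4g per dB, intercept %.4g\n",
              x$metric, x$slope, x$intercept))
  invisible(x)
}

#' Null band for a level-trend slope from label permutations
#'
#' Refits the trend under permutations of the level labels and returns a
#' normal-approximation null band for the slope (mean plus/minus
#' `z * sd` of the permuted slopes; `z = 2.576` gives a 99% band).  A slope
#' inside the band is indistinguishable from a level-less null.
#'
#' @param features Data frame from [wave_v_features()].
#' @param metric Metric to fit.
#' @param z Band half-width in null standard deviations.
#' @return List with `band` (absolute slope bound), `sd`, `slopes`.
#' @export
level_slope_null <- function(features, metric = "latency", z = 2.576) {
  lv <- features$level
  vals <- features[[metric]]
  perms <- permutations_of(seq_along(lv))
  slopes <- vapply(perms, function(p) {
    unname(coef(lm(vals[p] ~ lv))[2])
  }, numeric(1))
  list(band = z * sd(slopes), sd = sd(slopes), slopes = slopes)
}

permutations_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(permutations_of(v[-i]), function(p) c(v[i], p)))
  out
}

#' Holm-Sidak step-down multiple-comparison correction
#'
#' Sorts the p-values ascending, adjusts the i-th smallest as
#' `1 - (1 - p_i)^(m - i + 1)`, enforces monotonicity and restores the input
#' order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
holm_sidak_correct <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  ord <- order(p_values)
  adj <- 1 - (1 - p_values[ord])^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  adj[order(ord)]
}

#' Pearson correlations between paired feature tables
#'
#' Correlates each shared numeric column of two paired tables (e.g. click-ERP
#' versus speech-TRF wave V features across participants) and Holm-Sidak
#' corrects the p-values across the family.
#'
#' @param a,b Data frames with identical column names and matching rows.
#' @return Data frame with columns `feature`, `r`, `p`, `p_adj`.
#' @export
correlate_features <- function(a, b) {
  cols <- intersect(names(a), names(b))
  cols <- cols[vapply(cols, function(cn) is.numeric(a[[cn]]) &&
                        is.numeric(b[[cn]]), logical(1))]
  if (!length(cols)) stop("no shared numeric columns to correlate")
  if (nrow(a) != nrow(b) || nrow(a) < 3)
    stop("need >= 3 paired observations")
  rows <- lapply(cols, function(cn) {
    if (sd(a[[cn]]) == 0 || sd(b[[cn]]) == 0)
      stop("zero variance in feature ", cn)
    ct <- cor.test(a[[cn]], b[[cn]], method = "pearson")
    data.frame(feature = cn, r = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- holm_sidak_correct(out$p)
  out
}

#' Sweep TRF metrics over increasing data length
#'
#' Re-runs binning, normalization, the joint TRF fit and wave V extraction on
#' growing prefixes of a session, to chart how much data level-dependent
#' TRFs need.
#'
#' @param eeg An [eeg_recording()].
#' @param pred The session [predictor()].
#' @param schedule The session `trial_schedule`.
#' @param increments Prefix lengths in minutes.
#' @param lag_window Lag window in ms.
#' @param smooth_width Kernel smoothing width in ms.
#' @return Tidy data frame: one row per (datalength, level) with wave V
#'   features plus the latency and amplitude slopes for that datalength.
#' @export
datalength_sweep <- function(eeg, pred, schedule, increments,
                             lag_window = c(-10, 30), smooth_width = 4) {
  total_min <- length(eeg$series) / eeg$rate / 60
  if (max(increments) > total_min + 1e-9)
    stop("increment ", max(increments), " min exceeds the session length")
  rows <- lapply(increments, function(tmin) {
    n <- min(round(tmin * 60 * eeg$rate), length(eeg$series))
    sub_eeg <- eeg_recording(eeg$series[seq_len(n)], eeg$rate)
    sub_pred <- predictor(pred$series[seq_len(n)], pred$rate, pred$name)
    sub_sched <- schedule[schedule$start < tmin * 60, , drop = FALSE]
    sub_sched$end <- pmin(sub_sched$end, tmin * 60)
    attr(sub_sched, "levels") <- attr(schedule, "levels")
    class(sub_sched) <- class(schedule)
    bins <- normalize_bins(bin_by_ground_truth(sub_pred, sub_sched))
    fit <- estimate_trf(sub_eeg, bins, lag_window, keep_data = FALSE)
    feats <- wave_v_features(fit, smooth_width)
    feats$datalength <- tmin
    feats$latency_slope <- fit_level_trend(feats, "latency")$slope
    feats$amplitude_slope <- fit_level_trend(feats, "amplitude")$slope
    feats
  })
  out <- do.call(rbind, rows)
  out[, c("datalength", "level", "latency", "amplitude", "snr",
          "snr_display", "no_clear_peak", "latency_slope",
          "amplitude_slope")]
}
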