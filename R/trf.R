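# Joint level-dependent TRF estimation.  The EEG is modelled as
#   y = sum_l h_l * x_l + n
# with one impulse response h_l per intensity bin and x_l the normalized
# binned predictors.  The design matrix stacks lagged copies of all binned
# predictors (zero-padded at the record boundaries) and the unregularized
# least-squares solution beta = (X'X)^{-1} X'y is unstacked into the
# per-level kernels.  X'X and X'y are assembled in compiled code from
# cross-correlations of the binned predictors (exact, including the
# boundary rows), so the fit equals the dense normal-equations solution
# without ever materializing X.

#' Fit level-dependent temporal response functions
#'
#' The single model-fitting entry point of the package.  Returns an object of
#' class `ldtrf` with `print`, `summary`, `coef`, `plot`, `predict`,
#' `residuals` and `simulate` methods.
#'
#' @param eeg An [eeg_recording()] at the analysis rate.
#' @param bins A `level_bins` object (see [bin_by_ground_truth()] and
#'   [bin_by_inherent_intensity()]), normally normalized with
#'   [normalize_bins()].
#' @param lag_window Lag range in ms, default `c(-10, 30)` (matching the
#'   click ERP epoch window; the wave V search region lies inside it).
#' @param keep_data Store the EEG and bins in the fit (needed by `predict`
#'   and `residuals`); set `FALSE` for large batch runs.
#' @return An `ldtrf` object: `lags` (ms axis), `kernels` (lags x levels
#'   matrix), `labels`, `rate`, `smoothed`, `scale_factor`, `rank_deficient`.
#' @export
estimate_trf <- function(eeg, bins, lag_window = c(-10, 30),
                         keep_data = TRUE) {
  stopifnot(inherits(eeg, "eeg_recording"), inherits(bins, "level_bins"),
            eeg$rate == bins$rate,
            length(eeg$series) == length(bins$bin_index))
  rate <- eeg$rate
  kmin <- round(lag_window[1] / 1000 * rate)
  kmax <- round(lag_window[2] / 1000 * rate)
  if (kmin >= kmax) stop("infeasible lag window")
  K <- kmax - kmin + 1L
  L <- bins$n_bins
  xtx <- cpp_xtx_lagged(bins$binned, kmin, kmax)
  xty <- cpp_xty_lagged(bins$binned, eeg$series, kmin, kmax)
  sol <- solve_normal_equations(xtx, xty)
  kernels <- matrix(sol$beta, nrow = K, ncol = L,
                    dimnames = list(NULL, format(bins$labels)))
  structure(list(lags = (kmin:kmax) / rate * 1000, kernels = kernels,
                 n_lags = K, rate = rate, labels = bins$labels,
                 bin_mode = bins$mode, smoothed = FALSE, scale_factor = 1,
                 rank_deficient = sol$rank_deficient,
                 eeg = if (keep_data) eeg, bins = if (keep_data) bins,
                 call = match.call()),
            class = "ldtrf")
}

# Cholesky solve of the normal equations with an SVD pseudo-inverse fallback
# for singular X'X
solve_normal_equations <- function(xtx, xty) {
  beta <- tryCatch({
    ch <- chol(xtx)
    backsolve(ch, backsolve(ch, xty, transpose = TRUE))
  }, error = function(e) NULL)
  if (!is.null(beta))
    return(list(beta = as.numeric(beta), rank_deficient = FALSE))
  warning("X'X is singular or not positive definite; ",
          "using the pseudo-inverse (minimum-norm) solution")
  sv <- svd(xtx)
  tol <- max(dim(xtx)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  beta <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% xty) / sv$d[pos])
  list(beta = as.numeric(beta), rank_deficient = TRUE)
}

#' @export
print.ldtrf <- function(x, ...) {
  cat(sprintf("Level-dependent TRF fit (%s bins)\n", x$bin_mode))
  cat(sprintf("  %d levels x %d lags (%.1f to %.1f ms) @ %g Hz\n",
              ncol(x$kernels), x$n_lags, min(x$lags), max(x$lags), x$rate))
  cat(sprintf("  levels: %s\n", paste(format(x$labels), collapse = ", ")))
  if (x$smoothed) cat("  kernels smoothed\n")
  if (x$scale_factor != 1)
    cat(sprintf("  scaled to click-ERP r.m.s. (factor %.3g)\n",
                x$scale_factor))
  if (x$rank_deficient) cat("  note: rank-deficient fit (pseudo-inverse)\n")
  invisible(x)
}

#' @export
coef.ldtrf <- function(object, ...) object$kernels

#' @export
summary.ldtrf <- function(object, ...) {
  feats <- wave_v_features(object, ...)
  trends <- list(latency = fit_level_trend(feats, "latency"),
                 amplitude = fit_level_trend(feats, "amplitude"))
  structure(list(fit = object, features = feats, trends = trends),
            class = "summary.ldtrf")
}

#' @export
print.summary.ldtrf <- function(x, ...) {
  print(x$fit)
  cat("\nWave V features per level:\n")
  print(x$features, row.names = FALSE, digits = 4)
  cat(sprintf("\nLatency trend:  %+.4f ms/dB (intercept %.2f ms)\n",
              x$trends$latency$slope, x$trends$latency$intercept))
  cat(sprintf("Amplitude trend: %+.4f per dB (intercept %.3f)\n",
              x$trends$amplitude$slope, x$trends$amplitude$intercept))
  invisible(x)
}

#' @export
plot.ldtrf <- function(x, xlab = "Lag (ms)", ylab = "Amplitude (a.u.)",
                       main = "Level-dependent TRFs", ...) {
  pal <- grDevices::hcl.colors(ncol(x$kernels), "Zissou 1")
  graphics::matplot(x$lags, x$kernels, type = "l", lty = 1, col = pal,
                    xlab = xlab, ylab = ylab, main = main, ...)
  graphics::abline(v = c(4, 10), lty = 3, col = "grey60")
  graphics::legend("topright", legend = format(x$labels), col = pal,
                   lty = 1, cex = 0.8, bty = "n")
  invisible(x)
}

#' @export
predict.ldtrf <- function(object, bins = object$bins, ...) {
  if (is.null(bins))
    stop("no bins stored in the fit; refit with keep_data = TRUE ",
         "or supply bins")
  kmin <- round(min(object$lags) / 1000 * object$rate)
  yhat <- numeric(length(bins$bin_index))
  for (l in seq_len(bins$n_bins)) {
    x <- bins$binned[[l]]
    for (k in seq_len(object$n_lags)) {
      h <- object$kernels[k, l]
      if (h != 0) yhat <- yhat + h * shift_series(x, kmin + k - 1L)
    }
  }
  yhat
}

#' @export
fitted.ldtrf <- function(object, ...) predict(object)

#' @export
residuals.ldtrf <- function(object, ...) {
  if (is.null(object$eeg))
    stop("no EEG stored in the fit; refit with keep_data = TRUE")
  object$eeg$series - predict(object)
}

#' @export
simulate.ldtrf <- function(object, nsim = 1, seed = NULL, ...) {
  yhat <- predict(object)
  s <- sd(residuals(object))
  sims <- with_seed(if (is.null(seed)) 1L else seed, {
    replicate(nsim, yhat + rnorm(length(yhat), sd = s), simplify = FALSE)
  })
  lapply(sims, eeg_recording, rate = object$rate)
}

#' Smooth the fitted kernels
#'
#' Applies the moving Hamming-window average (see [smooth_waveform()]) to
#' every kernel; wave V features are extracted from the smoothed kernels.
#'
#' @param object An `ldtrf` fit.
#' @param width Window width in ms (4).
#' @return The fit with smoothed kernels and `smoothed = TRUE`.
#' @export
smooth_trf <- function(object, width = 4) {
  stopifnot(inherits(object, "ldtrf"))
  n <- round(width / 1000 * object$rate)
  object$kernels <- apply(object$kernels, 2, smooth_hamming, width = n)
  object$smoothed <- TRUE
  object
}

#' Estimate a click-evoked ERP
#'
#' Extracts EEG epochs around every click onset (rarefaction and
#' condensation epochs averaged together), then subtracts the mean over the
#' baseline window (lags up to 0 ms).  Epochs extending beyond the record are
#' dropped.
#'
#' @param eeg An [eeg_recording()].
#' @param train A `click_train` (onsets in the EEG's time base).
#' @param window Epoch window in ms, default `c(-10, 30)`.
#' @param level Optional level label stored with the ERP.
#' @return An object of class `click_erp`: `times` (ms), `waveform`,
#'   `level`, `n_epochs`, `rate`.
#' @export
estimate_click_erp <- function(eeg, train, window = c(-10, 30), level = NA) {
  stopifnot(inherits(eeg, "eeg_recording"), inherits(train, "click_train"))
  rate <- eeg$rate
  kmin <- round(window[1] / 1000 * rate)
  kmax <- round(window[2] / 1000 * rate)
  centers <- round(train$onsets * rate) + 1L
  ok <- centers + kmin >= 1L & centers + kmax <= length(eeg$series)
  if (!any(ok)) stop("no usable click epochs inside the record")
  if (any(!ok))
    message(sum(!ok), " click epochs extend beyond the record and were dropped")
  centers <- centers[ok]
  offsets <- kmin:kmax
  acc <- numeric(length(offsets))
  for (c0 in centers) acc <- acc + eeg$series[c0 + offsets]
  waveform <- acc / length(centers)
  times <- offsets / rate * 1000
  waveform <- waveform - mean(waveform[times <= 0])
  structure(list(times = times, waveform = waveform, level = level,
                 n_epochs = length(centers), rate = rate),
            class = "click_erp")
}

#' @export
print.click_erp <- function(x, ...) {
  cat(sprintf("<click_erp> %d epochs, %.1f..%.1f ms%s\n", x$n_epochs,
              min(x$times), max(x$times),
              if (!is.na(x$level)) sprintf(", level %s dB", x$level) else ""))
  invisible(x)
}

#' Export per-level kernels as CSV
#'
#' One column of lags in ms plus one amplitude column per level.
#'
#' @param object An `ldtrf` fit.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_trf_csv <- function(object, path) {
  df <- data.frame(lag_ms = object$lags, object$kernels, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
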