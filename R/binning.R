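# Intensity binning of a predictor: split the feature series into one
# series per level (zeroing everything presented at other levels), either
# from the experimental schedule or from quantiles of the smoothed predictor,
# then normalize each bin to unit r.m.s. over its support so every level
# drives the joint regression equally.

new_level_bins <- function(binned, labels, bin_index, rate, mode,
                           norm_scales = rep(1, length(binned))) {
  structure(list(n_bins = length(binned), labels = labels, binned = binned,
                 bin_index = bin_index, rate = rate, mode = mode,
                 norm_scales = norm_scales),
            class = "level_bins")
}

#' @export
print.level_bins <- function(x, ...) {
  cat(sprintf("<level_bins> %d bins (%s mode), %d samples @ %g Hz\n",
              x$n_bins, x$mode, length(x$bin_index), x$rate))
  counts <- tabulate(x$bin_index, nbins = x$n_bins)
  for (l in seq_len(x$n_bins))
    cat(sprintf("  bin %s: %.1f min of data, norm scale %.3g\n",
                format(x$labels[l]), counts[l] / x$rate / 60,
                x$norm_scales[l]))
  invisible(x)
}

# sample-wise bin index (0 = unassigned) from a schedule
schedule_bin_index <- function(schedule, n, rate, labels) {
  idx <- integer(n)
  for (i in seq_len(nrow(schedule))) {
    a <- floor(schedule$start[i] * rate) + 1L
    b <- min(floor(schedule$end[i] * rate), n)
    if (a <= b) idx[a:b] <- match(schedule$level[i], labels)
  }
  idx
}

#' Bin a predictor by the scheduled intensity levels
#'
#' For each level, a new predictor is formed by zeroing every sample that was
#' not presented at that level.  Before normalization the binned predictors
#' sum back to the original, sample-exactly.
#'
#' @param pred A [predictor()].
#' @param schedule A `trial_schedule` covering the predictor.
#' @return A `level_bins` object with one binned predictor per level,
#'   ordered from loudest to softest.
#' @export
bin_by_ground_truth <- function(pred, schedule) {
  stopifnot(inherits(pred, "predictor"), inherits(schedule, "trial_schedule"))
  n <- length(pred$series)
  labels <- sort(unique(schedule$level), decreasing = TRUE)
  idx <- schedule_bin_index(schedule, n, pred$rate, labels)
  n_out <- sum(idx == 0L)
  if (n_out > 0)
    message(n_out, " samples fall outside every scheduled segment ",
            "and are assigned to no bin")
  binned <- lapply(seq_along(labels), function(l) {
    x <- numeric(n)
    sel <- idx == l
    x[sel] <- pred$series[sel]
    x
  })
  new_level_bins(binned, labels, idx, pred$rate, mode = "ground_truth")
}

#' Bin a predictor by its inherent intensity
#'
#' The predictor is smoothed with a Hamming window (300 ms by default) as a
#' running measure of inherent intensity; bin edges are placed at the
#' equal-count quantiles of the smoothed series so every bin holds (up to
#' ties) the same amount of data.
#'
#' @param pred A [predictor()].
#' @param n_bins Number of intensity bins (8).
#' @param smooth_width Hamming smoothing width in seconds (0.3).
#' @return A `level_bins` object; bin labels are octile indices ordered from
#'   most to least intense.
#' @export
bin_by_inherent_intensity <- function(pred, n_bins = 8, smooth_width = 0.3) {
  stopifnot(inherits(pred, "predictor"), n_bins >= 2)
  s <- smooth_hamming(pred$series, round(smooth_width * pred$rate))
  if (sd(s) == 0)
    stop("constant predictor: inherent-intensity quantiles are degenerate")
  edges <- quantile(s, probs = seq_len(n_bins - 1) / n_bins, type = 7,
                    names = FALSE)
  if (any(diff(edges) <= 0))
    warning("tied quantile edges: bins will hold unequal amounts of data")
  # bin 1 = most intense so that labels order matches the ground-truth mode
  idx <- n_bins - findInterval(s, edges)
  n <- length(pred$series)
  binned <- lapply(seq_len(n_bins), function(l) {
    x <- numeric(n)
    sel <- idx == l
    x[sel] <- pred$series[sel]
    x
  })
  new_level_bins(binned, labels = seq_len(n_bins), idx, pred$rate,
                 mode = "inherent")
}

#' Normalize binned predictors to unit r.m.s.
#'
#' Each binned predictor is scaled so that its root mean square over its
#' non-zero support equals one, letting all
#' intensity levels contribute equally to the joint TRF fit.  The applied
#' scales are recorded in `norm_scales`, so the original predictor is
#' recoverable as `sum_l binned[[l]] / norm_scales[l]`.
#'
#' @param bins A `level_bins` object.
#' @return The normalized `level_bins`.
#' @export
normalize_bins <- function(bins) {
  stopifnot(inherits(bins, "level_bins"))
  for (l in seq_len(bins$n_bins)) {
    if (!any(bins$bin_index == l))
      stop("bin ", format(bins$labels[l]), " has no support")
    nz <- bins$binned[[l]] != 0
    if (!any(nz))
      stop("bin ", format(bins$labels[l]), " is all-zero on its support")
    r <- rms(bins$binned[[l]][nz])
    bins$binned[[l]] <- bins$binned[[l]] / r
    bins$norm_scales[l] <- bins$norm_scales[l] / r
  }
  bins
}

#' Reconstruct the original predictor from a bin set
#'
#' @param bins A `level_bins` object.
#' @return Numeric series: `sum_l binned[[l]] / norm_scales[l]`.
#' @export
unbin_predictor <- function(bins) {
  out <- numeric(length(bins$bin_index))
  for (l in seq_len(bins$n_bins))
    out <- out + bins$binned[[l]] / bins$norm_scales[l]
  out
}
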