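test_that("Hamming smoothing preserves constants and reduces variance", {
  rate <- 4096
  const <- rep(3, 400)
  expect_equal(smooth_waveform(const, 4, rate), const)

  imp <- numeric(401); imp[201] <- 1
  sm <- smooth_waveform(imp, 4, rate)
  # a bump with the window's shape whose interior weights sum to one
  w <- round(4 / 1000 * rate)
  expect_equal(sum(sm[(201 - w):(201 + w)]), 1, tolerance = 1e-9)
  expect_equal(which.max(sm), 201)

  set.seed(81)
  noise <- rnorm(20000)
  smn <- smooth_waveform(noise, 4, rate)
  w2 <- w + (1 - w %% 2)               # implementation centres an odd window
  wts <- 0.54 - 0.46 * cos(2 * pi * (0:(w2 - 1)) / (w2 - 1))
  wts <- wts / sum(wts)
  expect_equal(var(smn) / var(noise), sum(wts^2), tolerance = 0.05)
  expect_error(smooth_waveform(rep(1, 5), 4, rate), "shorter")
})

test_that("wave V detection picks the largest local maximum in 4-10 ms", {
  rate <- 4096
  lags <- seq(-10, 30, by = 1000 / rate)
  g <- function(mu, h) h * exp(-(lags - mu)^2 / (2 * 0.6^2))
  one <- g(lags[which.min(abs(lags - 6))], 1.3)  # centre on the lag grid
  pk <- detect_wave_v(one, lags)
  expect_equal(pk$latency, 6, tolerance = 1000 / rate)
  expect_equal(pk$amplitude, 1.3, tolerance = 1e-3)
  expect_false(pk$no_clear_peak)

  two <- g(5, 1) + g(8, 2)
  expect_equal(detect_wave_v(two, lags)$latency, 8, tolerance = 1000 / rate)

  ramp <- lags / 10
  pk3 <- detect_wave_v(ramp, lags)
  expect_true(pk3$no_clear_peak)
  expect_equal(pk3$latency, max(lags[lags <= 10]), tolerance = 1000 / rate)

  # latency is invariant under positive scaling and smoothing of a clean bump
  pk4 <- detect_wave_v(10 * smooth_waveform(one, 4, rate), lags)
  expect_equal(pk4$latency, pk$latency)
})

test_that("SNR follows the closed form and is scale invariant", {
  rate <- 4096
  lags <- seq(-10, 30, by = 1000 / rate)
  base <- rep(1, length(lags))
  make_w <- function(s) { w <- base; w[lags >= 3.5 & lags <= 8.5] <- sqrt(s); w }
  # S = 2N -> 0 dB (signal window sits inside the sqrt(2) plateau)
  expect_equal(compute_snr(make_w(2), lags, peak_latency = 6), 0)
  expect_equal(compute_snr(make_w(11), lags, peak_latency = 6), 10)
  expect_equal(compute_snr(make_w(1.5), lags, peak_latency = 6),
               10 * log10(0.5), tolerance = 1e-9)
  expect_equal(compute_snr(3 * make_w(1.5), lags, 6),
               compute_snr(make_w(1.5), lags, 6))
  expect_identical(compute_snr(make_w(0.5), lags, 6), -Inf)
  expect_error(compute_snr(0 * base, lags, 6), "zero noise power")
})

test_that("level trends follow ordinary least squares", {
  f <- data.frame(level = c(36, 48, 60, 72), latency = c(8, 7, 6, 5),
                  amplitude = c(1, 1, 1, 1))
  tr <- fit_level_trend(f, "latency")
  expect_equal(tr$slope, -1 / 12)
  expect_equal(tr$intercept, 11)
  expect_equal(fit_level_trend(f, "amplitude")$slope, 0)
  two <- data.frame(level = c(40, 70), latency = c(7, 5.5))
  tr2 <- fit_level_trend(two, "latency")
  expect_equal(tr2$intercept + tr2$slope * c(40, 70), c(7, 5.5))
  expect_error(fit_level_trend(f[1, ], "latency"), ">= 2 levels")
})

test_that("Holm-Sidak adjustment matches the step-down formula", {
  expect_equal(holm_sidak_correct(0.03), 0.03)
  expect_equal(holm_sidak_correct(c(0.01, 0.04)),
               c(1 - 0.99^2, max(1 - 0.99^2, 0.04)))
  expect_equal(holm_sidak_correct(c(0, 0, 0)), c(0, 0, 0))
  # monotone in the sorted order and order-preserving
  set.seed(91)
  p <- runif(7)
  adj <- holm_sidak_correct(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj >= p - 1e-12))
  expect_error(holm_sidak_correct(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("feature correlations match the covariance formula", {
  a <- data.frame(latency = c(5, 6, 7, 6.5, 5.5), amplitude = c(2, 1, 3, 2, 1))
  same <- correlate_features(a, a)
  expect_true(all(abs(same$r - 1) < 1e-12))
  flip <- a; flip$latency <- -a$latency; flip$amplitude <- -a$amplitude
  expect_true(all(abs(correlate_features(a, flip)$r + 1) < 1e-12))
  b <- data.frame(latency = c(5.2, 6.1, 6.8, 6.2, 5.9),
                  amplitude = c(1.8, 1.2, 2.9, 2.2, 1.4))
  got <- correlate_features(a, b)
  manual <- sum((a$latency - mean(a$latency)) * (b$latency - mean(b$latency))) /
    sqrt(sum((a$latency - mean(a$latency))^2) *
         sum((b$latency - mean(b$latency))^2))
  expect_equal(got$r[got$feature == "latency"], manual)
  expect_equal(got$p_adj, holm_sidak_correct(got$p))
  expect_error(correlate_features(a, transform(b, amplitude = 1)), "variance")
})

test_that("a common scalar matches TRF r.m.s. to the click ERPs", {
  rate <- 4096
  ses <- small_session(minutes = 2, seed = 95,
                       noise = noise_spec(rms = 0, white_rms = 0,
                                          artifact_rate = 0))
  bins <- normalize_bins(bin_by_ground_truth(ses$predictor, ses$schedule))
  fit <- estimate_trf(ses$eeg, bins, keep_data = FALSE)
  erp <- structure(list(times = fit$lags, waveform = rowMeans(fit$kernels),
                        level = 66, n_epochs = 100, rate = rate),
                   class = "click_erp")
  scaled <- scale_to_erp(list(fit), list(erp))
  expect_equal(scaled[[1]]$scale_factor, 1, tolerance = 1e-9)
  half <- fit; half$kernels <- fit$kernels / 2
  scaled2 <- scale_to_erp(list(half), list(erp))
  expect_equal(scaled2[[1]]$scale_factor, 2, tolerance = 1e-9)
  # latencies unchanged by scaling
  expect_equal(wave_v_features(scaled2[[1]])$latency,
               wave_v_features(fit)$latency)
})

test_that("datalength sweep is consistent with the full pipeline", {
  ses <- small_session(minutes = 4, seed = 97,
                       noise = noise_spec(artifact_rate = 0))
  sw <- datalength_sweep(ses$eeg, ses$predictor, ses$schedule,
                         increments = c(2, 4))
  expect_equal(nrow(sw), 8)
  # the full-length rows equal the non-sweep pipeline output
  bins <- normalize_bins(bin_by_ground_truth(ses$predictor, ses$schedule))
  fit <- estimate_trf(ses$eeg, bins, keep_data = FALSE)
  feats <- wave_v_features(fit)
  full <- sw[sw$datalength == 4, ]
  expect_equal(full$latency, feats$latency)
  expect_equal(full$amplitude, feats$amplitude)
  # a balanced prefix uses equal time per level
  idx2 <- ldtrf:::schedule_bin_index(ses$schedule, 2 * 60 * ses$eeg$rate,
                                     ses$eeg$rate, sort(unique(ses$schedule$level),
                                                        decreasing = TRUE))
  counts <- tabulate(idx2, 4)
  expect_true(all(abs(counts - 30 * ses$eeg$rate) <= 8))
  expect_error(datalength_sweep(ses$eeg, ses$predictor, ses$schedule, 10),
               "exceeds")
})

test_that("wave V SNR at the loudest level grows with datalength", {
  diffs <- sapply(1:4, function(s) {
    ses <- small_session(minutes = 4, seed = 200 + s,
                         noise = noise_spec(artifact_rate = 0))
    sw <- datalength_sweep(ses$eeg, ses$predictor, ses$schedule,
                           increments = c(2, 4))
    loud <- max(sw$level)
    sw$snr[sw$datalength == 4 & sw$level == loud] -
      sw$snr[sw$datalength == 2 & sw$level == loud]
  })
  expect_gt(median(diffs), 0)
})
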