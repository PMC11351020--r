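test_that("speech-like predictor has the advertised structure", {
  pred <- make_speech_like_predictor(120, rate = 512, seed = 7)
  expect_true(all(pred$series >= 0))
  expect_true(all(is.finite(pred$series)))
  # pauses: fraction of time where the smoothed predictor sits at the noise
  # floor (well below the median speech level)
  sm <- ldtrf:::smooth_hamming(pred$series, round(0.3 * 512))
  pause_frac <- mean(sm < 0.1 * median(sm[sm > quantile(sm, 0.3)]))
  expect_gt(pause_frac, 0.05)
  expect_lt(pause_frac, 0.3)
  # octile binning of the smoothed series is non-degenerate
  b8 <- bin_by_inherent_intensity(pred, n_bins = 8)
  expect_true(all(tabulate(b8$bin_index, 8) > 0))
  # deterministic given the seed
  again <- make_speech_like_predictor(120, rate = 512, seed = 7)
  expect_identical(pred$series, again$series)
})

test_that("ground-truth kernels enforce the physiological trend", {
  gt <- ground_truth_kernels()
  expect_equal(gt$params$level, c(72, 60, 48, 36))
  expect_true(all(diff(gt$params$latency) > 0))   # loudest first
  km <- kernel_waveforms(gt, 4096)
  lags <- attr(km, "lags_ms")
  for (l in 1:4) {
    expect_equal(lags[which.max(km[, l])], gt$params$latency[l],
                 tolerance = 0.15)
    # sampled maximum sits within one lag step of the continuous peak
    expect_equal(max(km[, l]), gt$params$amplitude[l], tolerance = 0.01)
  }
  expect_error(ground_truth_kernels(latencies = c(6, 6.3, 6.9, 7.5) * 0 + 6),
               "strictly decrease")
  expect_error(ground_truth_kernels(amplitudes = c(1, 1, 1, 1)),
               "strictly increase")
  expect_error(ground_truth_kernels(latencies = c(3, 6.3, 6.9, 7.5)), "4-10")
})

test_that("forward and inverse directions agree at zero noise", {
  # single level, zero noise: the estimator must reproduce the kernel from
  # EEG generated by the independent forward implementation
  rate <- 2048
  sched <- build_trial_schedule(2, 0, 60, seed = 15)
  gt <- ground_truth_kernels(levels = 60, latencies = 6.5, amplitudes = 2)
  ses <- simulate_session(sched, gt, noise_spec(rms = 0, white_rms = 0,
                                                artifact_rate = 0),
                          seed = 16, rate = rate)
  bins <- normalize_bins(bin_by_ground_truth(ses$predictor, sched))
  fit <- estimate_trf(ses$eeg, bins, keep_data = FALSE)
  km <- kernel_waveforms(gt, rate)
  lag0 <- which(abs(fit$lags) < 1e-9)
  est <- fit$kernels[lag0:(lag0 + nrow(km) - 1), 1]
  expect_lt(max(abs(est - km[, 1])) / max(km[, 1]), 1e-6)
})

test_that("fitted kernels reproduce the latency ordering under noise", {
  ses <- small_session(minutes = 8, seed = 120)
  rej <- reject_artifacts(ses$eeg, list(ses$predictor))
  bins <- normalize_bins(bin_by_ground_truth(rej$predictors[[1]],
                                             ses$schedule))
  fit <- estimate_trf(rej$eeg, bins, keep_data = FALSE)
  feats <- wave_v_features(fit)
  expect_true(all(diff(feats$latency) > 0))      # loudest first: increasing
  expect_true(all(diff(feats$amplitude) < 0))
  # artifacts at the default rate exclude a low-single-digit percentage,
  # the range reported in practice for this kind of recording
  expect_gt(rej$fraction_excluded, 0.004)
  expect_lt(rej$fraction_excluded, 0.06)
})

test_that("halving noise power raises wave V SNR by about 3 dB", {
  # baseline noise power N in the SNR formula scales with the squared noise
  # r.m.s.; a sqrt(2) change in noise r.m.s. shifts the (S - N)/N ratio by
  # about a factor two when S dominates
  snr_at <- function(noise_rms, seed) {
    sched <- build_trial_schedule(0, 6, c(72, 60, 48, 36), seed = seed)
    ses <- simulate_session(sched,
                            noise = noise_spec(rms = noise_rms,
                                               white_rms = noise_rms / 4,
                                               artifact_rate = 0),
                            seed = seed + 1)
    bins <- normalize_bins(bin_by_ground_truth(ses$predictor, ses$schedule))
    fit <- estimate_trf(ses$eeg, bins, keep_data = FALSE)
    wave_v_features(fit)$snr[1]
  }
  deltas <- sapply(c(301, 302, 303), function(s)
    snr_at(60, s) - snr_at(60 * sqrt(2), s))
  expect_gt(mean(deltas), 1)
  expect_lt(mean(deltas), 5)
})

test_that("the adaptive predictor equalizes level gains", {
  ses <- small_session(minutes = 4, seed = 130,
                       noise = noise_spec(artifact_rate = 0))
  ad <- make_adaptive_predictor(ses$predictor, ses$schedule, ses$kernels)
  idx <- ldtrf:::schedule_bin_index(ses$schedule, length(ad$series),
                                    ad$rate, ses$kernels$params$level)
  rms_l <- sapply(1:4, function(l) {
    v <- ad$series[idx == l]; sqrt(mean(v[v != 0]^2))
  })
  expect_true(max(rms_l) / min(rms_l) < 1.05)
})

test_that("click sessions carry the full epoch count and recover kernels", {
  gt <- ground_truth_kernels(levels = c(66, 60, 48, 36))
  ses <- simulate_click_session(gt, noise_spec(rms = 0, white_rms = 0,
                                               artifact_rate = 0),
                                seed = 140, rate = 4096)
  expect_equal(sum(sapply(ses$trains, function(tr) length(tr$onsets))), 21120)
  erp <- estimate_click_erp(ses$eeg, ses$trains[[1]], level = 66)
  pk <- detect_wave_v(erp$waveform, erp$times)
  expect_equal(pk$latency, gt$params$latency[1], tolerance = 0.25)
  expect_equal(mean(erp$waveform[erp$times <= 0]), 0)
})

test_that("click ERP SNR grows roughly as the epoch count", {
  gt <- ground_truth_kernels(levels = 66, latencies = 6, amplitudes = 2)
  rate <- 4096
  set.seed(150)
  tr <- generate_click_train(120, 44, sample_rate = rate, seed = 151)
  n <- 120 * rate
  imp <- numeric(n); imp[round(tr$onsets * rate) + 1] <- 1
  h <- kernel_waveforms(gt, rate)[, 1]
  y <- ldtrf:::causal_conv(imp, h) + rnorm(n, sd = 50)
  eeg <- eeg_recording(c(y, rnorm(round(0.05 * rate), sd = 50)), rate)
  sub_train <- function(k) {
    t2 <- tr; t2$onsets <- tr$onsets[seq_len(k)]; t2
  }
  snr_of <- function(k) {
    erp <- estimate_click_erp(eeg, sub_train(k), level = 66)
    w <- smooth_waveform(erp$waveform, 4, rate)
    pk <- detect_wave_v(w, erp$times)
    compute_snr(w, erp$times, pk$latency)
  }
  delta <- snr_of(5280) - snr_of(660)
  # 8x epochs: averaging noise power drops 8x -> ~9 dB when averaging noise
  # dominates, reduced by the deterministic overlap of adjacent click
  # responses at 44/s (a noise floor that does not average out)
  expect_gt(delta, 2)
  expect_lt(delta, 14)
})

test_that("sessions serialize to text and container files", {
  ses <- small_session(minutes = 2, seed = 160,
                       noise = noise_spec(artifact_rate = 0))
  out <- tempfile("session")
  paths <- write_session(ses, out)
  expect_true(all(file.exists(paths)))
  sched <- read_schedule(paths["schedule"])
  expect_equal(as.data.frame(sched), as.data.frame(ses$schedule))
  gt <- jsonlite::read_json(paths["kernels"], simplifyVector = TRUE)
  expect_equal(gt$params$latency, ses$kernels$params$latency)
})
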