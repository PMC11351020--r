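test_that("impulse-train deconvolution is exact without noise", {
  rate <- 1024
  n <- 20 * rate
  set.seed(51)
  x <- numeric(n)
  x[sample(200:(n - 200), 400)] <- 1
  h <- kernel_waveforms(ground_truth_kernels(levels = 60, latencies = 6,
                                             amplitudes = 1.5), rate)[, 1]
  y <- ldtrf:::causal_conv(x, h)
  bins <- ldtrf:::new_level_bins(list(x), labels = 60,
                                 bin_index = rep(1L, n), rate = rate,
                                 mode = "ground_truth")
  fit <- estimate_trf(eeg_recording(y, rate), bins)
  lag0 <- which(abs(fit$lags) < 1e-9)
  est <- fit$kernels[lag0:(lag0 + length(h) - 1), 1]
  expect_lt(max(abs(est - h)), 1e-8)
  # acausal lags stay at zero
  expect_lt(max(abs(fit$kernels[1:(lag0 - 1), 1])), 1e-8)
})

test_that("compiled normal equations match the dense oracle", {
  set.seed(52)
  for (case in 1:5) {
    N <- sample(100:400, 1)
    kmin <- sample(-8:0, 1); kmax <- sample(2:12, 1)
    L <- sample(1:3, 1)
    preds <- lapply(seq_len(L), function(l) {
      x <- numeric(N); idx <- sample(N, N %/% 3); x[idx] <- runif(length(idx)); x
    })
    y <- rnorm(N)
    beta_o <- dense_trf_oracle(preds, y, kmin, kmax)
    xtx <- ldtrf:::cpp_xtx_lagged(preds, kmin, kmax)
    xty <- ldtrf:::cpp_xty_lagged(preds, y, kmin, kmax)
    beta <- solve(xtx, xty)
    expect_lt(max(abs(beta - beta_o)) / max(abs(beta_o)), 1e-8)
  }
})

test_that("joint fitting beats separate per-level fits on interleaved bins", {
  rate <- 512
  n <- 120 * rate
  set.seed(53)
  x <- ldtrf:::speech_like_series(n, rate)
  pred <- predictor(x, rate)
  bins <- normalize_bins(bin_by_inherent_intensity(pred, n_bins = 2,
                                                   smooth_width = 0.3))
  gt <- ground_truth_kernels(levels = c(2, 1), latencies = c(5.7, 7.5),
                             amplitudes = c(2, 1))
  km <- kernel_waveforms(gt, rate)
  y <- ldtrf:::causal_conv(bins$binned[[1]], km[, 1]) +
    ldtrf:::causal_conv(bins$binned[[2]], km[, 2]) + rnorm(n, sd = 3)
  eeg <- eeg_recording(y, rate)
  joint <- estimate_trf(eeg, bins, keep_data = FALSE)
  lag0 <- which(abs(joint$lags) < 1e-9)
  idx <- lag0:(lag0 + nrow(km) - 1)
  err_joint <- 0; err_sep <- 0
  for (l in 1:2) {
    solo <- ldtrf:::new_level_bins(bins$binned[l], labels = l,
                                   bin_index = as.integer(bins$bin_index == l),
                                   rate = rate, mode = "inherent")
    sep <- estimate_trf(eeg, solo, keep_data = FALSE)
    err_joint <- err_joint + sqrt(mean((joint$kernels[idx, l] - km[, l])^2))
    err_sep <- err_sep + sqrt(mean((sep$kernels[idx, 1] - km[, l])^2))
  }
  expect_lt(err_joint, err_sep)
  expect_lt(err_joint / sum(apply(km, 2, max)), 0.05)
})

test_that("collinear bins fall back to the pseudo-inverse with a warning", {
  rate <- 256
  n <- 10 * rate
  set.seed(54)
  x <- pmax(rnorm(n), 0)
  bins <- ldtrf:::new_level_bins(list(x, x), labels = c(1, 2),
                                 bin_index = rep(1L, n), rate = rate,
                                 mode = "inherent")
  y <- rnorm(n)
  expect_warning(fit <- estimate_trf(eeg_recording(y, rate), bins,
                                     lag_window = c(-2, 5)),
                 "pseudo-inverse")
  expect_true(fit$rank_deficient)
  expect_true(all(is.finite(fit$kernels)))
  # minimum-norm solution splits the response between the duplicate bins
  expect_equal(fit$kernels[, 1], fit$kernels[, 2], tolerance = 1e-8)
})

test_that("fit methods are coherent: predict, residuals, summary, simulate", {
  ses <- small_session(minutes = 2, seed = 61,
                       noise = noise_spec(rms = 0, white_rms = 0,
                                          artifact_rate = 0))
  bins <- normalize_bins(bin_by_ground_truth(ses$predictor, ses$schedule))
  fit <- estimate_trf(ses$eeg, bins)
  expect_s3_class(fit, "ldtrf")
  expect_equal(dim(coef(fit)), c(fit$n_lags, 4))
  # noise-free: fitted values explain the EEG
  res <- residuals(fit)
  expect_lt(sd(res) / sd(ses$eeg$series), 1e-6)
  out <- capture.output(print(summary(fit)))
  expect_true(any(grepl("Latency trend", out)))
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "eeg_recording")
  expect_equal(length(sims[[1]]$series), length(ses$eeg$series))
})

test_that("click ERPs average to the kernel and obey the epoch count", {
  rate <- 4096
  tr <- generate_click_train(120, 44, sample_rate = rate, seed = 71)
  expect_equal(length(tr$onsets), 5280)
  h <- kernel_waveforms(ground_truth_kernels(levels = 66, latencies = 6.2,
                                             amplitudes = 2), rate)[, 1]
  n <- 120 * rate + round(0.05 * rate)  # record outlasts the last epoch
  imp <- numeric(n)
  imp[round(tr$onsets * rate) + 1] <- 1
  y <- ldtrf:::causal_conv(imp, h)
  erp <- estimate_click_erp(eeg_recording(y, rate), tr)
  expect_equal(erp$n_epochs, 5280)
  # baseline is exactly zero-mean
  expect_equal(mean(erp$waveform[erp$times <= 0]), 0)
  # noise-free ERP reproduces the kernel up to the deterministic overlap of
  # adjacent click responses at 44/s (and its removal by baseline correction)
  pk <- detect_wave_v(erp$waveform, erp$times)
  expect_equal(pk$latency, 6.2, tolerance = 0.15)
  expect_equal(pk$amplitude, 2, tolerance = 0.25)
})
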