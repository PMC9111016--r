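test_that("simulated envelopes are nonnegative, deterministic and speech-like", {
  e <- simulate_envelope(60, 64, seed = 5)
  expect_length(e$samples, 3840)
  expect_true(all(e$samples >= 0))
  expect_identical(e$samples, simulate_envelope(60, 64, seed = 5)$samples)
  expect_false(identical(e$samples, simulate_envelope(60, 64, seed = 6)$samples))
  # modulation power concentrated below 8 Hz (periodogram oracle)
  P <- Mod(stats::fft(e$samples))^2
  f <- (seq_along(P) - 1) * 64 / length(P)
  below <- f < 8 | f > 64 - 8
  expect_gte(sum(P[below]) / sum(P), 0.95)
  expect_error(simulate_envelope(-1, 64), "must be > 0")
  expect_error(simulate_envelope(60, 0), "must be > 0")
})

test_that("degenerate single-channel subject equals the pure kernel response", {
  cfg <- cohort_config(n_subjects = 1, n_left = 1, duration_s = 60,
                       eeg_rate_hz = 64, audio_rate_hz = 64, n_channels = 1,
                       gain_att = 3, gain_ign = 0, shared_component_gain = 0,
                       noise_sd = 0, alpha_drift = 0, n_blocks = 1)
  env <- simulate_envelope(60, 64, seed = 2)
  topo <- list(att = 1, ign = 1, shared_left = 1, shared_right = 1,
               noise_mix = matrix(1, 1, 1))
  rec <- simulate_subject(env, env, cfg, subject_seed = 9, topographies = topo)
  k <- earaad:::response_kernel(64, cfg$kernel_lags_ms)
  expected <- cfg$gain_att * earaad:::causal_fir(k, env$samples)
  expect_equal(as.numeric(rec$data[1, ]), expected, tolerance = 1e-12)
})

test_that("alpha drift raises late-session 8-12 Hz band power", {
  cfg <- cohort_config(n_subjects = 1, n_left = 1, duration_s = 300,
                       gain_att = 0, gain_ign = 0, shared_component_gain = 0,
                       noise_sd = 0.3, alpha_drift = 0.2, n_blocks = 1)
  env <- simulate_envelope(300, 250, seed = 2)
  rec <- simulate_subject(env, env, cfg, subject_seed = 3)
  fs <- rec$rate_hz
  bp <- function(idx) mean(apply(rec$data[, idx, drop = FALSE], 1,
                                 earaad:::band_power, rate_hz = fs, lo = 8, hi = 12))
  first <- bp(1:(60 * fs))
  last <- bp((ncol(rec$data) - 60 * fs + 1):ncol(rec$data))
  expect_gt(last, first)
})

test_that("same-stream subjects share channel-averaged signal", {
  cors <- vapply(1:10, function(r) {
    cfg <- cohort_config(n_subjects = 2, n_left = 2, duration_s = 300,
                         n_blocks = 1, noise_sd = 0.3, seed = 100 + r)
    coh <- simulate_cohort(cfg)
    cor(colMeans(coh$recordings[[1]]$data), colMeans(coh$recordings[[2]]$data))
  }, numeric(1))
  expect_gt(mean(cors), 0)
})

test_that("cohorts assign attended streams in order and are reproducible", {
  cfg <- cohort_config(n_subjects = 4, n_left = 2, duration_s = 120,
                       n_blocks = 2, seed = 77)
  coh <- simulate_cohort(cfg)
  expect_length(coh$recordings, 4)
  expect_identical(vapply(coh$recordings, `[[`, "", "attended"),
                   c("left", "left", "right", "right"))
  coh2 <- simulate_cohort(cfg)
  expect_identical(coh$recordings[[3]]$data, coh2$recordings[[3]]$data)
  expect_identical(coh$env_left$samples, coh2$env_left$samples)
  expect_length(coh$recordings[[1]]$block_bounds, 2)
})

test_that("burst injection follows its Poisson and amplitude contract", {
  set.seed(1)
  rec <- recording(matrix(rnorm(4 * 6000), 4), 100, paste0("ch", 1:4))
  none <- inject_bursts(rec, 0, 10, seed = 3)
  expect_identical(none$recording$data, rec$data)
  expect_false(any(none$burst_mask))

  # rate 2/min on a 10-min recording: expected 20 bursts, count within the
  # Poisson 99% interval (counted directly from mask runs)
  rec10 <- recording(matrix(rnorm(4 * 100 * 600), 4), 100, paste0("ch", 1:4))
  ib <- inject_bursts(rec10, 2, 10, seed = 11)
  runs <- rle(ib$burst_mask)
  n_bursts <- sum(runs$values)
  expect_gte(n_bursts, qpois(0.005, 20))
  expect_lte(n_bursts, qpois(0.995, 20))

  rms_in <- sqrt(mean(ib$recording$data[, ib$burst_mask]^2))
  rms_out <- sqrt(mean(ib$recording$data[, !ib$burst_mask]^2))
  expect_gt(rms_in, 3 * rms_out)
  expect_error(inject_bursts(rec, 2, 1), "must be > 1")
})

test_that("attended stream is identifiable by direct cross-correlation", {
  cfg <- cohort_config(n_subjects = 1, n_left = 1, duration_s = 600,
                       n_blocks = 1, seed = 7)
  coh <- simulate_cohort(cfg)
  pre <- preprocess_decoding(coh$recordings[[1]], asr = FALSE)
  ea <- resample_to(coh$env_left, 64)
  ei <- resample_to(coh$env_right, 64)
  ss <- segment_recording(pre, ea, ei)
  topo <- coh$topographies$att
  xcmax <- function(seg, env) {
    y <- as.numeric(topo %*% seg$eeg)
    n <- length(env)
    max(vapply(2:16, function(lag)
      abs(cor(env[1:(n - lag)], y[(1 + lag):n])), numeric(1)))
  }
  att <- vapply(ss$segments, function(s) xcmax(s, s$env_att), numeric(1))
  ign <- vapply(ss$segments, function(s) xcmax(s, s$env_ign), numeric(1))
  expect_gte(mean(att > ign), 0.9)
})

test_that("cohorts survive a plain-text write/read round trip", {
  cfg <- cohort_config(n_subjects = 2, n_left = 1, duration_s = 60,
                       eeg_rate_hz = 64, audio_rate_hz = 64, n_blocks = 1,
                       seed = 5)
  coh <- simulate_cohort(cfg)
  dir <- tempfile("cohort")
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_length(back$recordings, 2)
  expect_equal(back$recordings[[1]]$data, coh$recordings[[1]]$data,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(back$recordings[[2]]$attended, "right")
  expect_equal(back$env_left$samples, coh$env_left$samples, tolerance = 1e-6)
  expect_error(read_cohort(tempfile()), "manifest not found")
})
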