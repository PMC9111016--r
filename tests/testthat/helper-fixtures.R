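# Shared fixtures, built once per test run and memoised. The default cohort
# configuration IS the study condition set (8 subjects, 30 min, 16 channels);
# heavy derived objects (preprocessed segment sets, design-moment caches,
# grid evaluations) are reused across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

fixture_cohort <- function() {
  memo("cohort", function() simulate_cohort(cohort_config(seed = 1L)))
}

# decoding-path fixture: preprocessed 64 Hz segment sets, moment caches,
# per-subject LOO grids, and group/individual selections
fixture_decoding <- function() {
  memo("decoding", function() {
    coh <- fixture_cohort()
    grid <- enumerate_hypergrid()
    nS <- length(coh$recordings)
    seg_sets <- caches <- accs <- mses <- vector("list", nS)
    for (i in seq_len(nS)) {
      rec <- coh$recordings[[i]]
      pre <- preprocess_decoding(rec, asr = TRUE)
      att <- rec$attended
      ea <- resample_to(if (att == "left") coh$env_left else coh$env_right, 64)
      ei <- resample_to(if (att == "left") coh$env_right else coh$env_left, 64)
      seg_sets[[i]] <- segment_recording(pre, ea, ei)
      caches[[i]] <- grid_cache(seg_sets[[i]], grid)
      g <- evaluate_grid(grid = grid, cache = caches[[i]])
      accs[[i]] <- g$accuracy
      mses[[i]] <- g$mse
    }
    list(grid = grid, seg_sets = seg_sets, caches = caches,
         accs = accs, mses = mses,
         sel_group = select_hyperparameters(accs, mses, "group", grid),
         sel_ind = select_hyperparameters(accs, mses, "individual", grid))
  })
}

# ISC-path fixture: first-block 250 Hz views
fixture_isc_views <- function() {
  memo("isc_views", function() {
    coh <- fixture_cohort()
    lapply(coh$recordings, function(rec) {
      b <- rec$block_bounds[[1]]
      blk <- recording(rec$data[, (b[1] + 1):b[2], drop = FALSE], rec$rate_hz,
                       rec$channel_labels, rec$subject_id,
                       attended = rec$attended)
      preprocess_isc(blk, asr = TRUE)$data
    })
  })
}

fixture_labels <- function() {
  vapply(fixture_cohort()$recordings, `[[`, "", "attended")
}

# entropy-path fixture: drift-removed full recordings (the default cohort is
# burst-free, so subspace correction is a near no-op and is exercised
# separately by the burst fixture)
fixture_entropy_courses <- function() {
  memo("entropy", function() {
    coh <- fixture_cohort()
    lapply(coh$recordings, function(rec) {
      hp <- apply_filter(rec, filter_spec("highpass", 0.5, "butterworth", 4))
      entropy_timecourse(hp, character())
    })
  })
}

# small synthetic segment set for decoding unit tests: the EEG response
# lags the attended envelope by `lag` samples (cortical-delay convention)
toy_segments <- function(n_seg = 6, n = 400, n_ch = 2, rate = 64,
                         lag = 4, snr = 4, seed = 42) {
  set.seed(seed)
  smooth_env <- function(n) {
    e <- as.numeric(stats::filter(rnorm(n), rep(0.2, 5), sides = 1))
    e[is.na(e)] <- 0
    abs(e)
  }
  segs <- lapply(seq_len(n_seg), function(k) {
    ea <- smooth_env(n)
    ei <- smooth_env(n)
    eeg <- matrix(0, n_ch, n)
    for (c in seq_len(n_ch)) {
      eeg[c, ] <- snr * c(rep(0, lag), ea[seq_len(n - lag)]) + rnorm(n)
    }
    list(eeg = eeg, env_att = ea, env_ign = ei)
  })
  structure(list(segments = segs, rate_hz = rate, subject_id = "toy",
                 attended = "left", seg_len_s = n / rate),
            class = "segment_set")
}

expect_rel_error <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(max(abs(y)), 1e-12), tol)
}
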