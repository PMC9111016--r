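#' Configuration for a synthetic competing-speaker cohort
#'
#' Defines the generative conditions for a cohort of listeners attending one
#' of two simultaneously presented speech streams. Each subject's EEG is a
#' lagged-kernel cortical response to the attended envelope (gain
#' `gain_att`) plus a weaker response to the ignored envelope (`gain_ign`),
#' a stimulus-locked component shared across subjects attending the same
#' stream, spatially correlated 1/f background noise, and an alpha-band
#' (10 Hz) oscillation whose amplitude grows linearly over the session.
#'
#' @param n_subjects number of subjects.
#' @param n_left number of subjects attending the left stream (listed first).
#' @param duration_s session duration in seconds; must divide into 60-s
#'   segments.
#' @param eeg_rate_hz EEG sampling rate (Hz).
#' @param audio_rate_hz envelope sampling rate (Hz).
#' @param n_channels number of referenced EEG channels.
#' @param kernel_lags_ms length-2 span of the envelope-response kernel (ms).
#' @param gain_att,gain_ign response gains, `gain_att >= gain_ign >= 0`.
#' @param shared_component_gain gain of the stimulus-locked component shared
#'   by subjects attending the same stream.
#' @param noise_sd standard deviation of the 1/f background noise per channel.
#' @param alpha_drift linear growth of the 8-12 Hz oscillation amplitude, in
#'   noise-SD units per minute.
#' @param burst_rate_per_min Poisson rate of high-amplitude artifact bursts.
#' @param burst_amp_factor burst amplitude relative to channel SD (> 1).
#' @param n_blocks number of equal recording blocks (the paradigm uses
#'   10-min blocks).
#' @param seed master seed; all per-subject seeds derive from it.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 8, n_left = 4, duration_s = 1800,
                          eeg_rate_hz = 250, audio_rate_hz = 250,
                          n_channels = 16, kernel_lags_ms = c(0, 450),
                          gain_att = 3.0, gain_ign = 1.0,
                          shared_component_gain = 2.0, noise_sd = 1.0,
                          alpha_drift = 0.04, burst_rate_per_min = 0,
                          burst_amp_factor = 10, n_blocks = 3, seed = 1L) {
  cfg <- list(n_subjects = n_subjects, n_left = n_left, duration_s = duration_s,
              eeg_rate_hz = eeg_rate_hz, audio_rate_hz = audio_rate_hz,
              n_channels = n_channels, kernel_lags_ms = kernel_lags_ms,
              gain_att = gain_att, gain_ign = gain_ign,
              shared_component_gain = shared_component_gain,
              noise_sd = noise_sd, alpha_drift = alpha_drift,
              burst_rate_per_min = burst_rate_per_min,
              burst_amp_factor = burst_amp_factor,
              n_blocks = n_blocks, seed = as.integer(seed))
  if (cfg$n_left > cfg$n_subjects) stopf("n_left must be <= n_subjects")
  if (!(cfg$gain_att >= cfg$gain_ign && cfg$gain_ign >= 0)) {
    stopf("need gain_att >= gain_ign >= 0")
  }
  if (cfg$eeg_rate_hz <= 0 || cfg$audio_rate_hz <= 0) stopf("rates must be > 0")
  if (cfg$duration_s <= 0 || abs(cfg$duration_s / 60 - round(cfg$duration_s / 60)) > 1e-9) {
    stopf("duration_s must divide into 60-s segments")
  }
  if (cfg$duration_s %% cfg$n_blocks != 0) stopf("duration_s must divide into n_blocks")
  class(cfg) <- "cohort_config"
  cfg
}

#' Simulate a speech-like amplitude envelope
#'
#' Rectified low-pass-filtered Gaussian noise: modulation power is
#' concentrated below 8 Hz, as for a natural speech envelope. Deterministic
#' given `seed`.
#'
#' @param duration_s duration in seconds (> 0).
#' @param rate_hz sampling rate in Hz (> 0).
#' @param seed RNG seed.
#' @param stream stream label for the returned track.
#' @return An [envelope_track].
#' @export
simulate_envelope <- function(duration_s, rate_hz, seed = 1L, stream = "left") {
  if (duration_s <= 0 || rate_hz <= 0) stopf("duration and rate must be > 0")
  n <- round(duration_s * rate_hz)
  x <- with_seed(seed, {
    w <- stats::rnorm(n)
    bf <- signal::butter(4, min(5 / (rate_hz / 2), 0.95), "low")
    abs(signal::filtfilt(bf, w))
  })
  envelope_track(x, rate_hz, stream)
}

# difference-of-Gammas envelope-response kernel peaking near 120 ms,
# sampled over `lags_ms` at `rate_hz`, normalised to unit positive-lobe sum
response_kernel <- function(rate_hz, lags_ms = c(0, 450),
                            peak1_s = 0.120, peak2_s = 0.280, w2 = 0.5) {
  t <- seq(lags_ms[1], lags_ms[2], by = 1000 / rate_hz) / 1000
  t <- t[t >= 0]
  g <- function(tt, a, s) ifelse(tt <= 0, 0, tt^(a - 1) * exp(-tt / s))
  a1 <- 6; s1 <- peak1_s / (a1 - 1)
  a2 <- 8; s2 <- peak2_s / (a2 - 1)
  k <- g(t, a1, s1) / max(g(t, a1, s1)) - w2 * g(t, a2, s2) / max(g(t, a2, s2))
  k / sum(k[k > 0])
}

# kernel for the shared stimulus-locked component: different shape (broader,
# shallower undershoot) but the same ~120 ms peak region, so that all
# stimulus-locked energy is consistent with the generative response latency
shared_kernel <- function(rate_hz, lags_ms = c(0, 450)) {
  response_kernel(rate_hz, lags_ms, peak1_s = 0.130, peak2_s = 0.320, w2 = 0.3)
}

# cohort-level spatial structure: unit-norm response topographies, one
# shared-component topography per stream, and a positive-dominant noise
# mixing matrix (volume conduction / common reference make neighbouring
# referenced channels correlate positively)
cohort_topographies <- function(config) {
  with_seed(derive_seed(config$seed, 0L, 11L), {
    C <- config$n_channels
    # positive-biased draws: evoked-response topographies share a common
    # polarity across the referenced montage (they survive channel
    # averaging), while still varying in shape between components
    unitv <- function() { v <- stats::rnorm(C) + 1; v / sqrt(sum(v^2)) }
    K <- 6L
    mix <- matrix(abs(stats::rnorm(C * K, mean = 0.8, sd = 0.4)) + 0.2, C, K)
    mix <- sweep(mix, 2, sqrt(colSums(mix^2)), "/")
    list(att = unitv(), ign = unitv(),
         shared_left = unitv(), shared_right = unitv(),
         noise_mix = mix)
  })
}

#' Simulate one subject's EEG response to two competing envelopes
#'
#' The multichannel output is
#' `gain_att * (kernel (*) env_att)` and `gain_ign * (kernel (*) env_ign)`
#' spread over channels through fixed topographies, plus a shared
#' stimulus-locked component (common to all subjects attending the same
#' stream), spatially correlated 1/f noise, and a 10 Hz oscillation with
#' linearly growing amplitude. Deterministic given `subject_seed`.
#'
#' @param env_att,env_ign attended / ignored [envelope_track]s of equal
#'   length and rate.
#' @param config a [cohort_config].
#' @param subject_seed per-subject RNG seed.
#' @param topographies cohort-level topography set (from the internal
#'   generator by default; a list with `att`, `ign`, `shared_left`,
#'   `shared_right`, `noise_mix` to override, e.g. for degenerate tests).
#' @param subject_id,attended metadata for the returned [recording].
#' @return A [recording] at `config$eeg_rate_hz`.
#' @export
simulate_subject <- function(env_att, env_ign, config, subject_seed = 1L,
                             topographies = NULL, subject_id = "s01",
                             attended = "left") {
  if (length(env_att$samples) != length(env_ign$samples) ||
      env_att$rate_hz != env_ign$rate_hz) {
    stopf("attended and ignored envelopes must have equal length and rate")
  }
  fs <- config$eeg_rate_hz
  ea <- env_att$samples
  ei <- env_ign$samples
  if (env_att$rate_hz != fs) {
    ea <- resample_vector(ea, env_att$rate_hz, fs)
    ei <- resample_vector(ei, env_ign$rate_hz, fs)
  }
  n <- length(ea)
  C <- config$n_channels
  if (is.null(topographies)) topographies <- cohort_topographies(config)

  k <- response_kernel(fs, config$kernel_lags_ms)
  r_att <- causal_fir(k, ea)
  r_ign <- causal_fir(k, ei)
  X <- config$gain_att * (topographies$att %o% r_att) +
    config$gain_ign * (topographies$ign %o% r_ign)

  if (config$shared_component_gain > 0) {
    s <- causal_fir(shared_kernel(fs, config$kernel_lags_ms), ea)
    topo_s <- if (identical(attended, "right")) topographies$shared_right else topographies$shared_left
    X <- X + config$shared_component_gain * (topo_s %o% (s - mean(s)))
  }

  X <- X + with_seed(subject_seed, {
    N <- matrix(0, C, n)
    if (config$noise_sd > 0) {
      K <- ncol(topographies$noise_mix)
      src <- matrix(0, K, n)
      for (j in seq_len(K)) src[j, ] <- one_over_f_noise(n)
      shared <- topographies$noise_mix %*% src
      indep <- matrix(0, C, n)
      for (c in seq_len(C)) indep[c, ] <- one_over_f_noise(n)
      # ~70% shared, ~30% independent noise variance per channel
      N <- config$noise_sd * (sqrt(0.7) * shared / sqrt(mean(shared^2)) * 1 +
                                sqrt(0.3) * indep)
    }
    if (config$alpha_drift > 0) {
      tt <- (seq_len(n) - 1) / fs
      amp <- config$alpha_drift * tt / 60
      phase <- stats::runif(1, 0, 2 * pi)
      wch <- 0.5 + stats::runif(C)
      dph <- stats::runif(C, -0.5, 0.5)
      for (c in seq_len(C)) {
        N[c, ] <- N[c, ] + wch[c] * amp * sin(2 * pi * 10 * tt + phase + dph[c])
      }
    }
    N
  })

  block_len <- n %/% config$n_blocks
  bounds <- lapply(seq_len(config$n_blocks) - 1L,
                   function(b) c(b * block_len, (b + 1L) * block_len))
  labels <- if (C == 16) ceegrid_labels() else paste0("ch", seq_len(C))
  recording(X, fs, labels, subject_id = subject_id,
            block_bounds = bounds, attended = attended)
}

#' Simulate a full competing-speaker cohort
#'
#' All subjects hear the same two envelopes; the first `n_left` attend the
#' left stream, the rest the right stream. Per-subject seeds are derived
#' deterministically from `config$seed`.
#'
#' @param config a [cohort_config].
#' @return A `cohort` list with elements `recordings` (list of [recording]),
#'   `env_left`, `env_right` ([envelope_track]s), `topographies`, `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  env_left <- simulate_envelope(config$duration_s, config$audio_rate_hz,
                                seed = derive_seed(config$seed, 0L, 1L),
                                stream = "left")
  env_right <- simulate_envelope(config$duration_s, config$audio_rate_hz,
                                 seed = derive_seed(config$seed, 0L, 2L),
                                 stream = "right")
  topo <- cohort_topographies(config)
  recs <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    att <- if (i <= config$n_left) "left" else "right"
    ea <- if (att == "left") env_left else env_right
    ei <- if (att == "left") env_right else env_left
    rec <- simulate_subject(ea, ei, config,
                            subject_seed = derive_seed(config$seed, i, 3L),
                            topographies = topo,
                            subject_id = sprintf("s%02d", i), attended = att)
    if (config$burst_rate_per_min > 0) {
      rec <- inject_bursts(rec, config$burst_rate_per_min,
                           config$burst_amp_factor,
                           seed = derive_seed(config$seed, i, 4L))$recording
    }
    recs[[i]] <- rec
  }
  structure(list(recordings = recs, env_left = env_left, env_right = env_right,
                 topographies = topo, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d left / %d right), %g s @ %g Hz, %d channels\n",
              x$config$n_subjects, x$config$n_left,
              x$config$n_subjects - x$config$n_left,
              x$config$duration_s, x$config$eeg_rate_hz, x$config$n_channels))
  invisible(x)
}

#' Inject high-amplitude broadband artifact bursts
#'
#' Adds short (0.2-1 s) broadband transients at Poisson-distributed times on
#' random channel subsets, emulating movement/muscle artifacts for testing
#' artifact subspace reconstruction.
#'
#' @param rec a [recording].
#' @param burst_rate_per_min expected bursts per minute (>= 0).
#' @param burst_amp_factor burst amplitude as a multiple of the channel SD
#'   (> 1).
#' @param seed RNG seed.
#' @return list with `recording` (contaminated copy) and `burst_mask`
#'   (logical per-sample vector, TRUE where any channel is contaminated).
#' @export
inject_bursts <- function(rec, burst_rate_per_min, burst_amp_factor = 10,
                          seed = 1L) {
  stopifnot(inherits(rec, "recording"))
  if (burst_amp_factor <= 1) stopf("burst_amp_factor must be > 1")
  n <- n_samples(rec)
  fs <- rec$rate_hz
  mask <- logical(n)
  if (burst_rate_per_min <= 0) {
    return(list(recording = rec, burst_mask = mask))
  }
  X <- rec$data
  C <- nrow(X)
  ch_sd <- apply(X, 1, stats::sd)
  with_seed(seed, {
    n_bursts <- stats::rpois(1, burst_rate_per_min * n / fs / 60)
    if (n_bursts > 0) {
      for (b in seq_len(n_bursts)) {
        dur <- round(stats::runif(1, 0.2, 1) * fs)
        start <- sample.int(max(n - dur, 1), 1)
        idx <- start:min(start + dur - 1, n)
        n_ch <- max(1L, round(stats::runif(1, 0.25, 0.75) * C))
        chs <- sample.int(C, n_ch)
        win <- sin(pi * seq_along(idx) / length(idx))^2  # smooth on/offset
        for (c in chs) {
          X[c, idx] <- X[c, idx] +
            burst_amp_factor * ch_sd[c] * win * stats::rnorm(length(idx))
        }
        mask[idx] <- TRUE
      }
    }
  })
  out <- rec
  out$data <- X
  list(recording = out, burst_mask = mask)
}

#' Write / read a cohort as plain-text files
#'
#' Recordings and envelopes are written as CSV (one file per subject and per
#' stream) with a JSON manifest holding subject ids, attended labels, rates,
#' block bounds and file paths.
#'
#' @param cohort a `cohort` from [simulate_cohort].
#' @param dir output directory (created if missing).
#' @return `write_cohort`: the manifest path, invisibly. `read_cohort`: a
#'   `cohort` list (without topographies).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(cohort$config), subjects = list(),
                   envelopes = list())
  for (stream in c("left", "right")) {
    env <- cohort[[paste0("env_", stream)]]
    path <- file.path(dir, paste0("envelope_", stream, ".csv"))
    utils::write.csv(data.frame(sample = env$samples), path, row.names = FALSE)
    manifest$envelopes[[stream]] <-
      list(file = basename(path), rate_hz = env$rate_hz)
  }
  for (rec in cohort$recordings) {
    path <- file.path(dir, paste0(rec$subject_id, ".csv"))
    df <- as.data.frame(t(rec$data))
    names(df) <- rec$channel_labels
    utils::write.csv(df, path, row.names = FALSE)
    manifest$subjects[[rec$subject_id]] <- list(
      file = basename(path), rate_hz = rec$rate_hz, attended = rec$attended,
      block_bounds = rec$block_bounds)
  }
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) stopf("[cohort] manifest not found: %s", mp)
  manifest <- jsonlite::read_json(mp)
  envs <- lapply(c("left", "right"), function(stream) {
    e <- manifest$envelopes[[stream]]
    df <- utils::read.csv(file.path(dir, e$file))
    envelope_track(df$sample, e$rate_hz, stream)
  })
  recs <- lapply(names(manifest$subjects), function(sid) {
    s <- manifest$subjects[[sid]]
    df <- utils::read.csv(file.path(dir, s$file), check.names = FALSE)
    recording(t(as.matrix(df)), s$rate_hz, names(df), subject_id = sid,
              block_bounds = lapply(s$block_bounds, function(b)
                as.integer(unlist(b))),
              attended = s$attended)
  })
  cfg <- manifest$config
  structure(list(recordings = recs, env_left = envs[[1]], env_right = envs[[2]],
                 config = structure(lapply(cfg, function(v)
                   if (is.list(v)) unlist(v) else v), class = "cohort_config")),
            class = "cohort")
}
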