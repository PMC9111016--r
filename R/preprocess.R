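#' Re-reference to algebraic linked mastoids
#'
#' Subtracts half of the reference channel from every channel, then removes
#' the reference channel and its contralateral counterpart so the layout
#' stays symmetric (e.g. 18 recorded channels in, 16 out).
#'
#' @param rec a [recording].
#' @param ref_label label of the channel whose half is subtracted.
#' @param drop_label additional channel removed to keep the layout symmetric.
#' @return A [recording] with `length(channel_labels) - 2` channels.
#' @export
rereference_linked_mastoids <- function(rec, ref_label = "L4b",
                                        drop_label = "L4a") {
  stopifnot(inherits(rec, "recording"))
  ri <- match(ref_label, rec$channel_labels)
  if (is.na(ri)) stopf("reference channel \"%s\" not found", ref_label)
  di <- match(drop_label, rec$channel_labels)
  if (is.na(di)) stopf("drop channel \"%s\" not found", drop_label)
  X <- sweep(rec$data, 2, rec$data[ri, ] / 2, "-")
  keep <- setdiff(seq_len(nrow(X)), c(ri, di))
  out <- rec
  out$data <- X[keep, , drop = FALSE]
  out$channel_labels <- rec$channel_labels[keep]
  out
}

#' Shift a recording by a constant latency
#'
#' Compensates a constant acquisition delay between stimulus markers and
#' EEG by shifting the data `shift_samples` forward (positive: the EEG is
#' moved earlier relative to the markers), zero-padding the tail. Default 0
#' for synthetic data.
#'
#' @param rec a [recording].
#' @param shift_samples signed integer shift in samples.
#' @return A shifted [recording] of identical length.
#' @export
shift_latency <- function(rec, shift_samples = 0L) {
  stopifnot(inherits(rec, "recording"))
  k <- as.integer(shift_samples)
  if (k == 0L) return(rec)
  n <- n_samples(rec)
  out <- rec
  if (k > 0) {
    out$data <- cbind(rec$data[, (k + 1):n, drop = FALSE],
                      matrix(0, nrow(rec$data), k))
  } else {
    out$data <- cbind(matrix(0, nrow(rec$data), -k),
                      rec$data[, 1:(n + k), drop = FALSE])
  }
  out
}

#' Filter specification
#'
#' @param kind `"lowpass"` or `"highpass"`.
#' @param cutoff_hz cutoff frequency in Hz (must be below Nyquist when
#'   applied).
#' @param design `"fir_hann"` (linear-phase FIR with a Hann window) or
#'   `"butterworth"`.
#' @param order filter order (> 0).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(kind = c("lowpass", "highpass"), cutoff_hz,
                        design = c("fir_hann", "butterworth"), order) {
  kind <- match.arg(kind)
  design <- match.arg(design)
  if (order <= 0) stopf("filter order must be > 0")
  if (cutoff_hz <= 0) stopf("cutoff must be > 0")
  structure(list(kind = kind, cutoff_hz = cutoff_hz, design = design,
                 order = as.integer(order)),
            class = "filter_spec")
}

# zero-phase filtering of one numeric vector
filter_vector <- function(x, spec, rate_hz) {
  if (spec$cutoff_hz >= rate_hz / 2) {
    stopf("cutoff %g Hz is not below the Nyquist frequency %g Hz",
          spec$cutoff_hz, rate_hz / 2)
  }
  w <- spec$cutoff_hz / (rate_hz / 2)
  type <- if (spec$kind == "lowpass") "low" else "high"
  if (spec$design == "fir_hann") {
    b <- signal::fir1(spec$order, w, type,
                      window = signal::hanning(spec$order + 1))
    fir_zerophase(as.numeric(b), x)
  } else {
    bt <- signal::butter(spec$order, w, type)
    as.numeric(signal::filtfilt(bt, x))
  }
}

#' Apply a zero-phase filter
#'
#' Filters are applied forward-backward (zero phase): the effective
#' magnitude response is the square of the one-pass response and no group
#' delay is introduced. Length is preserved.
#'
#' @param x a [recording], [envelope_track], numeric vector or channels x
#'   samples matrix.
#' @param spec a [filter_spec].
#' @param rate_hz sampling rate, required for plain vectors/matrices.
#' @return Same type as `x`.
#' @export
apply_filter <- function(x, spec, rate_hz = NULL) {
  stopifnot(inherits(spec, "filter_spec"))
  if (inherits(x, "recording")) {
    out <- x
    for (c in seq_len(nrow(x$data))) {
      out$data[c, ] <- filter_vector(x$data[c, ], spec, x$rate_hz)
    }
    out
  } else if (inherits(x, "envelope_track")) {
    out <- x
    out$samples <- filter_vector(x$samples, spec, x$rate_hz)
    out
  } else if (is.matrix(x)) {
    if (is.null(rate_hz)) stopf("`rate_hz` required for matrix input")
    t(apply(x, 1, filter_vector, spec = spec, rate_hz = rate_hz))
  } else {
    if (is.null(rate_hz)) stopf("`rate_hz` required for vector input")
    filter_vector(as.numeric(x), spec, rate_hz)
  }
}

# anti-aliased downsampling of a vector with exact output length, by
# Fourier-domain truncation (ideal brick-wall anti-alias filter)
resample_vector <- function(x, from_hz, to_hz) {
  if (to_hz == from_hz) return(x)
  if (to_hz > from_hz) stopf("upsampling (%g -> %g Hz) is not supported",
                             from_hz, to_hz)
  n <- length(x)
  n_out <- round(n * to_hz / from_hz)
  X <- stats::fft(x)
  Y <- complex(length.out = n_out)
  K <- floor((n_out - 1) / 2)
  Y[1] <- X[1]
  if (K >= 1) {
    Y[2:(K + 1)] <- X[2:(K + 1)]
    Y[n_out - (1:K) + 1] <- X[n - (1:K) + 1]
  }
  if (n_out %% 2 == 0) {
    ny <- n_out / 2 + 1
    Y[ny] <- X[ny] + X[n - n_out / 2 + 1]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Downsample a recording or envelope track
#'
#' Polyphase anti-aliased resampling; the new length is
#' `round(n * target / current)` and block bounds are rescaled.
#'
#' @param x a [recording] or [envelope_track].
#' @param target_rate_hz target rate, at most the current rate.
#' @return Same type as `x` at `target_rate_hz`.
#' @export
resample_to <- function(x, target_rate_hz) {
  if (inherits(x, "recording")) {
    if (target_rate_hz > x$rate_hz) stopf("upsampling is not supported")
    if (target_rate_hz == x$rate_hz) return(x)
    r <- target_rate_hz / x$rate_hz
    n_out <- round(ncol(x$data) * r)
    Y <- matrix(0, nrow(x$data), n_out)
    for (c in seq_len(nrow(x$data))) {
      Y[c, ] <- resample_vector(x$data[c, ], x$rate_hz, target_rate_hz)
    }
    out <- x
    out$data <- Y
    out$rate_hz <- target_rate_hz
    out$block_bounds <- lapply(x$block_bounds, function(b) round(b * r))
    out$block_bounds[[length(out$block_bounds)]][2] <-
      min(out$block_bounds[[length(out$block_bounds)]][2], n_out)
    out
  } else if (inherits(x, "envelope_track")) {
    if (target_rate_hz > x$rate_hz) stopf("upsampling is not supported")
    out <- x
    out$samples <- resample_vector(x$samples, x$rate_hz, target_rate_hz)
    out$rate_hz <- target_rate_hz
    out
  } else {
    stopf("resample_to expects a recording or envelope_track")
  }
}

#' Extract a speech amplitude envelope from audio
#'
#' Order of operations: divide by the standard deviation, take the modulus of
#' the analytic signal, low-pass at 8 Hz (Butterworth, order 3, zero-phase),
#' then downsample to `target_rate`.
#'
#' @param audio_samples numeric audio vector (finite, non-constant).
#' @param audio_rate audio sampling rate in Hz.
#' @param target_rate output envelope rate (default 64 Hz).
#' @param stream stream label for the returned track.
#' @return An [envelope_track] at `target_rate`.
#' @export
extract_envelope <- function(audio_samples, audio_rate, target_rate = 64,
                             stream = "left") {
  x <- as.numeric(audio_samples)
  if (!all(is.finite(x))) stopf("audio must be finite")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stopf("degenerate input: constant audio (SD = 0)")
  x <- x / s
  env <- Mod(analytic_signal(x))
  env <- filter_vector(env, filter_spec("lowpass", 8, "butterworth", 3),
                       audio_rate)
  if (target_rate < audio_rate) env <- resample_vector(env, audio_rate, target_rate)
  envelope_track(env, min(target_rate, audio_rate), stream)
}

# per-window channel-averaged band power for consecutive windows
windowed_band_power <- function(X, rate_hz, band, window_s) {
  L <- round(window_s * rate_hz)
  n_win <- floor(ncol(X) / L)
  vapply(seq_len(n_win), function(w) {
    idx <- ((w - 1) * L + 1):(w * L)
    mean(apply(X[, idx, drop = FALSE], 1, band_power,
               rate_hz = rate_hz, lo = band[1], hi = band[2]))
  }, numeric(1))
}

#' Audit spectral-power changes between two versions of a recording
#'
#' Splits both recordings into consecutive windows, computes channel-averaged
#' band power per window, and reports the change in dB
#' (`10 * log10(after / before)`). Windows with zero before-power are
#' returned as `NA` and flagged.
#'
#' @param before,after [recording]s (or channels x samples matrices) of equal
#'   shape.
#' @param band length-2 frequency band in Hz (default 2-8 Hz).
#' @param window_s window length in seconds (default 1).
#' @param rate_hz required when matrices are passed.
#' @return data.frame with columns `window`, `power_before`, `power_after`,
#'   `delta_db`.
#' @export
power_change_audit <- function(before, after, band = c(2, 8), window_s = 1,
                               rate_hz = NULL) {
  if (inherits(before, "recording")) {
    rate_hz <- before$rate_hz
    Xb <- before$data; Xa <- after$data
  } else {
    Xb <- before; Xa <- after
    if (is.null(rate_hz)) stopf("`rate_hz` required for matrix input")
  }
  if (!all(dim(Xb) == dim(Xa))) stopf("before/after shapes differ")
  pb <- windowed_band_power(Xb, rate_hz, band, window_s)
  pa <- windowed_band_power(Xa, rate_hz, band, window_s)
  delta <- ifelse(pb > 0, 10 * log10(pa / pb), NA_real_)
  data.frame(window = seq_along(pb), power_before = pb, power_after = pa,
             delta_db = delta)
}

#' Flag channels that do not follow their robust estimate
#'
#' For each 5-s window, each channel is correlated with a robust estimate of
#' what it should look like (the per-sample median of the other channels); a
#' channel whose median windowed correlation falls below `corr_threshold` is
#' flagged as artifactual.
#'
#' @param rec a [recording] with at least 3 channels.
#' @param corr_threshold correlation threshold (default 0.6).
#' @param window_s window length in seconds (default 5).
#' @return character vector of flagged channel labels (possibly empty).
#' @export
flag_bad_channels <- function(rec, corr_threshold = 0.6, window_s = 5) {
  stopifnot(inherits(rec, "recording"))
  X <- rec$data
  C <- nrow(X)
  if (C < 3) stopf("need at least 3 channels")
  L <- round(window_s * rec$rate_hz)
  n_win <- max(1L, floor(ncol(X) / L))
  cors <- matrix(NA_real_, C, n_win)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * L + 1):(w * L)
    Xw <- X[, idx, drop = FALSE]
    if (C <= 8) {
      for (c in seq_len(C)) {
        est <- apply(Xw[-c, , drop = FALSE], 2, stats::median)
        cors[c, w] <- safe_cor(Xw[c, ], est)
      }
    } else {
      # for larger montages the all-channel median is an adequate proxy
      # for the leave-one-out median
      est <- apply(Xw, 2, stats::median)
      for (c in seq_len(C)) cors[c, w] <- safe_cor(Xw[c, ], est)
    }
  }
  med_cor <- apply(cors, 1, stats::median, na.rm = TRUE)
  med_cor[is.na(med_cor)] <- 0
  rec$channel_labels[med_cor < corr_threshold]
}

safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) return(1)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}
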