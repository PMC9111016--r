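#' Multichannel EEG-like recording
#'
#' Container for one subject's multichannel time series. Data are stored as a
#' channels x samples matrix in microvolt-like arbitrary units, together with
#' the sampling rate, ordered channel labels, half-open block boundaries (in
#' samples, 0-based) and the attended-stream label.
#'
#' @param data numeric matrix, channels x samples.
#' @param rate_hz sampling rate in Hz (> 0).
#' @param channel_labels character vector of unique labels, one per row.
#' @param subject_id subject identifier.
#' @param block_bounds list of length-2 integer vectors `c(start, end)`,
#'   0-based half-open sample intervals; defaults to one block spanning the
#'   whole recording. Blocks must be ordered, non-overlapping and in range.
#' @param attended `"left"`, `"right"` or `NA`.
#' @return An object of class `recording`.
#' @export
recording <- function(data, rate_hz, channel_labels,
                      subject_id = "s01", block_bounds = NULL,
                      attended = NA_character_) {
  if (!is.matrix(data) || !is.numeric(data)) stopf("`data` must be a numeric matrix")
  if (!is.numeric(rate_hz) || rate_hz <= 0) stopf("`rate_hz` must be > 0")
  if (length(channel_labels) != nrow(data)) {
    stopf("need one channel label per data row (%d labels, %d rows)",
          length(channel_labels), nrow(data))
  }
  if (anyDuplicated(channel_labels)) stopf("channel labels must be unique")
  n <- ncol(data)
  if (is.null(block_bounds)) block_bounds <- list(c(0L, n))
  bb <- do.call(rbind, block_bounds)
  if (any(bb[, 1] >= bb[, 2]) || any(bb[, 1] < 0) || any(bb[, 2] > n)) {
    stopf("block bounds must be half-open [start, end) intervals within the data")
  }
  if (nrow(bb) > 1 && any(bb[-1, 1] < bb[-nrow(bb), 2])) {
    stopf("block bounds must be ordered and non-overlapping")
  }
  if (!is.na(attended) && !attended %in% c("left", "right")) {
    stopf("`attended` must be \"left\", \"right\" or NA")
  }
  structure(
    list(data = data, rate_hz = rate_hz,
         channel_labels = as.character(channel_labels),
         subject_id = subject_id, block_bounds = block_bounds,
         attended = attended),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s: %d channels x %d samples @ %g Hz, %d block(s), attended=%s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$rate_hz,
              length(x$block_bounds), x$attended))
  invisible(x)
}

#' Number of samples / channels in a recording
#' @param x a `recording`.
#' @export
n_samples <- function(x) ncol(x$data)

#' @rdname n_samples
#' @export
n_channels <- function(x) nrow(x$data)

#' Amplitude-envelope track of one audio stream
#'
#' @param samples numeric vector of envelope samples.
#' @param rate_hz sampling rate in Hz.
#' @param stream `"left"` or `"right"`.
#' @return An object of class `envelope_track`.
#' @export
envelope_track <- function(samples, rate_hz, stream = "left") {
  if (!is.numeric(samples) || !all(is.finite(samples))) {
    stopf("envelope samples must be finite numeric")
  }
  if (!is.numeric(rate_hz) || rate_hz <= 0) stopf("`rate_hz` must be > 0")
  if (!stream %in% c("left", "right")) stopf("`stream` must be \"left\" or \"right\"")
  structure(list(samples = as.numeric(samples), rate_hz = rate_hz, stream = stream),
            class = "envelope_track")
}

#' @export
print.envelope_track <- function(x, ...) {
  cat(sprintf("<envelope_track> %s: %d samples @ %g Hz\n",
              x$stream, length(x$samples), x$rate_hz))
  invisible(x)
}

#' Symmetric 16-channel around-the-ear layout labels
#'
#' Eight channels per ear after linked-mastoid referencing (the reference-half
#' channel and its contralateral counterpart are removed during referencing).
#' @return character vector of 16 labels.
#' @export
ceegrid_labels <- function() {
  c(paste0("L", 1:8), paste0("R", 1:8))
}
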