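#' Calibrate an artifact-subspace-reconstruction model
#'
#' Selects artifact-free calibration windows from the (already high-passed)
#' recording, computes the calibration covariance, its principal square root
#' (mixing matrix), and per-component RMS thresholds `mu + cutoff_k * sigma`.
#'
#' Calibration windows are 1-s windows whose per-channel RMS z-scores
#' (robust: median/MAD) lie within `[-3.5, 5.5]` for at least 92.5% of
#' channels.
#'
#' @param rec a [recording], high-passed (e.g. 0.25-0.75 Hz transition) so
#'   that drift does not dominate the covariance.
#' @param cutoff_k threshold multiplier k in `mu + k * sigma` (> 0; the
#'   pipeline default is the liberal value 10).
#' @param window_s sliding-window length in seconds used for component RMS
#'   statistics and later correction (default 0.5).
#' @return An `asr_model` list with `calibration_cov`, `mixing`, `eigvec`,
#'   `component_thresholds`, `cutoff_k`, `window_s`, `channel_labels`,
#'   `calibration_windows` (selected 1-s window indices).
#' @export
asr_calibrate <- function(rec, cutoff_k = 10, window_s = 0.5) {
  stopifnot(inherits(rec, "recording"))
  if (!is.numeric(cutoff_k) || cutoff_k <= 0) stopf("cutoff_k must be > 0")
  X <- rec$data
  fs <- rec$rate_hz
  C <- nrow(X)
  L1 <- round(fs)  # 1-s selection windows
  n_win <- floor(ncol(X) / L1)
  if (n_win < 2) stopf("recording too short for calibration")
  rms <- matrix(0, C, n_win)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * L1 + 1):(w * L1)
    rms[, w] <- sqrt(rowMeans(X[, idx, drop = FALSE]^2))
  }
  med <- apply(rms, 1, stats::median)
  md <- apply(rms, 1, stats::mad)
  md[md == 0] <- .Machine$double.eps
  z <- (rms - med) / md
  frac_ok <- colMeans(z >= -3.5 & z <= 5.5)
  sel <- which(frac_ok >= 0.925)
  if (length(sel) == 0) stopf("calibration failure: no artifact-free window found")
  idx <- unlist(lapply(sel, function(w) ((w - 1) * L1 + 1):(w * L1)))
  Xc <- X[, idx, drop = FALSE]
  Ccov <- tcrossprod(Xc) / ncol(Xc)
  e <- eigen(Ccov, symmetric = TRUE)
  V <- e$vectors
  M <- V %*% (sqrt(pmax(e$values, 0)) * t(V))
  # component RMS over window_s sub-windows of the calibration data
  Y <- crossprod(V, Xc)
  Ls <- max(2L, round(window_s * fs))
  n_sub <- floor(ncol(Y) / Ls)
  crms <- matrix(0, C, n_sub)
  for (w in seq_len(n_sub)) {
    j <- ((w - 1) * Ls + 1):(w * Ls)
    crms[, w] <- sqrt(rowMeans(Y[, j, drop = FALSE]^2))
  }
  mu <- rowMeans(crms)
  sig <- apply(crms, 1, stats::sd)
  structure(list(calibration_cov = Ccov, mixing = M, eigvec = V,
                 component_thresholds = mu + cutoff_k * sig,
                 cutoff_k = cutoff_k, window_s = window_s,
                 channel_labels = rec$channel_labels,
                 calibration_windows = sel),
            class = "asr_model")
}

#' @export
print.asr_model <- function(x, ...) {
  cat(sprintf("<asr_model> %d channels, cutoff_k=%g, %d calibration windows\n",
              nrow(x$calibration_cov), x$cutoff_k, length(x$calibration_windows)))
  invisible(x)
}

#' Correct artifacts by subspace reconstruction
#'
#' Slides half-overlapping windows over the recording; in each window the
#' data covariance is eigendecomposed and components whose variance exceeds
#' the calibration threshold (projected into the window's eigenbasis) are
#' reconstructed from the retained subspace via the calibration mixing
#' matrix. Windows are blended with raised-cosine weights, so the output is
#' continuous and no samples are removed. Windows in which no component
#' exceeds its threshold are copied through unchanged; if no window is
#' modified the input is returned bit-identically.
#'
#' @param rec a [recording] (same channels as used for calibration).
#' @param model an `asr_model` from [asr_calibrate].
#' @return A corrected [recording].
#' @export
asr_correct <- function(rec, model) {
  stopifnot(inherits(rec, "recording"), inherits(model, "asr_model"))
  if (!identical(rec$channel_labels, model$channel_labels)) {
    stopf("recording channels do not match the calibration model")
  }
  X <- rec$data
  C <- nrow(X)
  n <- ncol(X)
  fs <- rec$rate_hz
  L <- max(4L, round(model$window_s * fs))
  step <- max(1L, L %/% 2L)
  starts <- seq(1L, max(n - L + 1L, 1L), by = step)
  if (starts[length(starts)] + L - 1L < n) starts <- c(starts, n - L + 1L)
  Tm <- model$component_thresholds * t(model$eigvec)  # diag(thr) %*% t(V)
  M <- model$mixing
  acc <- matrix(0, C, n)
  wacc <- numeric(n)
  modified <- FALSE
  blend <- sin(pi * (seq_len(L) - 0.5) / L)^2 + 1e-3
  for (s in starts) {
    idx <- s:(s + L - 1L)
    Xw <- X[, idx, drop = FALSE]
    Cw <- tcrossprod(Xw) / L
    e <- eigen(Cw, symmetric = TRUE)
    Vw <- e$vectors
    thr2 <- colSums((Tm %*% Vw)^2)
    keep <- e$values < thr2
    if (all(keep)) {
      Yw <- Xw
    } else {
      modified <- TRUE
      B <- t(Vw) %*% M           # C x C
      B[!keep, ] <- 0
      R <- M %*% pinv(B) %*% t(Vw)
      Yw <- R %*% Xw
    }
    acc[, idx] <- acc[, idx] + sweep(Yw, 2, blend, "*")
    wacc[idx] <- wacc[idx] + blend
  }
  if (!modified) return(rec)
  out <- rec
  out$data <- sweep(acc, 2, wacc, "/")
  out
}
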