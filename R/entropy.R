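# Discrete prolate spheroidal (Slepian) tapers via the classical symmetric
# tridiagonal eigenproblem: diagonal ((N-1-2t)/2)^2 cos(2*pi*W), off-diagonal
# t(N-t)/2. The k largest eigenvalues are found by Sturm-count bisection and
# eigenvectors by shifted inverse iteration (Thomas solves), which keeps the
# cost O(k N) and makes minute-long segments tractable without a dense
# eigendecomposition.

.dpss_cache <- new.env(parent = emptyenv())

# number of eigenvalues of the tridiagonal matrix strictly below each shift
sturm_counts <- function(d, e, sigmas) {
  m <- length(sigmas)
  cnt <- integer(m)
  q <- d[1] - sigmas
  cnt <- cnt + (q < 0)
  n <- length(d)
  e2 <- e^2
  for (i in 2:n) {
    q <- ifelse(abs(q) < 1e-300, 1e-300 * sign(q + (q == 0)), q)
    q <- (d[i] - sigmas) - e2[i - 1] / q
    cnt <- cnt + (q < 0)
  }
  cnt
}

# solve (T - sigma I) x = b for symmetric tridiagonal T (Thomas algorithm)
tridiag_solve <- function(d, e, sigma, b) {
  n <- length(d)
  dd <- d - sigma
  cp <- numeric(n); bp <- numeric(n)
  denom <- dd[1]
  if (abs(denom) < 1e-300) denom <- 1e-300
  cp[1] <- e[1] / denom
  bp[1] <- b[1] / denom
  for (i in 2:n) {
    denom <- dd[i] - e[i - 1] * cp[i - 1]
    if (abs(denom) < 1e-300) denom <- 1e-300
    if (i < n) cp[i] <- e[i] / denom
    bp[i] <- (b[i] - e[i - 1] * bp[i - 1]) / denom
  }
  x <- numeric(n)
  x[n] <- bp[n]
  for (i in (n - 1):1) x[i] <- bp[i] - cp[i] * x[i + 1]
  x
}

#' Discrete prolate spheroidal sequences (Slepian tapers)
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product (default 4).
#' @param k number of tapers (default `2 * nw - 1 = 7`).
#' @return n x k matrix of orthonormal tapers, ordered by decreasing
#'   spectral concentration; each taper's sign is fixed so that its mean
#'   (even orders) or initial slope (odd orders) is positive.
#' @export
dpss_tapers <- function(n, nw = 4, k = 2 * nw - 1) {
  key <- sprintf("n%d_nw%g_k%d", n, nw, k)
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  W <- nw / n
  t0 <- 0:(n - 1)
  d <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * W)
  e <- (seq_len(n - 1) * (n - seq_len(n - 1))) / 2
  lo <- min(d) - 2 * max(abs(e))
  hi <- max(d) + 2 * max(abs(e))
  # bisect for eigenvalue ranks n-k+1 ... n (the k largest), in parallel
  lows <- rep(lo, k); highs <- rep(hi, k)
  target <- n - (k:1)  # count of eigenvalues strictly below the j-th sought
  for (it in 1:60) {
    mids <- (lows + highs) / 2
    cnt <- sturm_counts(d, e, mids)
    below <- cnt <= target
    lows[below] <- mids[below]
    highs[!below] <- mids[!below]
    if (max(highs - lows) < 1e-9 * max(abs(hi), 1)) break
  }
  evals <- (lows + highs) / 2
  V <- matrix(0, n, k)
  for (j in seq_len(k)) {
    x <- sin((1:n) * pi * j / (n + 1))  # deterministic start
    for (it in 1:4) {
      x <- tridiag_solve(d, e, evals[j] + 1e-8 * abs(evals[j]), x)
      if (j > 1) {  # deflate against previously found vectors
        prev <- V[, seq_len(j - 1), drop = FALSE]
        x <- x - prev %*% crossprod(prev, x)
      }
      x <- x / sqrt(sum(x^2))
    }
    V[, j] <- x
  }
  # order by decreasing concentration: largest tridiagonal eigenvalue first
  V <- V[, order(evals, decreasing = TRUE), drop = FALSE]
  for (j in seq_len(k)) {
    if (j %% 2 == 1) {
      if (sum(V[, j]) < 0) V[, j] <- -V[, j]
    } else {
      if (V[2, j] - V[1, j] < 0) V[, j] <- -V[, j]
    }
  }
  .dpss_cache[[key]] <- V
  V
}

#' Multitaper power spectral density of one segment
#'
#' Average of the eigenspectra obtained with `n_tapers` Slepian tapers
#' (time-bandwidth product `nw = (n_tapers + 1) / 2`, so 7 tapers correspond
#' to NW = 4), on the native FFT grid of the segment.
#'
#' @param x numeric vector (one channel of one segment; >= 64 samples).
#' @param rate_hz sampling rate in Hz.
#' @param n_tapers number of tapers (default 7).
#' @return list with `freq` (Hz, one-sided) and `psd` (non-negative).
#' @export
multitaper_spectrum <- function(x, rate_hz, n_tapers = 7) {
  n <- length(x)
  if (n < 64) stopf("segment too short for multitaper estimation (%d samples)", n)
  nw <- (n_tapers + 1) / 2
  V <- dpss_tapers(n, nw, n_tapers)
  nf <- floor(n / 2) + 1
  P <- numeric(nf)
  for (j in seq_len(n_tapers)) {
    s <- Mod(stats::fft(x * V[, j]))^2
    P <- P + s[seq_len(nf)]
  }
  list(freq = (seq_len(nf) - 1) * rate_hz / n, psd = P / (n_tapers * rate_hz))
}

#' Restrict a PSD to a band and normalize it to unit sum
#'
#' @param psd numeric PSD vector.
#' @param freq matching frequency grid in Hz.
#' @param f_lo,f_hi inclusive band edges (default 8-32 Hz).
#' @return A `spectrum_segment`: list with `p` (sums to 1), `freq`, `n_bins`.
#' @export
normalize_band <- function(psd, freq, f_lo = 8, f_hi = 32) {
  keep <- freq >= f_lo & freq <= f_hi
  if (sum(keep) < 2) stopf("band [%g, %g] Hz contains fewer than 2 bins", f_lo, f_hi)
  tot <- sum(psd[keep])
  if (tot <= 0) stopf("degenerate input: zero power in band [%g, %g] Hz", f_lo, f_hi)
  structure(list(p = psd[keep] / tot, freq = freq[keep], n_bins = sum(keep)),
            class = "spectrum_segment")
}

#' Normalized spectral entropy
#'
#' `H = (1 / log N) * sum_f p_f log(1 / p_f)`, with zero-power bins
#' contributing 0. H = 1 for a flat spectrum, 0 when all power sits in one
#' bin.
#'
#' @param p normalized power vector (non-negative, sums to 1), or a
#'   `spectrum_segment`.
#' @return entropy in `[0, 1]`.
#' @export
spectral_entropy <- function(p) {
  if (inherits(p, "spectrum_segment")) p <- p$p
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-6) {
    stopf("`p` must be a normalized power vector (>= 0, summing to 1)")
  }
  p <- pmax(p, 0)
  nz <- p > 0
  sum(p[nz] * log(1 / p[nz])) / log(length(p))
}

#' Fraction of normalized band power in a sub-band
#'
#' @param p normalized power vector or `spectrum_segment`.
#' @param freq frequency grid (taken from a `spectrum_segment` if given).
#' @param f_lo,f_hi inclusive sub-band edges (default 8-12 Hz, the alpha
#'   band).
#' @return sum of `p` over bins in `[f_lo, f_hi]`.
#' @export
band_fraction <- function(p, freq = NULL, f_lo = 8, f_hi = 12) {
  if (inherits(p, "spectrum_segment")) {
    freq <- p$freq
    p <- p$p
  }
  if (is.null(freq)) stopf("`freq` required")
  sum(p[freq >= f_lo & freq <= f_hi])
}

#' Spectral-entropy and alpha-power time courses
#'
#' Splits the (artifact-corrected) recording into consecutive segments; for
#' each segment and non-flagged channel the 8-32 Hz multitaper spectrum is
#' normalized, its spectral entropy and alpha (8-12 Hz) power fraction
#' computed, and both are averaged over retained channels. Spearman rank
#' correlations of each series against the segment index quantify the
#' time-on-task trends.
#'
#' @param rec a [recording] (artifact-corrected).
#' @param bad_channels labels to exclude (from [flag_bad_channels]).
#' @param seg_len_s segment length in seconds (default 60).
#' @param band entropy band in Hz (default `c(8, 32)`).
#' @param n_tapers number of Slepian tapers (default 7).
#' @return An `entropy_course`: list with `per_segment` (data.frame
#'   `segment`, `H`, `alpha`), `rho_H`, `p_H`, `rho_alpha`, `p_alpha`,
#'   `retained_channels`.
#' @export
entropy_timecourse <- function(rec, bad_channels = character(),
                               seg_len_s = 60, band = c(8, 32),
                               n_tapers = 7) {
  stopifnot(inherits(rec, "recording"))
  keep <- !(rec$channel_labels %in% bad_channels)
  if (!any(keep)) stopf("degenerate input: all channels flagged")
  X <- rec$data[keep, , drop = FALSE]
  L <- round(seg_len_s * rec$rate_hz)
  n_seg <- floor(ncol(X) / L)
  if (n_seg < 1) stopf("recording shorter than one segment")
  H <- alpha <- numeric(n_seg)
  for (s in seq_len(n_seg)) {
    idx <- ((s - 1) * L + 1):(s * L)
    hs <- as_ <- numeric(nrow(X))
    for (c in seq_len(nrow(X))) {
      mt <- multitaper_spectrum(X[c, idx], rec$rate_hz, n_tapers)
      sp <- normalize_band(mt$psd, mt$freq, band[1], band[2])
      hs[c] <- spectral_entropy(sp)
      as_[c] <- band_fraction(sp)
    }
    H[s] <- mean(hs)
    alpha[s] <- mean(as_)
  }
  if (n_seg >= 4) {
    ct_h <- stats::cor.test(seq_len(n_seg), H, method = "spearman", exact = FALSE)
    ct_a <- stats::cor.test(seq_len(n_seg), alpha, method = "spearman", exact = FALSE)
    rho_H <- unname(ct_h$estimate); p_H <- ct_h$p.value
    rho_alpha <- unname(ct_a$estimate); p_alpha <- ct_a$p.value
  } else {
    rho_H <- p_H <- rho_alpha <- p_alpha <- NA_real_
  }
  structure(list(per_segment = data.frame(segment = seq_len(n_seg),
                                          H = H, alpha = alpha),
                 rho_H = rho_H, p_H = p_H,
                 rho_alpha = rho_alpha, p_alpha = p_alpha,
                 retained_channels = rec$channel_labels[keep]),
            class = "entropy_course")
}

#' @export
print.entropy_course <- function(x, ...) {
  cat(sprintf("<entropy_course> %d segments; rho_H=%.3f (p=%.3g), rho_alpha=%.3f (p=%.3g)\n",
              nrow(x$per_segment), x$rho_H, x$p_H, x$rho_alpha, x$p_alpha))
  invisible(x)
}
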