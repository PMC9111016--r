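# Internal numerical helpers shared across modules.

#' @importFrom stats fft nextn rnorm runif sd var median mad quantile
NULL

# round half away from zero (ms -> sample lag conversions)
round_half_away <- function(x) trunc(x + 0.5 * sign(x))

# deterministic 32-bit sub-seed from a master seed and an index/salt
derive_seed <- function(seed, index, salt = 0L) {
  s <- (as.double(seed) %% 1000003) * 8191 +
    as.double(index) * 2654435 + as.double(salt) * 97561
  as.integer(s %% 2147483647)
}

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# analytic signal via frequency-domain Hilbert transform
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# causal FIR filtering y(t) = sum_u k(u+1) x(t-u), zero initial state, via FFT
causal_fir <- function(k, x) {
  n <- length(x)
  m <- length(k)
  nfft <- stats::nextn(n + m, c(2, 3, 5))
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                       stats::fft(c(k, numeric(nfft - m))), inverse = TRUE)) / nfft
  y[seq_len(n)]
}

# zero-phase FIR filtering (forward-backward, i.e. convolution with
# k correlated with itself); implicit zero padding at the edges
fir_zerophase <- function(k, x) {
  n <- length(x)
  m <- length(k)
  c2 <- convolve(k, rev(k), type = "open")  # length 2m-1, symmetric, centre m
  nfft <- stats::nextn(n + 2 * m, c(2, 3, 5))
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                       stats::fft(c(c2, numeric(nfft - length(c2)))),
                     inverse = TRUE)) / nfft
  y[m:(m + n - 1)]
}

# one-sided periodogram band power (sum over bins with lo <= f <= hi)
band_power <- function(x, rate_hz, lo, hi) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * rate_hz / n
  keep <- f <= rate_hz / 2
  sum(P[keep & f >= lo & f <= hi])
}

# unit-variance 1/f^(exponent/2 in amplitude) noise by spectral shaping
one_over_f_noise <- function(n, exponent = 1) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f)  # symmetric |frequency| index
  scale <- ifelse(f == 0, 0, 1 / f^(exponent / 2))
  y <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Moore-Penrose pseudo-inverse via SVD
pinv <- function(A, tol = NULL) {
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * max(s$d) * .Machine$double.eps
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# symmetric positive semi-definite matrix square root
sqrtm_psd <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  d <- pmax(e$values, 0)
  e$vectors %*% (sqrt(d) * t(e$vectors))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
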