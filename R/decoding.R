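#' Segment a recording and its envelopes into aligned 60-s pieces
#'
#' Segments never cross block boundaries; segment k of a block spans samples
#' `[k*L, (k+1)*L)` within that block, where `L = seg_len_s * rate`.
#'
#' @param rec a [recording].
#' @param env_att,env_ign [envelope_track]s at the same rate as `rec`, with
#'   length matching the recording.
#' @param seg_len_s segment length in seconds (default 60).
#' @return A `segment_set`: list of segments (each with `eeg` channels x
#'   samples, `env_att`, `env_ign`) plus rate and subject metadata.
#' @export
segment_recording <- function(rec, env_att, env_ign, seg_len_s = 60) {
  stopifnot(inherits(rec, "recording"))
  if (env_att$rate_hz != rec$rate_hz || env_ign$rate_hz != rec$rate_hz) {
    stopf("EEG and envelopes must share a sampling rate")
  }
  n <- n_samples(rec)
  if (length(env_att$samples) != n || length(env_ign$samples) != n) {
    stopf("EEG and envelope lengths are misaligned (%d vs %d/%d)",
          n, length(env_att$samples), length(env_ign$samples))
  }
  L <- round(seg_len_s * rec$rate_hz)
  segs <- list()
  for (b in rec$block_bounds) {
    k_max <- floor((b[2] - b[1]) / L)
    for (k in seq_len(k_max)) {
      idx <- (b[1] + (k - 1) * L + 1):(b[1] + k * L)  # 0-based bounds -> 1-based
      segs[[length(segs) + 1]] <- list(
        eeg = rec$data[, idx, drop = FALSE],
        env_att = env_att$samples[idx],
        env_ign = env_ign$samples[idx])
    }
  }
  structure(list(segments = segs, rate_hz = rec$rate_hz,
                 subject_id = rec$subject_id, attended = rec$attended,
                 seg_len_s = seg_len_s),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %s: %d segments of %g s @ %g Hz\n",
              x$subject_id, length(x$segments), x$seg_len_s, x$rate_hz))
  invisible(x)
}

#' Enumerate the time-lag / regularization hyperparameter grid
#'
#' 47 lag windows of 45 ms duration starting at -115, -100, ..., 575 ms
#' (30 ms overlap between consecutive windows) crossed with 11 regularization
#' parameters 10^-5 ... 10^5.
#'
#' @return A `hyper_grid` list with `windows` (data.frame `start_ms`,
#'   `end_ms`) and `lambdas`.
#' @export
enumerate_hypergrid <- function() {
  starts <- seq(-115, 575, by = 15)
  structure(list(windows = data.frame(start_ms = starts, end_ms = starts + 45),
                 lambdas = 10^seq(-5, 5)),
            class = "hyper_grid")
}

# ms -> integer sample lag, rounding half away from zero
ms_to_lag <- function(ms, rate_hz) round_half_away(ms * rate_hz / 1000)

#' Build a time-lagged design matrix
#'
#' Row `t` contains the EEG at samples `t + tau` for every integer lag
#' `tau` in `[round(start*fs/1000), round(end*fs/1000)]` and every channel
#' (channel-major, lag ascending within a channel), with out-of-range samples
#' zero-padded, plus a constant bias column (last). A positive lag means the
#' neural response lags the stimulus (backward-model convention): the
#' envelope at time t is predicted from EEG recorded after t.
#'
#' @param eeg channels x samples matrix.
#' @param lag_window numeric `c(start_ms, end_ms)`.
#' @param rate_hz sampling rate in Hz.
#' @return numeric matrix, samples x (n_lags * n_channels + 1).
#' @export
build_lagged_design <- function(eeg, lag_window, rate_hz) {
  if (!is.matrix(eeg)) eeg <- matrix(eeg, nrow = 1)
  l0 <- ms_to_lag(lag_window[1], rate_hz)
  l1 <- ms_to_lag(lag_window[2], rate_hz)
  if (l1 < l0) stopf("empty lag set for window (%g, %g) ms at %g Hz",
                     lag_window[1], lag_window[2], rate_hz)
  lags <- l0:l1
  C <- nrow(eeg); n <- ncol(eeg); nl <- length(lags)
  X <- matrix(0, n, C * nl + 1)
  for (c in seq_len(C)) {
    for (j in seq_len(nl)) {
      tau <- lags[j]
      src <- seq_len(n) + tau
      ok <- src >= 1 & src <= n
      X[ok, (c - 1) * nl + j] <- eeg[c, src[ok]]
    }
  }
  X[, C * nl + 1] <- 1
  X
}

# banded second-difference (temporal smoothness) or identity penalty,
# block-diagonal per channel, bias unpenalized; size p x p with p = nl*C + 1
penalty_matrix <- function(n_lags, n_channels,
                           type = c("second_diff", "identity")) {
  type <- match.arg(type)
  p <- n_lags * n_channels + 1
  M <- matrix(0, p, p)
  if (type == "identity") {
    diag(M)[seq_len(p - 1)] <- 1
    return(M)
  }
  blk <- diag(c(1, rep(2, max(n_lags - 2, 0)), 1)[seq_len(n_lags)], n_lags)
  if (n_lags == 1) blk <- matrix(1, 1, 1)
  if (n_lags >= 2) {
    for (i in seq_len(n_lags - 1)) {
      blk[i, i + 1] <- -1
      blk[i + 1, i] <- -1
    }
  }
  for (c in seq_len(n_channels)) {
    idx <- ((c - 1) * n_lags + 1):(c * n_lags)
    M[idx, idx] <- blk
  }
  M
}

solve_penalized <- function(A, r, lambda, M) {
  H <- A + lambda * M
  ch <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(ch)) {
    warning("singular regularized system; using least-squares pseudo-inverse",
            call. = FALSE)
    return(as.numeric(pinv(H) %*% r))
  }
  as.numeric(backsolve(ch, forwardsolve(t(ch), r)))
}

#' Train a backward (stimulus-reconstruction) model
#'
#' Solves `w = (X'X + lambda * M)^-1 X'y`, where X stacks the lagged designs
#' of all training segments, y stacks the attended envelopes, and M is a
#' banded second-difference penalty applied within each channel's lag block
#' (no cross-channel coupling); the bias column is unpenalized.
#'
#' @param train_segments a `segment_set` or a list of segments (each with
#'   `eeg` and `env_att`).
#' @param lag_window numeric `c(start_ms, end_ms)`.
#' @param lambda regularization parameter (>= 0).
#' @param rate_hz sampling rate; taken from a `segment_set` if given.
#' @param penalty `"second_diff"` (default) or `"identity"`.
#' @return A `decoder_weights` object with `w` (full coefficient vector,
#'   bias last), `weights` (lags x channels matrix), `bias`, `lag_window`,
#'   `lambda`, `train_rate_hz`, `lags`.
#' @export
train_backward_model <- function(train_segments, lag_window, lambda,
                                 rate_hz = NULL, penalty = "second_diff") {
  if (inherits(train_segments, "segment_set")) {
    rate_hz <- train_segments$rate_hz
    train_segments <- train_segments$segments
  }
  if (length(train_segments) < 1) stopf("need at least one training segment")
  if (is.null(rate_hz)) stopf("`rate_hz` required for raw segment lists")
  C <- nrow(train_segments[[1]]$eeg)
  X1 <- build_lagged_design(train_segments[[1]]$eeg, lag_window, rate_hz)
  p <- ncol(X1)
  A <- crossprod(X1)
  r <- crossprod(X1, train_segments[[1]]$env_att)
  if (length(train_segments) > 1) {
    for (k in 2:length(train_segments)) {
      Xk <- build_lagged_design(train_segments[[k]]$eeg, lag_window, rate_hz)
      A <- A + crossprod(Xk)
      r <- r + crossprod(Xk, train_segments[[k]]$env_att)
    }
  }
  nl <- (p - 1) / C
  M <- penalty_matrix(nl, C, penalty)
  w <- solve_penalized(A, r, lambda, M)
  structure(list(w = w,
                 weights = matrix(w[seq_len(p - 1)], nrow = nl),
                 bias = w[p], lag_window = lag_window, lambda = lambda,
                 train_rate_hz = rate_hz, n_channels = C,
                 lags = ms_to_lag(lag_window[1], rate_hz):ms_to_lag(lag_window[2], rate_hz)),
            class = "decoder_weights")
}

#' @export
print.decoder_weights <- function(x, ...) {
  cat(sprintf("<decoder_weights> window (%g, %g) ms, lambda=%g, %d lags x %d channels\n",
              x$lag_window[1], x$lag_window[2], x$lambda,
              length(x$lags), x$n_channels))
  invisible(x)
}

#' Reconstruct the attended envelope from EEG
#'
#' @param weights a `decoder_weights` object.
#' @param eeg_segment channels x samples matrix (or a segment list with an
#'   `eeg` element) at the training rate.
#' @return numeric vector: `design %*% w + bias`.
#' @export
reconstruct_envelope <- function(weights, eeg_segment) {
  stopifnot(inherits(weights, "decoder_weights"))
  eeg <- if (is.list(eeg_segment)) eeg_segment$eeg else eeg_segment
  if (!is.matrix(eeg)) eeg <- matrix(eeg, nrow = 1)
  if (nrow(eeg) != weights$n_channels) {
    stopf("channel count mismatch: decoder has %d, segment has %d",
          weights$n_channels, nrow(eeg))
  }
  X <- build_lagged_design(eeg, weights$lag_window, weights$train_rate_hz)
  as.numeric(X %*% weights$w)
}

#' Score a reconstructed envelope against both streams
#'
#' Pearson correlations of the prediction with the attended and ignored
#' envelope; the attentional gain is their difference, and the segment is
#' classified correctly iff the gain is strictly positive. A constant
#' prediction has undefined correlation: the gain is set to 0 and flagged.
#'
#' @param prediction,env_att,env_ign numeric vectors of equal length.
#' @return list with `corr_att`, `corr_ign`, `gain`, `mse`, `degenerate`.
#' @export
score_segment <- function(prediction, env_att, env_ign) {
  if (length(prediction) != length(env_att) ||
      length(prediction) != length(env_ign)) {
    stopf("prediction and envelopes must have equal length")
  }
  mse <- mean((prediction - env_att)^2)
  if (stats::sd(prediction) == 0 || stats::sd(env_att) == 0 ||
      stats::sd(env_ign) == 0) {
    return(list(corr_att = NA_real_, corr_ign = NA_real_, gain = 0,
                mse = mse, degenerate = TRUE))
  }
  ca <- stats::cor(prediction, env_att)
  ci <- stats::cor(prediction, env_ign)
  list(corr_att = ca, corr_ign = ci, gain = ca - ci, mse = mse,
       degenerate = FALSE)
}

#' Leave-one-out decoding accuracy for one hyperparameter set
#'
#' For each segment, a decoder is trained on all other segments and scored on
#' the left-out one; the accuracy is the fraction of segments with strictly
#' positive attentional gain, compared against the exact binomial chance
#' threshold.
#'
#' @param segments a `segment_set` (>= 2 segments).
#' @param lag_window numeric `c(start_ms, end_ms)`.
#' @param lambda regularization parameter.
#' @param alpha significance level of the binomial chance threshold.
#' @param penalty penalty type, see [train_backward_model].
#' @return A `decoding_result`: list with `per_segment` (data.frame of
#'   `corr_att`, `corr_ign`, `gain`, `mse`), `accuracy`, `chance_threshold`.
#' @export
loo_accuracy <- function(segments, lag_window, lambda, alpha = 0.05,
                         penalty = "second_diff") {
  stopifnot(inherits(segments, "segment_set"))
  segs <- segments$segments
  K <- length(segs)
  if (K < 2) stopf("need at least 2 segments for leave-one-out")
  fs <- segments$rate_hz
  C <- nrow(segs[[1]]$eeg)
  X <- lapply(segs, function(s) build_lagged_design(s$eeg, lag_window, fs))
  p <- ncol(X[[1]])
  S <- lapply(X, crossprod)
  b <- lapply(seq_len(K), function(k) crossprod(X[[k]], segs[[k]]$env_att))
  A_tot <- Reduce(`+`, S)
  b_tot <- Reduce(`+`, b)
  nl <- (p - 1) / C
  M <- penalty_matrix(nl, C, penalty)
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    w <- solve_penalized(A_tot - S[[k]], b_tot - b[[k]], lambda, M)
    pred <- as.numeric(X[[k]] %*% w)
    sc <- score_segment(pred, segs[[k]]$env_att, segs[[k]]$env_ign)
    rows[[k]] <- data.frame(segment = k, corr_att = sc$corr_att,
                            corr_ign = sc$corr_ign, gain = sc$gain,
                            mse = sc$mse, degenerate = sc$degenerate)
  }
  per_segment <- do.call(rbind, rows)
  structure(list(per_segment = per_segment,
                 accuracy = mean(per_segment$gain > 0),
                 chance_threshold = binomial_chance(K, alpha = alpha),
                 lag_window = lag_window, lambda = lambda),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> accuracy %.3f over %d segments (chance %.3f), window (%g, %g) ms, lambda=%g\n",
              x$accuracy, nrow(x$per_segment), x$chance_threshold,
              x$lag_window[1], x$lag_window[2], x$lambda))
  invisible(x)
}

#' Binomial chance-level threshold
#'
#' The smallest fraction `k/n` such that `P(X >= k | n, p) < alpha` under the
#' binomial law (if no `k <= n` qualifies, `n/n` is returned).
#'
#' @param n_segments number of test segments (>= 1).
#' @param p success probability under the null (default 0.5).
#' @param alpha significance level in (0, 1).
#' @return threshold fraction in (0, 1].
#' @export
binomial_chance <- function(n_segments, p = 0.5, alpha = 0.05) {
  if (n_segments < 1) stopf("n_segments must be >= 1")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  for (k in seq_len(n_segments)) {
    if (stats::pbinom(k - 1, n_segments, p, lower.tail = FALSE) < alpha) {
      return(k / n_segments)
    }
  }
  1
}

# ---- fast moment cache over the full grid lag range ----------------------

#' Precompute per-segment design moments over the grid's full lag range
#'
#' Computes, once per segment, the cross-products of the full-lag-range
#' design matrix with itself and with both envelopes. Every grid cell and
#' cross-validation fold is then solvable by subsetting columns and
#' subtracting segment moments, which makes the 47 x 11 grid and nested
#' cross-validation tractable.
#'
#' @param segments a `segment_set`.
#' @param grid a `hyper_grid` (defines the lag range).
#' @param penalty penalty type.
#' @return A `grid_cache` object.
#' @export
grid_cache <- function(segments, grid = enumerate_hypergrid(),
                       penalty = "second_diff") {
  stopifnot(inherits(segments, "segment_set"))
  fs <- segments$rate_hz
  lag_min <- ms_to_lag(min(grid$windows$start_ms), fs)
  lag_max <- ms_to_lag(max(grid$windows$end_ms), fs)
  full_window <- c(lag_min, lag_max) * 1000 / fs
  segs <- segments$segments
  K <- length(segs)
  C <- nrow(segs[[1]]$eeg)
  S <- vector("list", K)
  b_att <- b_ign <- vector("list", K)
  env_stats <- matrix(0, K, 5,
                      dimnames = list(NULL, c("sa", "ssa", "si", "ssi", "n")))
  for (k in seq_len(K)) {
    Xk <- build_lagged_design(segs[[k]]$eeg, full_window, fs)
    S[[k]] <- crossprod(Xk)
    b_att[[k]] <- as.numeric(crossprod(Xk, segs[[k]]$env_att))
    b_ign[[k]] <- as.numeric(crossprod(Xk, segs[[k]]$env_ign))
    env_stats[k, ] <- c(sum(segs[[k]]$env_att), sum(segs[[k]]$env_att^2),
                        sum(segs[[k]]$env_ign), sum(segs[[k]]$env_ign^2),
                        length(segs[[k]]$env_att))
  }
  structure(list(S = S, b_att = b_att, b_ign = b_ign, env_stats = env_stats,
                 lags = lag_min:lag_max, n_channels = C, rate_hz = fs,
                 n_segments = K, penalty = penalty,
                 subject_id = segments$subject_id),
            class = "grid_cache")
}

# column indices (incl. bias) of a lag window inside the full-range design
window_columns <- function(cache, lag_window) {
  l0 <- ms_to_lag(lag_window[1], cache$rate_hz)
  l1 <- ms_to_lag(lag_window[2], cache$rate_hz)
  nlf <- length(cache$lags)
  off <- match(l0, cache$lags)
  nl <- l1 - l0 + 1
  cols <- as.vector(outer(off:(off + nl - 1),
                          (seq_len(cache$n_channels) - 1) * nlf, `+`))
  c(cols, nlf * cache$n_channels + 1)
}

# correlation/mse of pred = X w with an envelope, from moments
score_from_moments <- function(w, Sk, bk, e_sum, e_ss, n) {
  p_ss <- as.numeric(t(w) %*% Sk %*% w)
  p_sum <- sum(w * Sk[, ncol(Sk)])
  pe <- sum(w * bk)
  var_p <- p_ss - p_sum^2 / n
  var_e <- e_ss - e_sum^2 / n
  cov_pe <- pe - p_sum * e_sum / n
  r <- if (var_p <= 1e-12 * max(p_ss, 1) || var_e <= 0) NA_real_
  else cov_pe / sqrt(var_p * var_e)
  mse <- (p_ss - 2 * pe + e_ss) / n
  c(r = as.numeric(r), mse = as.numeric(mse))
}

#' Evaluate the full hyperparameter grid by leave-one-out cross-validation
#'
#' @param segments a `segment_set` (ignored when `cache` is supplied).
#' @param grid a `hyper_grid`.
#' @param cache optional [grid_cache]; computed if missing.
#' @param subset optional integer vector of segment indices to restrict the
#'   cross-validation to (used by nested cross-validation inner folds).
#' @return list with matrices `accuracy` and `mse`
#'   (`nrow(grid$windows)` x `length(grid$lambdas)`) and `grid`.
#' @export
evaluate_grid <- function(segments = NULL, grid = enumerate_hypergrid(),
                          cache = NULL, subset = NULL) {
  if (is.null(cache)) cache <- grid_cache(segments, grid)
  idx_seg <- if (is.null(subset)) seq_len(cache$n_segments) else subset
  K <- length(idx_seg)
  nW <- nrow(grid$windows)
  nL <- length(grid$lambdas)
  acc <- mse <- matrix(0, nW, nL)
  for (wi in seq_len(nW)) {
    win <- as.numeric(grid$windows[wi, ])
    cols <- window_columns(cache, win)
    nl <- (length(cols) - 1) / cache$n_channels
    M <- penalty_matrix(nl, cache$n_channels, cache$penalty)
    Ssub <- lapply(idx_seg, function(k) cache$S[[k]][cols, cols])
    bsub <- lapply(idx_seg, function(k) cache$b_att[[k]][cols])
    A_tot <- Reduce(`+`, Ssub)
    b_tot <- Reduce(`+`, bsub)
    for (li in seq_len(nL)) {
      lam <- grid$lambdas[li]
      gains <- mses <- numeric(K)
      for (j in seq_len(K)) {
        k <- idx_seg[j]
        w <- solve_penalized(A_tot - Ssub[[j]], b_tot - bsub[[j]], lam, M)
        es <- cache$env_stats[k, ]
        sa <- score_from_moments(w, Ssub[[j]], bsub[[j]], es["sa"], es["ssa"], es["n"])
        si <- score_from_moments(w, Ssub[[j]], cache$b_ign[[k]][cols],
                                 es["si"], es["ssi"], es["n"])
        gains[j] <- if (is.na(sa["r"]) || is.na(si["r"])) 0 else sa["r"] - si["r"]
        mses[j] <- sa["mse"]
      }
      acc[wi, li] <- mean(gains > 0)
      mse[wi, li] <- mean(mses)
    }
  }
  list(accuracy = acc, mse = mse, grid = grid)
}

#' Select hyperparameters from accuracy/error grids
#'
#' Group mode: the cell with the largest grand-average accuracy across
#' subjects; ties broken by the lowest grand-average prediction error, then
#' by earliest grid order (windows, then lambdas). Individual mode: the same
#' rule applied to each subject's own grids.
#'
#' @param acc_grid matrix (windows x lambdas) or list of such matrices (one
#'   per subject).
#' @param mse_grid matching matrix or list.
#' @param mode `"group"` or `"individual"`.
#' @param grid the `hyper_grid` the matrices were computed on.
#' @return data.frame with one row (group) or one per subject (individual):
#'   `window_idx`, `lambda_idx`, `start_ms`, `end_ms`, `lambda`, `accuracy`,
#'   `mse`.
#' @export
select_hyperparameters <- function(acc_grid, mse_grid,
                                   mode = c("group", "individual"),
                                   grid = enumerate_hypergrid()) {
  mode <- match.arg(mode)
  if (is.matrix(acc_grid)) acc_grid <- list(acc_grid)
  if (is.matrix(mse_grid)) mse_grid <- list(mse_grid)
  if (length(acc_grid) == 0 || nrow(acc_grid[[1]]) == 0) stopf("empty grid")
  pick <- function(a, m) {
    wi <- as.vector(row(a)); li <- as.vector(col(a))
    ord <- order(-as.vector(a), as.vector(m), wi, li)
    j <- ord[1]
    data.frame(window_idx = wi[j], lambda_idx = li[j],
               start_ms = grid$windows$start_ms[wi[j]],
               end_ms = grid$windows$end_ms[wi[j]],
               lambda = grid$lambdas[li[j]],
               accuracy = a[wi[j], li[j]], mse = m[wi[j], li[j]])
  }
  if (mode == "group") {
    pick(Reduce(`+`, acc_grid) / length(acc_grid),
         Reduce(`+`, mse_grid) / length(mse_grid))
  } else {
    do.call(rbind, lapply(seq_along(acc_grid),
                          function(s) pick(acc_grid[[s]], mse_grid[[s]])))
  }
}

# train at one grid cell on given segments (by cache moments) and score
# the held-out segments; returns accuracy over the held-out set
validate_from_cache <- function(cache, grid, sel, train_idx, val_idx) {
  cols <- window_columns(cache, c(sel$start_ms, sel$end_ms))
  nl <- (length(cols) - 1) / cache$n_channels
  M <- penalty_matrix(nl, cache$n_channels, cache$penalty)
  A <- Reduce(`+`, lapply(train_idx, function(k) cache$S[[k]][cols, cols]))
  r <- Reduce(`+`, lapply(train_idx, function(k) cache$b_att[[k]][cols]))
  w <- solve_penalized(A, r, sel$lambda, M)
  gains <- vapply(val_idx, function(k) {
    es <- cache$env_stats[k, ]
    sa <- score_from_moments(w, cache$S[[k]][cols, cols],
                             cache$b_att[[k]][cols], es["sa"], es["ssa"], es["n"])
    si <- score_from_moments(w, cache$S[[k]][cols, cols],
                             cache$b_ign[[k]][cols], es["si"], es["ssi"], es["n"])
    if (is.na(sa["r"]) || is.na(si["r"])) 0 else unname(sa["r"] - si["r"])
  }, numeric(1))
  mean(gains > 0)
}

#' Nested cross-validation decoding accuracy
#'
#' Per repetition, `n_val` segments per subject are held out for validation;
#' an inner leave-one-out over the remaining segments produces
#' accuracy/error grids from which hyperparameters are selected (group mode
#' aggregates the inner grids across all subjects of the cohort for that
#' repetition); a model trained on all inner segments is then scored on the
#' held-out segments. Accuracies are averaged over repetitions.
#' Deterministic given `seed`.
#'
#' @param segments a `segment_set` (one subject) or a list of `segment_set`s
#'   (cohort; required for group mode to be meaningful).
#' @param grid a `hyper_grid`.
#' @param mode `"group"` or `"individual"`.
#' @param n_val validation segments per repetition (< number of segments).
#' @param n_rep number of repetitions (default 50).
#' @param seed RNG seed.
#' @param caches optional list of precomputed [grid_cache]s.
#' @return list with `mean_accuracy` (named per subject), `per_rep`
#'   (repetitions x subjects matrix).
#' @export
nested_cv_accuracy <- function(segments, grid = enumerate_hypergrid(),
                               mode = c("individual", "group"),
                               n_val = 10, n_rep = 50, seed = 1L,
                               caches = NULL) {
  mode <- match.arg(mode)
  sets <- if (inherits(segments, "segment_set")) list(segments) else segments
  nS <- length(sets)
  if (is.null(caches)) caches <- lapply(sets, grid_cache, grid = grid)
  K <- caches[[1]]$n_segments
  if (n_val >= K) stopf("n_val must be smaller than the number of segments")
  per_rep <- matrix(NA_real_, n_rep, nS)
  for (r in seq_len(n_rep)) {
    val_sets <- with_seed(derive_seed(seed, r, 7L),
                          lapply(seq_len(nS), function(s) sort(sample.int(K, n_val))))
    inner <- lapply(seq_len(nS), function(s) {
      evaluate_grid(grid = grid, cache = caches[[s]],
                    subset = setdiff(seq_len(K), val_sets[[s]]))
    })
    if (mode == "group") {
      sel <- select_hyperparameters(lapply(inner, `[[`, "accuracy"),
                                    lapply(inner, `[[`, "mse"),
                                    "group", grid)
      sels <- replicate(nS, sel, simplify = FALSE)
    } else {
      sels <- lapply(inner, function(g)
        select_hyperparameters(g$accuracy, g$mse, "group", grid))
    }
    for (s in seq_len(nS)) {
      per_rep[r, s] <- validate_from_cache(
        caches[[s]], grid, sels[[s]],
        train_idx = setdiff(seq_len(K), val_sets[[s]]),
        val_idx = val_sets[[s]])
    }
  }
  colnames(per_rep) <- vapply(caches, `[[`, "", "subject_id")
  list(mean_accuracy = colMeans(per_rep), per_rep = per_rep)
}
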