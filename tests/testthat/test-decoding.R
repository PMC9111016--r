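test_that("the hyperparameter grid has the published window/lambda structure", {
  g <- enumerate_hypergrid()
  expect_equal(nrow(g$windows), 47)
  expect_length(g$lambdas, 11)
  expect_equal(nrow(g$windows) * length(g$lambdas), 517)
  expect_equal(as.numeric(g$windows[1, ]), c(-115, -70))
  expect_equal(as.numeric(g$windows[47, ]), c(575, 620))
  expect_true(all(diff(g$windows$start_ms) == 15))
  expect_true(all(g$windows$end_ms - g$windows$start_ms == 45))
  expect_equal(g$lambdas, 10^seq(-5, 5))
})

test_that("segmentation respects block bounds and the 60-s convention", {
  fs <- 64
  n <- fs * 1800
  rec <- recording(matrix(seq_len(2 * n), 2, byrow = TRUE), fs, c("a", "b"),
                   block_bounds = list(c(0, n / 3), c(n / 3, 2 * n / 3),
                                       c(2 * n / 3, n)))
  env <- envelope_track(numeric(n), fs)
  ss <- segment_recording(rec, env, env)
  expect_length(ss$segments, 30)
  # segment k spans [k*60*fs, (k+1)*60*fs) within its block
  expect_equal(ss$segments[[2]]$eeg[1, 1], 60 * fs + 1)
  expect_equal(ss$segments[[11]]$eeg[1, 1], n / 3 + 1)

  short <- recording(matrix(0, 1, 59 * fs), fs, "a")
  e59 <- envelope_track(numeric(59 * fs), fs)
  expect_length(segment_recording(short, e59, e59)$segments, 0)
  expect_error(segment_recording(rec, envelope_track(numeric(10), fs), env),
               "misaligned")
})

test_that("lagged designs use the stated rounding, padding and bias conventions", {
  eeg <- matrix(rnorm(3 * 50), 3)
  X <- build_lagged_design(eeg, c(95, 140), 64)
  expect_equal(ncol(X), 4 * 3 + 1)              # lags {6,7,8,9} per channel
  expect_equal(X[1, 1:4], eeg[1, 7:10])          # row t reads eeg at t+tau
  expect_true(all(X[, 13] == 1))
  expect_equal(X[48, 2], 0)                      # t+7 beyond range: zero pad

  x1 <- matrix(rnorm(20), 1)
  X0 <- build_lagged_design(x1, c(0, 0), 64)
  expect_equal(X0, cbind(as.numeric(x1), 1), ignore_attr = TRUE)

  Xn <- build_lagged_design(x1, c(-115, -70), 64)  # lags {-7..-4}: row 1 pads
  expect_equal(ncol(Xn), 5)
  expect_equal(Xn[1, 1:4], rep(0, 4))
  expect_equal(Xn[10, 1], x1[1, 3])
  expect_error(build_lagged_design(eeg, c(10, 5), 64), "empty lag set")
})

test_that("training solves the penalized normal equations exactly", {
  set.seed(11)
  seg <- list(list(eeg = matrix(rnorm(4 * 200), 4), env_att = rnorm(200)))
  win <- c(0, 30)  # 3 lags x 4 channels + bias = 13 columns
  X <- build_lagged_design(seg[[1]]$eeg, win, 64)
  M <- earaad:::penalty_matrix(3, 4)

  w_ols <- qr.solve(X, seg[[1]]$env_att)
  fit0 <- train_backward_model(seg, win, 0, rate_hz = 64)
  expect_equal(fit0$w, as.numeric(w_ols), tolerance = 1e-8)

  w_direct <- solve(crossprod(X) + 1 * M, crossprod(X, seg[[1]]$env_att))
  fit1 <- train_backward_model(seg, win, 1, rate_hz = 64)
  expect_rel_error(fit1$w, as.numeric(w_direct), 1e-8)

  # heavy regularization shrinks the penalized subspace: the component of w
  # orthogonal to the penalty null space (per-channel constant lag profiles)
  # vanishes, and the overall norm never exceeds the least-squares norm
  fit9 <- train_backward_model(seg, win, 1e9, rate_hz = 64)
  null_b <- matrix(0, 13, 4)
  for (c in 1:4) null_b[((c - 1) * 3 + 1):(c * 3), c] <- 1 / sqrt(3)
  perp <- function(w) w[1:12] - (null_b[1:12, ] %*% crossprod(null_b[1:12, ], w[1:12]))
  expect_lt(sqrt(sum(perp(fit9$w)^2)), 1e-3 * sqrt(sum(perp(as.numeric(w_ols))^2)))
  expect_lte(sqrt(sum(fit9$w[1:12]^2)), sqrt(sum(w_ols[1:12]^2)) + 1e-10)

  # monotone shrinkage of the penalized norm along the lambda grid
  norms <- vapply(10^seq(-5, 5), function(l)
    sqrt(sum(train_backward_model(seg, win, l, rate_hz = 64)$w[1:12]^2)),
    numeric(1))
  expect_true(all(diff(norms) <= 1e-10))
})

test_that("the second-difference penalty is banded per channel with free bias", {
  M <- earaad:::penalty_matrix(4, 2)
  blk <- rbind(c(1, -1, 0, 0), c(-1, 2, -1, 0), c(0, -1, 2, -1), c(0, 0, -1, 1))
  expect_equal(M[1:4, 1:4], blk)
  expect_equal(M[5:8, 5:8], blk)
  expect_true(all(M[1:4, 5:8] == 0))
  expect_equal(M[9, 9], 0)
  expect_equal(earaad:::penalty_matrix(2, 1, "identity"), diag(c(1, 1, 0)))
})

test_that("reconstruction is linear and interpolates overfit training data", {
  set.seed(12)
  w0 <- train_backward_model(list(list(eeg = matrix(rnorm(100), 1),
                                       env_att = rnorm(100))),
                             c(0, 60), 1, rate_hz = 64)
  w0$w[] <- 0
  w0$w[length(w0$w)] <- 2.5
  w0$bias <- 2.5
  expect_equal(reconstruct_envelope(w0, matrix(rnorm(50), 1)), rep(2.5, 50))

  # square full-rank system: lambda = 0 reproduces its own training target
  n <- 13
  seg <- list(list(eeg = matrix(rnorm(n), 1), env_att = rnorm(n)))
  fit <- train_backward_model(seg, c(0, 170), 0, rate_hz = 64)  # 12 lags + bias
  pred <- reconstruct_envelope(fit, seg[[1]]$eeg)
  expect_gt(cor(pred, seg[[1]]$env_att), 0.999)

  # linearity in the input up to the bias
  eeg <- matrix(rnorm(40), 1)
  fitl <- train_backward_model(list(list(eeg = matrix(rnorm(80), 1),
                                         env_att = rnorm(80))),
                               c(0, 30), 1, rate_hz = 64)
  p1 <- reconstruct_envelope(fitl, eeg)
  p2 <- reconstruct_envelope(fitl, 2 * eeg)
  expect_equal(p2, 2 * p1 - fitl$bias, tolerance = 1e-10)
  expect_error(reconstruct_envelope(fitl, matrix(0, 3, 40)), "mismatch")
})

test_that("segment scoring implements the attentional-gain rule", {
  set.seed(13)
  ea <- rnorm(500); ei <- rnorm(500)
  s1 <- score_segment(ea, ea, ei)
  expect_equal(s1$corr_att, 1)
  expect_gt(s1$gain, 0)
  s2 <- score_segment(ei, ea, ei)
  expect_lt(s2$gain, 0)

  eps <- 1e-3
  noise <- rnorm(500)
  s3 <- score_segment(ea + eps * noise, ea, ei)
  expect_equal(s3$mse, eps^2 * mean(noise^2), tolerance = 1e-12)

  s4 <- score_segment(rep(1, 500), ea, ei)
  expect_true(s4$degenerate)
  expect_equal(s4$gain, 0)
})

test_that("leave-one-out recovers high-SNR toys and inverts under label swap", {
  ss <- toy_segments(n_seg = 8)
  res <- loo_accuracy(ss, c(50, 95), 1e-2)
  expect_equal(nrow(res$per_segment), 8)
  expect_gte(res$accuracy, 0.9)

  # retraining on the relabelled (wrong) envelope performs at mirror level
  swapped <- ss
  swapped$segments <- lapply(ss$segments, function(s)
    list(eeg = s$eeg, env_att = s$env_ign, env_ign = s$env_att))
  res_sw <- loo_accuracy(swapped, c(50, 95), 1e-2)
  expect_lte(res_sw$accuracy, 0.1)

  # relabelling at scoring negates every gain exactly: accuracy a -> 1 - a
  gain_relabel <- res$per_segment$corr_ign - res$per_segment$corr_att
  expect_equal(gain_relabel, -res$per_segment$gain)
  expect_equal(mean(gain_relabel > 0), 1 - res$accuracy)
})

test_that("the moment-cache grid path agrees with the direct LOO path", {
  ss <- toy_segments(n_seg = 5, n = 300)
  grid <- enumerate_hypergrid()
  g <- evaluate_grid(ss, grid)
  for (cell in list(c(12, 3), c(15, 6), c(1, 11))) {
    win <- as.numeric(grid$windows[cell[1], ])
    direct <- loo_accuracy(ss, win, grid$lambdas[cell[2]])
    expect_equal(g$accuracy[cell[1], cell[2]], direct$accuracy)
    expect_equal(g$mse[cell[1], cell[2]], mean(direct$per_segment$mse),
                 tolerance = 1e-8)
  }
})

test_that("hyperparameter selection applies the accuracy/error/order tie-breaks", {
  grid <- enumerate_hypergrid()
  a <- matrix(0, 47, 11); m <- matrix(1, 47, 11)
  a[5, 3] <- 0.9
  sel <- select_hyperparameters(a, m, "individual", grid)
  expect_equal(c(sel$window_idx, sel$lambda_idx), c(5, 3))

  # equal accuracy, lower error wins
  a2 <- a; a2[5, 4] <- 0.9
  m2 <- m; m2[5, 3] <- 0.5; m2[5, 4] <- 0.4
  sel2 <- select_hyperparameters(a2, m2, "individual", grid)
  expect_equal(c(sel2$window_idx, sel2$lambda_idx), c(5, 4))

  # full tie: earliest grid order (windows, then lambdas)
  sel3 <- select_hyperparameters(matrix(1, 47, 11), m, "individual", grid)
  expect_equal(c(sel3$window_idx, sel3$lambda_idx), c(1, 1))

  # crafted cohort where the group argmax matches no individual argmax
  s1 <- matrix(0, 47, 11); s2 <- matrix(0, 47, 11)
  s1[1, 1] <- 0.8; s1[2, 1] <- 1.0
  s2[1, 1] <- 0.8; s2[3, 1] <- 1.0
  selg <- select_hyperparameters(list(s1, s2), list(m, m), "group", grid)
  seli <- select_hyperparameters(list(s1, s2), list(m, m), "individual", grid)
  expect_equal(selg$window_idx, 1)
  expect_equal(seli$window_idx, c(2, 3))
  expect_false(selg$window_idx %in% seli$window_idx)
})

test_that("nested cross-validation is deterministic and in range", {
  ss <- toy_segments(n_seg = 6, n = 300)
  grid <- enumerate_hypergrid()
  cache <- grid_cache(ss, grid)
  r1 <- nested_cv_accuracy(ss, grid, "individual", n_val = 2, n_rep = 2,
                           seed = 9, caches = list(cache))
  r2 <- nested_cv_accuracy(ss, grid, "individual", n_val = 2, n_rep = 2,
                           seed = 9, caches = list(cache))
  expect_identical(r1, r2)
  expect_true(all(r1$per_rep >= 0 & r1$per_rep <= 1))
  expect_error(nested_cv_accuracy(ss, grid, n_val = 6, n_rep = 1,
                                  caches = list(cache)),
               "n_val")
})

test_that("binomial chance matches the exact tail-sum oracle", {
  # oracle: direct summation of binomial tail probabilities
  oracle <- function(n, p = 0.5, alpha = 0.05) {
    for (k in 1:n) {
      if (sum(dbinom(k:n, n, p)) < alpha) return(k / n)
    }
    1
  }
  expect_equal(binomial_chance(30), 20 / 30)
  expect_equal(binomial_chance(30), oracle(30))
  expect_equal(binomial_chance(10), 9 / 10)
  expect_equal(binomial_chance(10), oracle(10))
  expect_equal(binomial_chance(1), 1)
  for (n in c(5, 17, 48)) expect_equal(binomial_chance(n), oracle(n))
  expect_error(binomial_chance(30, alpha = 1.2), "alpha")
})
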