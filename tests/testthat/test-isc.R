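random_views <- function(N, D = 4, Tn = 2000, seed = 1, shared = 0) {
  set.seed(seed)
  s <- matrix(rnorm(D * Tn), D)
  lapply(seq_len(N), function(k) shared * s + matrix(rnorm(D * Tn), D))
}

test_that("pairwise covariances satisfy their defining identities", {
  v <- random_views(2, D = 3, Tn = 500, seed = 2)
  v[[2]] <- v[[1]]
  cc <- pairwise_covariances(v)
  expect_equal(cc$R[, , 1, 2], cc$R[, , 1, 1])
  expect_equal(cc$Rb, cc$R[, , 1, 2] + cc$R[, , 2, 1])

  # independent subjects: between-subject covariance vanishes with T
  big <- pairwise_covariances(random_views(3, D = 4, Tn = 50000, seed = 3))
  expect_lt(norm(big$Rb, "F") / norm(big$Rw, "F"), 0.05)
  expect_error(pairwise_covariances(list(matrix(0, 2, 10), matrix(0, 3, 10))),
               "equal shape")
})

test_that("corrca recovers a perfectly shared component", {
  set.seed(4)
  a <- c(1, -2, 0.5); a <- a / sqrt(sum(a^2))
  s <- rnorm(20000)
  v <- lapply(1:3, function(k) a %o% s + 1e-4 * matrix(rnorm(3 * 20000), 3))
  cc <- pairwise_covariances(v)
  m <- corrca(cc$Rw, cc$Rb, shrink_gamma = 0)
  w1 <- m$W[, 1]
  expect_gt(abs(sum(w1 * a)) / sqrt(sum(w1^2)), 0.99)
  expect_equal(m$eigenvalues[1], 3 - 1, tolerance = 1e-2)  # N - 1, unnormalized
  expect_equal(ncol(m$W), 3)
})

test_that("corrca with gamma = 0 matches a brute-force generalized eigensolver", {
  for (D in 4:6) {
    set.seed(D)
    A <- matrix(rnorm(D * D), D)
    Rw <- crossprod(A) + diag(D)
    B <- matrix(rnorm(D * D), D)
    Rb <- (B + t(B)) / 2
    m <- corrca(Rw, Rb, shrink_gamma = 0)
    ev <- eigen(solve(Rw, Rb))
    expect_rel_error(m$eigenvalues, sort(Re(ev$values), decreasing = TRUE), 1e-8)
    for (j in seq_len(D)) {  # verify the generalized eigen equation itself
      expect_rel_error(Rb %*% m$W[, j], m$eigenvalues[j] * (Rw %*% m$W[, j]),
                       1e-8)
    }
    expect_true(all(diff(m$eigenvalues) <= 1e-10))
  }
  expect_error(corrca(matrix(rnorm(9), 3), diag(3)), "symmetric")
})

test_that("per-subject ISC is 1 for identical data and ~0 for independent data", {
  v <- random_views(2, D = 3, Tn = 4000, seed = 5)
  v[[2]] <- v[[1]]
  cc <- pairwise_covariances(v)
  m <- corrca(cc$Rw, cc$Rb)
  isc <- subject_isc(1, 2, m$W, cc)
  expect_equal(isc, rep(1, 3), tolerance = 1e-9)

  vi <- random_views(4, D = 3, Tn = 40000, seed = 6)
  cci <- pairwise_covariances(vi)
  mi <- corrca(cci$Rw, cci$Rb)
  expect_true(all(abs(subject_isc(1, 2:4, mi$W, cci)) < 3 / sqrt(40000) * 3))
  expect_error(subject_isc(1, integer(0), m$W, cc), "empty")
  expect_error(subject_isc(1, c(1, 2), m$W, cc), "comparison group")
})

test_that("scaling one subject changes the ISC only via its closed-form terms", {
  v <- random_views(3, D = 3, Tn = 3000, seed = 7, shared = 0.7)
  cc <- pairwise_covariances(v)
  m <- corrca(cc$Rw, cc$Rb)
  v2 <- v; v2[[1]] <- 2 * v[[1]]
  cc2 <- pairwise_covariances(v2)
  isc_scaled <- subject_isc(1, 2:3, m$W, cc2)
  # algebraic oracle from the original covariances: numerator doubles,
  # denominator mixes 4*R_kk with the unchanged group term
  W <- m$W
  Rcross <- (cc$R[, , 1, 2] + cc$R[, , 2, 1] + cc$R[, , 1, 3] + cc$R[, , 3, 1]) / 4
  Rgrp <- (cc$R[, , 2, 2] + cc$R[, , 3, 3]) / 2
  num <- colSums(W * ((2 * Rcross) %*% W))
  den <- colSums(W * (((4 * cc$R[, , 1, 1] + Rgrp) / 2) %*% W))
  expect_equal(isc_scaled, num / den, tolerance = 1e-10)
})

test_that("leave-one-subject-out ISC respects grouping and hygiene", {
  v <- random_views(8, D = 4, Tn = 3000, seed = 8, shared = 0.3)
  labels <- rep(c("left", "right"), each = 4)
  res <- isc_same_other(v, labels)
  expect_equal(nrow(res$per_subject), 8)
  expect_true(all(res$basis_excludes_subject))
  expect_equal(res$per_subject$sum_same, colSums(res$isc_same[1:3, ]))

  # the basis for subject k must not depend on subject k's data
  v2 <- v
  v2[[1]] <- matrix(rnorm(4 * 3000), 4)
  res2 <- isc_same_other(v2, labels)
  expect_equal(res2$models[[1]]$W, res$models[[1]]$W)
  expect_error(isc_same_other(v, rep("left", 8)), "2 subjects per label")

  # shuffled labels destroy the same/other distinction on average
  deltas <- vapply(1:20, function(r) {
    set.seed(100 + r)
    lab <- sample(labels)
    rs <- isc_same_other(v, lab)
    mean(rs$per_subject$sum_same - rs$per_subject$sum_other)
  }, numeric(1))
  expect_lt(abs(mean(deltas)), 0.02)
})

test_that("circular shifts preserve within-subject covariance", {
  v <- random_views(2, D = 3, Tn = 1000, seed = 9)
  shifted <- v[[1]][, c(301:1000, 1:300)]
  c1 <- tcrossprod(v[[1]] - rowMeans(v[[1]])) / 1000
  c2 <- tcrossprod(shifted - rowMeans(shifted)) / 1000
  expect_equal(c1, c2, tolerance = 1e-12)

  null <- circular_shift_null(random_views(4, D = 3, Tn = 2000, seed = 10),
                              rep(c("left", "right"), each = 2),
                              n_perm = 5, seed = 3)
  expect_length(null$chance_same, 3)
  expect_true(all(is.finite(null$chance_same)))
})

test_that("ROC classification scores and chance behave canonically", {
  # perfectly separated scores
  expect_equal(earaad:::auc_score(c(5, 6, 7, 1, 2, 3), rep(c(TRUE, FALSE), each = 3)), 1)
  expect_equal(earaad:::auc_score(1:6, rep(c(TRUE, FALSE), each = 3)), 0)
  # label-independent scores give AUC ~ 0.5 on average
  set.seed(11)
  aucs <- replicate(300, earaad:::auc_score(rnorm(16), sample(rep(c(TRUE, FALSE), 8))))
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(12)
    sc <- rnorm(20); lb <- sample(rep(c(TRUE, FALSE), 10))
    expect_equal(earaad:::auc_score(sc, lb),
                 as.numeric(pROC::auc(lb, sc, direction = "<", quiet = TRUE)))
  }
  v <- random_views(6, D = 3, Tn = 2000, seed = 13, shared = 0.3)
  expect_error(classify_direction(v, c("left", rep("right", 5))),
               "at least 2 members")
})

test_that("spatial patterns reduce to filters for white data and ignore scale", {
  set.seed(14)
  W <- qr.Q(qr(matrix(rnorm(16), 4)))
  W <- W %*% diag(sign(apply(W, 2, function(c) c[which.max(abs(c))])))
  expect_equal(spatial_patterns(W, diag(4)), W, tolerance = 1e-10)
  A <- matrix(rnorm(16), 4)
  Rw <- crossprod(A) + diag(4)
  expect_equal(spatial_patterns(W, Rw), spatial_patterns(W, 2 * Rw),
               tolerance = 1e-10)
})
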