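#' Pairwise channel covariances across subjects
#'
#' For mean-centered channel x sample views `X_k`, computes
#' `R_kl = (1/T) X_k X_l'` for all ordered pairs, the pooled within-subject
#' covariance `Rw = sum_k R_kk` and between-subject covariance
#' `Rb = sum_{k != l} R_kl`.
#'
#' @param views list of channels x samples matrices of equal shape (centered
#'   per channel internally).
#' @return list with `R` (D x D x N x N array), `Rw`, `Rb`, `N`, `D`.
#' @export
pairwise_covariances <- function(views) {
  N <- length(views)
  if (N < 1) stopf("need at least one view")
  dims <- vapply(views, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stopf("all views must have equal shape")
  }
  D <- dims[1, 1]; Tn <- dims[2, 1]
  Xc <- lapply(views, function(X) X - rowMeans(X))
  R <- array(0, c(D, D, N, N))
  for (k in seq_len(N)) {
    for (l in k:N) {
      Rkl <- tcrossprod(Xc[[k]], Xc[[l]]) / Tn
      R[, , k, l] <- Rkl
      if (l != k) R[, , l, k] <- t(Rkl)
    }
  }
  Rw <- matrix(0, D, D); Rb <- matrix(0, D, D)
  for (k in seq_len(N)) {
    for (l in seq_len(N)) {
      if (k == l) Rw <- Rw + R[, , k, k] else Rb <- Rb + R[, , k, l]
    }
  }
  list(R = R, Rw = Rw, Rb = Rb, N = N, D = D)
}

# pooled Rw/Rb restricted to a subset of subjects, from the cached array
pooled_cov_subset <- function(cov_cache, ids) {
  D <- cov_cache$D
  Rw <- matrix(0, D, D); Rb <- matrix(0, D, D)
  for (k in ids) {
    for (l in ids) {
      if (k == l) Rw <- Rw + cov_cache$R[, , k, k]
      else Rb <- Rb + cov_cache$R[, , k, l]
    }
  }
  list(Rw = Rw, Rb = Rb)
}

#' Correlated component analysis
#'
#' Finds projections that are maximally correlated between subjects by
#' solving the generalized eigenproblem `Rb w = rho * Rw~ w`, with
#' `Rw~ = (1 - gamma) Rw + gamma * (tr(Rw)/D) I` (diagonal shrinkage for
#' invertibility; set `rank_truncate = TRUE` to project onto the principal
#' subspace of `Rw` instead). The number of components equals the number of
#' channels; components are sorted by descending eigenvalue and sign-fixed so
#' that the largest-magnitude entry of each spatial pattern is positive.
#'
#' @param Rw,Rb pooled within/between covariance matrices (symmetric).
#' @param shrink_gamma shrinkage weight in `[0, 1)` (default 0.01).
#' @param rank_truncate if TRUE, rank-truncate `Rw` instead of shrinking.
#' @return A `corrca_model`: list with `W` (channels x components
#'   projections), `eigenvalues`, `A` (spatial patterns), `gamma`.
#' @export
corrca <- function(Rw, Rb, shrink_gamma = 0.01, rank_truncate = FALSE) {
  D <- nrow(Rw)
  if (max(abs(Rw - t(Rw))) > 1e-8 * max(abs(Rw), 1)) {
    stopf("Rw must be symmetric")
  }
  if (max(abs(Rb - t(Rb))) > 1e-8 * max(abs(Rb), 1)) {
    stopf("Rb must be symmetric")
  }
  Rw <- (Rw + t(Rw)) / 2
  Rb <- (Rb + t(Rb)) / 2
  if (rank_truncate) {
    e <- eigen(Rw, symmetric = TRUE)
    tol <- max(e$values) * D * .Machine$double.eps * 100
    r <- max(sum(e$values > tol), 1L)
    P <- e$vectors[, seq_len(r), drop = FALSE]
    Li <- P %*% diag(1 / sqrt(e$values[seq_len(r)]), r)
    eg <- eigen(crossprod(Li, Rb %*% Li), symmetric = TRUE)
    W <- Li %*% eg$vectors
    rho <- eg$values
    if (r < D) {  # pad null-space components with zero eigenvalue
      W <- cbind(W, e$vectors[, (r + 1):D, drop = FALSE])
      rho <- c(rho, rep(0, D - r))
    }
    Rwt <- Rw
  } else {
    Rwt <- (1 - shrink_gamma) * Rw +
      shrink_gamma * (sum(diag(Rw)) / D) * diag(D)
    ch <- chol(Rwt)
    Li <- backsolve(ch, diag(D))  # Rwt^{-1/2} (upper-triangular inverse)
    eg <- eigen(crossprod(Li, Rb %*% Li), symmetric = TRUE)
    W <- Li %*% eg$vectors
    rho <- eg$values
  }
  ord <- order(rho, decreasing = TRUE)
  W <- W[, ord, drop = FALSE]
  rho <- rho[ord]
  A <- patterns_from_filters(W, Rwt)
  # sign fix: largest-|entry| of each pattern positive
  for (j in seq_len(ncol(A))) {
    if (A[which.max(abs(A[, j])), j] < 0) {
      A[, j] <- -A[, j]
      W[, j] <- -W[, j]
    }
  }
  structure(list(W = W, eigenvalues = rho, A = A,
                 gamma = if (rank_truncate) NA_real_ else shrink_gamma),
            class = "corrca_model")
}

#' @export
print.corrca_model <- function(x, ...) {
  cat(sprintf("<corrca_model> %d components; top eigenvalues: %s\n",
              ncol(x$W),
              paste(signif(utils::head(x$eigenvalues, 3), 3), collapse = ", ")))
  invisible(x)
}

patterns_from_filters <- function(W, Rw) {
  G <- crossprod(W, Rw %*% W)
  Gi <- tryCatch(solve(G), error = function(e) {
    warning("singular W' Rw W; using pseudo-inverse", call. = FALSE)
    pinv(G)
  })
  Rw %*% W %*% Gi
}

#' Transform projection vectors (spatial filters) into spatial patterns
#'
#' `A = Rw W (W' Rw W)^-1`, sign-fixed so the largest-magnitude entry of
#' each column is positive. Patterns, unlike filters, are physiologically
#' interpretable as component topographies.
#'
#' @param W channels x components projection matrix.
#' @param Rw pooled within-subject covariance.
#' @return channels x components pattern matrix.
#' @export
spatial_patterns <- function(W, Rw) {
  A <- patterns_from_filters(W, Rw)
  for (j in seq_len(ncol(A))) {
    if (A[which.max(abs(A[, j])), j] < 0) A[, j] <- -A[, j]
  }
  A
}

#' Per-component intersubject correlation of one subject with a group
#'
#' For each component `c` with projection `w_c`:
#' `rho = [w' (mean_l (R_kl + R_lk)/2) w] / [w' ((R_kk + mean_l R_ll)/2) w]`.
#'
#' @param k subject index (not in `group_ids`).
#' @param group_ids indices of the comparison group (non-empty).
#' @param W channels x components projection matrix.
#' @param cov_cache result of [pairwise_covariances].
#' @return numeric vector of per-component ISC values.
#' @export
subject_isc <- function(k, group_ids, W, cov_cache) {
  if (length(group_ids) == 0) stopf("empty comparison group")
  if (k %in% group_ids) stopf("subject %d must not be in its own comparison group", k)
  D <- cov_cache$D
  Rcross <- matrix(0, D, D)
  Rgrp <- matrix(0, D, D)
  for (l in group_ids) {
    Rcross <- Rcross + (cov_cache$R[, , k, l] + cov_cache$R[, , l, k]) / 2
    Rgrp <- Rgrp + cov_cache$R[, , l, l]
  }
  Rcross <- Rcross / length(group_ids)
  Rgrp <- Rgrp / length(group_ids)
  Rden <- (cov_cache$R[, , k, k] + Rgrp) / 2
  num <- colSums(W * (Rcross %*% W))
  den <- colSums(W * (Rden %*% W))
  ifelse(den > 0, num / den, 0)
}

#' Leave-one-subject-out ISC under same/other attended-stream groupings
#'
#' For each subject, the projection basis is computed by correlated component
#' analysis on all other subjects; the subject's per-component ISC is then
#' evaluated against the group attending the same stream (`isc_same`) and the
#' group attending the other stream (`isc_other`). Sum scores add components
#' 1-3.
#'
#' @param views list of channels x samples matrices, or a precomputed
#'   `cov_cache` from [pairwise_covariances].
#' @param labels character vector (`"left"`/`"right"`), one per subject;
#'   at least 2 subjects per label.
#' @param shrink_gamma,rank_truncate passed to [corrca].
#' @return An `isc_result`: list with `per_subject` (data.frame `subject`,
#'   `label`, `sum_same`, `sum_other`), `isc_same`/`isc_other` (components x
#'   subjects matrices), `models` (per-subject `corrca_model`s),
#'   `basis_excludes_subject` (bookkeeping flag per subject).
#' @export
isc_same_other <- function(views, labels, shrink_gamma = 0.01,
                           rank_truncate = FALSE) {
  cc <- if (is.list(views) && !is.null(views$R)) views else pairwise_covariances(views)
  N <- cc$N
  if (length(labels) != N) stopf("need one label per subject")
  if (any(table(factor(labels, levels = c("left", "right"))) < 2)) {
    stopf("need at least 2 subjects per label")
  }
  isc_s <- isc_o <- matrix(0, cc$D, N)
  models <- vector("list", N)
  excl_ok <- logical(N)
  for (k in seq_len(N)) {
    others <- setdiff(seq_len(N), k)
    excl_ok[k] <- !(k %in% others)
    pc <- pooled_cov_subset(cc, others)
    m <- corrca(pc$Rw, pc$Rb, shrink_gamma, rank_truncate)
    models[[k]] <- m
    same <- others[labels[others] == labels[k]]
    other <- others[labels[others] != labels[k]]
    isc_s[, k] <- subject_isc(k, same, m$W, cc)
    isc_o[, k] <- subject_isc(k, other, m$W, cc)
  }
  per_subject <- data.frame(subject = seq_len(N), label = labels,
                            sum_same = colSums(isc_s[1:3, , drop = FALSE]),
                            sum_other = colSums(isc_o[1:3, , drop = FALSE]))
  structure(list(per_subject = per_subject, isc_same = isc_s,
                 isc_other = isc_o, models = models,
                 basis_excludes_subject = excl_ok),
            class = "isc_result")
}

#' @export
print.isc_result <- function(x, ...) {
  cat(sprintf("<isc_result> %d subjects; mean sum_same %.4f, mean sum_other %.4f\n",
              nrow(x$per_subject), mean(x$per_subject$sum_same),
              mean(x$per_subject$sum_other)))
  invisible(x)
}

#' Circular-shift surrogate chance levels for ISC
#'
#' Each permutation circularly shifts every subject's multichannel data by
#' its own uniform random offset in `[1, T-1]` (the same shift for all
#' channels of a subject), destroying cross-subject alignment while keeping
#' within-subject structure; the full leave-one-subject-out ISC analysis is
#' recomputed and the 95th percentiles (pooled over subjects) per component
#' and condition are returned as chance levels.
#'
#' @param views list of channels x samples matrices.
#' @param labels attended-stream labels.
#' @param n_perm number of permutations (default 100).
#' @param seed RNG seed.
#' @param shrink_gamma passed to [corrca].
#' @return list with `chance_same`, `chance_other` (per-component 95th
#'   percentiles) and `perm_same`, `perm_other` (components x (subjects *
#'   permutations) samples).
#' @export
circular_shift_null <- function(views, labels, n_perm = 100, seed = 1L,
                                shrink_gamma = 0.01) {
  if (n_perm < 1) stopf("n_perm must be >= 1")
  Tn <- ncol(views[[1]])
  D <- nrow(views[[1]])
  N <- length(views)
  ps <- po <- vector("list", n_perm)
  for (p in seq_len(n_perm)) {
    shifts <- with_seed(derive_seed(seed, p, 13L),
                        sample.int(Tn - 1, N, replace = TRUE))
    shifted <- lapply(seq_len(N), function(k) {
      s <- shifts[k]
      views[[k]][, c((s + 1):Tn, 1:s), drop = FALSE]
    })
    res <- isc_same_other(shifted, labels, shrink_gamma)
    ps[[p]] <- res$isc_same
    po[[p]] <- res$isc_other
  }
  perm_same <- do.call(cbind, ps)
  perm_other <- do.call(cbind, po)
  list(chance_same = apply(perm_same, 1, stats::quantile, probs = 0.95),
       chance_other = apply(perm_other, 1, stats::quantile, probs = 0.95),
       perm_same = perm_same, perm_other = perm_other)
}

# Mann-Whitney AUC of scores for a binary response (TRUE = positive class)
auc_score <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classify the attended direction from ISC sum scores
#'
#' Two projection bases are trained (on left-attending and right-attending
#' subjects respectively, always excluding the scored subject); each
#' subject's top-3 ISC sum against the left group (`isc_left_sum`) and right
#' group (`isc_right_sum`) is computed, and classification accuracy is the
#' area under the ROC curve. Chance level is the 95th percentile of AUCs
#' under label shuffling, pooled over both classifications.
#'
#' @param views list of channels x samples matrices.
#' @param labels attended-stream labels (`"left"`/`"right"`, both present
#'   with >= 2 members each).
#' @param n_perm number of label permutations for the chance level
#'   (default 1000).
#' @param seed RNG seed.
#' @param shrink_gamma passed to [corrca].
#' @return list with `auc_left`, `auc_right`, `auc_chance`, `scores`
#'   (data.frame `subject`, `label`, `isc_left_sum`, `isc_right_sum`).
#' @export
classify_direction <- function(views, labels, n_perm = 1000, seed = 1L,
                               shrink_gamma = 0.01) {
  N <- length(views)
  tab <- table(factor(labels, levels = c("left", "right")))
  if (any(tab < 2)) stopf("each label class needs at least 2 members")
  cc <- pairwise_covariances(views)
  score <- matrix(0, N, 2, dimnames = list(NULL, c("left", "right")))
  for (k in seq_len(N)) {
    for (stream in c("left", "right")) {
      grp <- setdiff(which(labels == stream), k)
      if (length(grp) < 2) stopf("class \"%s\" too small after excluding subject %d",
                                 stream, k)
      pc <- pooled_cov_subset(cc, grp)
      m <- corrca(pc$Rw, pc$Rb, shrink_gamma)
      isc <- subject_isc(k, grp, m$W, cc)
      score[k, stream] <- sum(isc[1:3])
    }
  }
  auc_left <- auc_score(score[, "left"], labels == "left")
  auc_right <- auc_score(score[, "right"], labels == "right")
  perm <- with_seed(derive_seed(seed, 0L, 17L), {
    unlist(lapply(seq_len(n_perm), function(p) {
      lp <- sample(labels)
      c(auc_score(score[, "left"], lp == "left"),
        auc_score(score[, "right"], lp == "right"))
    }))
  })
  list(auc_left = auc_left, auc_right = auc_right,
       auc_chance = as.numeric(stats::quantile(perm, 0.95, na.rm = TRUE)),
       scores = data.frame(subject = seq_len(N), label = labels,
                           isc_left_sum = score[, "left"],
                           isc_right_sum = score[, "right"]))
}
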