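#' Paired two-sided comparison
#'
#' Wilcoxon signed-rank test (zero differences dropped; exact p via the
#' signed-rank distribution for n <= 25 without ties, normal-approximation Z
#' otherwise, no continuity correction) or paired t-test, both against their
#' textbook definitions.
#'
#' @param a,b paired numeric vectors (length >= 5).
#' @param test `"wilcoxon_signed_rank"` or `"paired_t"`.
#' @return list with `statistic` (Z or t), `p`, `n` (pairs used), `method`.
#' @export
paired_compare <- function(a, b, test = c("wilcoxon_signed_rank", "paired_t")) {
  test <- match.arg(test)
  if (length(a) != length(b)) stopf("paired vectors must have equal length")
  if (length(a) < 5) stopf("need at least 5 pairs")
  d <- a - b
  if (test == "paired_t") {
    s <- stats::sd(d)
    if (s == 0) stopf("degenerate input: zero-variance differences")
    n <- length(d)
    t <- mean(d) / (s / sqrt(n))
    return(list(statistic = t, p = 2 * stats::pt(-abs(t), n - 1),
                n = n, method = "paired_t"))
  }
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stopf("degenerate input: all differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  Z <- (W - mu) / sigma
  ties <- anyDuplicated(abs(d)) > 0
  p <- if (n <= 25 && !ties) {
    min(1, 2 * min(stats::psignrank(W, n), stats::psignrank(W - 1, n, lower.tail = FALSE)))
  } else {
    2 * stats::pnorm(-abs(Z))
  }
  list(statistic = Z, p = p, n = n, method = "wilcoxon_signed_rank")
}

#' Spearman rank correlation with t-approximation p-value
#'
#' @param x,y numeric vectors (length >= 4, non-constant). Ties receive
#'   average ranks.
#' @return list with `rho`, `p`, `n`.
#' @export
correlate_measures <- function(x, y) {
  if (length(x) != length(y)) stopf("vectors must have equal length")
  n <- length(x)
  if (n < 4) stopf("need at least 4 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("degenerate input: constant vector")
  }
  rho <- stats::cor(rank(x), rank(y))
  t <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * stats::pt(-abs(t), n - 2), n = n)
}

# ---- pipeline ------------------------------------------------------------

#' Default pipeline configuration
#'
#' @param seed master seed for every stochastic stage.
#' @param cohort list of [cohort_config] arguments (the generator's
#'   defaults are the study conditions).
#' @param ... named sections overriding the defaults (`preprocess`,
#'   `decode`, `isc`, `entropy`).
#' @return nested configuration list.
#' @export
pipeline_config <- function(seed = 1L, cohort = list(), ...) {
  cfg <- list(
    seed = as.integer(seed),
    cohort = cohort,
    preprocess = list(asr = TRUE, asr_cutoff = 10, latency_shift_samples = 0),
    decode = list(target_rate_hz = 64, nested_n_rep = 10, nested_n_val = 10,
                  run_nested = TRUE),
    isc = list(block = 1, target_rate_hz = 250, n_perm = 100,
               n_perm_auc = 1000, shrink_gamma = 0.01),
    entropy = list(band = c(8, 32), n_tapers = 7, corr_threshold = 0.6))
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("[%s] %s", name, conditionMessage(e))
  })
}

#' Preprocess a recording for envelope decoding
#'
#' Order of operations: drift-removal highpass (0.5 Hz Butterworth,
#' zero-phase) -> optional artifact subspace reconstruction -> 8 Hz FIR
#' lowpass (Hann, order 100) -> 2 Hz FIR highpass (Hann, order 500) ->
#' per-channel SD normalization -> downsample to `target_rate`.
#'
#' @param rec a [recording].
#' @param asr run artifact subspace reconstruction (default TRUE).
#' @param asr_cutoff ASR threshold multiplier (default 10).
#' @param target_rate output rate in Hz (default 64).
#' @return A preprocessed [recording].
#' @export
preprocess_decoding <- function(rec, asr = TRUE, asr_cutoff = 10,
                                target_rate = 64) {
  hp <- apply_filter(rec, filter_spec("highpass", 0.5, "butterworth", 4))
  if (asr) {
    model <- asr_calibrate(hp, cutoff_k = asr_cutoff)
    hp <- asr_correct(hp, model)
  }
  lp <- apply_filter(hp, filter_spec("lowpass", 8, "fir_hann", 100))
  bp <- apply_filter(lp, filter_spec("highpass", 2, "fir_hann", 500))
  bp$data <- bp$data / apply(bp$data, 1, stats::sd)
  resample_to(bp, target_rate)
}

#' Preprocess a recording for intersubject-correlation analysis
#'
#' Drift-removal highpass -> optional artifact subspace reconstruction ->
#' 40 Hz FIR lowpass (Hann, order 100) -> 1 Hz FIR highpass (Hann, order
#' 500) -> downsample to `target_rate` (250 Hz; a no-op if the recording is
#' already at or below it).
#'
#' @inheritParams preprocess_decoding
#' @param target_rate output rate in Hz (default 250).
#' @return A preprocessed [recording].
#' @export
preprocess_isc <- function(rec, asr = TRUE, asr_cutoff = 10,
                           target_rate = 250) {
  hp <- apply_filter(rec, filter_spec("highpass", 0.5, "butterworth", 4))
  if (asr) {
    model <- asr_calibrate(hp, cutoff_k = asr_cutoff)
    hp <- asr_correct(hp, model)
  }
  lp <- apply_filter(hp, filter_spec("lowpass", 40, "fir_hann", 100))
  bp <- apply_filter(lp, filter_spec("highpass", 1, "fir_hann", 500))
  resample_to(bp, min(target_rate, bp$rate_hz))
}

# extract one block of a recording as its own single-block recording
crop_block <- function(rec, block) {
  b <- rec$block_bounds[[block]]
  out <- rec
  out$data <- rec$data[, (b[1] + 1):b[2], drop = FALSE]
  out$block_bounds <- list(c(0L, b[2] - b[1]))
  out
}

#' Run the full attention-analysis pipeline
#'
#' Generates (or loads) a competing-speaker cohort, then runs the three
#' analyses end to end: envelope decoding (hyperparameter grid, group and
#' individual selection, standard leave-one-out and nested cross-validation),
#' intersubject correlation (leave-one-subject-out correlated component
#' analysis with circular-shift chance levels and left/right ROC
#' classification), and multitaper spectral entropy / alpha-power trends;
#' finally the three per-subject measures are cross-correlated. All outputs
#' are written as CSV plus a `summary.json`; runs are bit-identical for
#' identical config and seed.
#'
#' @param config a [pipeline_config] list (or path to a YAML file with the
#'   same structure).
#' @param out_dir output directory, created if missing.
#' @param cohort optional pre-built `cohort` (e.g. from [read_cohort]);
#'   generated from `config$cohort` when NULL. Set
#'   `config$cohort$manifest` to load one from disk.
#' @return invisibly, a list with all stage results and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("report"),
                         cohort = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed)

  cohort <- stage("cohort", {
    if (!is.null(cohort)) cohort
    else if (!is.null(config$cohort$manifest)) read_cohort(config$cohort$manifest)
    else {
      args <- config$cohort
      args$manifest <- NULL
      args$seed <- if (is.null(args$seed)) seed else args$seed
      simulate_cohort(do.call(cohort_config, args))
    }
  })
  nS <- length(cohort$recordings)
  labels <- vapply(cohort$recordings, `[[`, "", "attended")
  subjects <- vapply(cohort$recordings, `[[`, "", "subject_id")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # ---- decoding path -----------------------------------------------------
  dec <- stage("decoding", {
    grid <- enumerate_hypergrid()
    fs_dec <- config$decode$target_rate_hz
    caches <- vector("list", nS)
    seg_sets <- vector("list", nS)
    audits <- vector("list", nS)
    for (i in seq_len(nS)) {
      rec <- shift_latency(cohort$recordings[[i]],
                           config$preprocess$latency_shift_samples)
      pre <- preprocess_decoding(rec, config$preprocess$asr,
                                 config$preprocess$asr_cutoff, fs_dec)
      ea <- resample_to(if (labels[i] == "left") cohort$env_left else cohort$env_right,
                        fs_dec)
      ei <- resample_to(if (labels[i] == "left") cohort$env_right else cohort$env_left,
                        fs_dec)
      seg_sets[[i]] <- segment_recording(pre, ea, ei)
      caches[[i]] <- grid_cache(seg_sets[[i]], grid)
    }
    grids <- lapply(caches, function(cc) evaluate_grid(grid = grid, cache = cc))
    accs <- lapply(grids, `[[`, "accuracy")
    mses <- lapply(grids, `[[`, "mse")
    sel_group <- select_hyperparameters(accs, mses, "group", grid)
    sel_ind <- select_hyperparameters(accs, mses, "individual", grid)
    acc_group <- vapply(seq_len(nS), function(i)
      accs[[i]][sel_group$window_idx, sel_group$lambda_idx], numeric(1))
    acc_ind <- vapply(seq_len(nS), function(i)
      accs[[i]][sel_ind$window_idx[i], sel_ind$lambda_idx[i]], numeric(1))
    loo <- lapply(seq_len(nS), function(i)
      loo_accuracy(seg_sets[[i]],
                   c(sel_ind$start_ms[i], sel_ind$end_ms[i]),
                   sel_ind$lambda[i]))
    nested <- NULL
    if (isTRUE(config$decode$run_nested)) {
      nested <- list(
        group = nested_cv_accuracy(seg_sets, grid, "group",
                                   n_val = config$decode$nested_n_val,
                                   n_rep = config$decode$nested_n_rep,
                                   seed = derive_seed(seed, 0L, 23L),
                                   caches = caches),
        individual = nested_cv_accuracy(seg_sets, grid, "individual",
                                        n_val = config$decode$nested_n_val,
                                        n_rep = config$decode$nested_n_rep,
                                        seed = derive_seed(seed, 0L, 23L),
                                        caches = caches))
    }
    list(grid = grid, accs = accs, mses = mses, sel_group = sel_group,
         sel_ind = sel_ind, acc_group = acc_group, acc_ind = acc_ind,
         loo = loo, nested = nested,
         chance = binomial_chance(caches[[1]]$n_segments))
  })

  # ---- ISC path ----------------------------------------------------------
  isc <- stage("isc", {
    views <- lapply(cohort$recordings, function(rec) {
      pre <- preprocess_isc(crop_block(rec, config$isc$block),
                            config$preprocess$asr, config$preprocess$asr_cutoff,
                            config$isc$target_rate_hz)
      pre$data
    })
    res <- isc_same_other(views, labels, config$isc$shrink_gamma)
    null <- circular_shift_null(views, labels, config$isc$n_perm,
                                seed = derive_seed(seed, 0L, 29L),
                                shrink_gamma = config$isc$shrink_gamma)
    cls <- classify_direction(views, labels, config$isc$n_perm_auc,
                              seed = derive_seed(seed, 0L, 31L),
                              shrink_gamma = config$isc$shrink_gamma)
    cc_all <- pairwise_covariances(views)
    m_all <- corrca(cc_all$Rw, cc_all$Rb, config$isc$shrink_gamma)
    list(result = res, null = null, classify = cls, patterns = m_all$A)
  })

  # ---- entropy path ------------------------------------------------------
  ent <- stage("entropy", {
    courses <- lapply(cohort$recordings, function(rec) {
      hp <- apply_filter(rec, filter_spec("highpass", 0.5, "butterworth", 4))
      if (isTRUE(config$preprocess$asr)) {
        hp <- asr_correct(hp, asr_calibrate(hp, config$preprocess$asr_cutoff))
      }
      bad <- flag_bad_channels(hp, config$entropy$corr_threshold)
      if (length(bad) >= n_channels(hp)) bad <- character()
      entropy_timecourse(hp, bad, band = config$entropy$band,
                         n_tapers = config$entropy$n_tapers)
    })
    n_seg <- nrow(courses[[1]]$per_segment)
    grand_H <- rowMeans(vapply(courses, function(cr) cr$per_segment$H,
                               numeric(n_seg)))
    grand_alpha <- rowMeans(vapply(courses, function(cr) cr$per_segment$alpha,
                                   numeric(n_seg)))
    trend_H <- correlate_measures(seq_len(n_seg), grand_H)
    trend_alpha <- correlate_measures(seq_len(n_seg), grand_alpha)
    list(courses = courses, grand_H = grand_H, grand_alpha = grand_alpha,
         trend_H = trend_H, trend_alpha = trend_alpha)
  })

  # ---- cross-measure relations -------------------------------------------
  rel <- stage("report", {
    measures <- data.frame(
      subject = subjects, label = labels,
      mean_gain = vapply(dec$loo, function(r) mean(r$per_segment$gain), numeric(1)),
      isc_effect = isc$result$per_subject$sum_same - isc$result$per_subject$sum_other,
      mean_entropy = vapply(ent$courses, function(cr) mean(cr$per_segment$H),
                            numeric(1)),
      decoding_accuracy = vapply(dec$loo, `[[`, numeric(1), "accuracy"))
    list(measures = measures,
         gain_vs_isc = correlate_measures(measures$mean_gain, measures$isc_effect),
         gain_vs_entropy = correlate_measures(measures$mean_gain,
                                              measures$mean_entropy),
         isc_vs_entropy = correlate_measures(measures$isc_effect,
                                             measures$mean_entropy),
         isc_same_vs_other = paired_compare(isc$result$per_subject$sum_same,
                                            isc$result$per_subject$sum_other,
                                            "paired_t"))
  })

  # ---- write outputs -----------------------------------------------------
  stage("write", {
    seg_rows <- do.call(rbind, lapply(seq_len(nS), function(i) {
      df <- dec$loo[[i]]$per_segment
      df$subject <- subjects[i]
      df
    }))
    write_csv_out(seg_rows, file.path(out_dir, "decoding_segments.csv"))
    grid_df <- expand.grid(window_idx = seq_len(nrow(dec$grid$windows)),
                           lambda_idx = seq_along(dec$grid$lambdas))
    grid_df$window_start_ms <- dec$grid$windows$start_ms[grid_df$window_idx]
    grid_df$window_end_ms <- dec$grid$windows$end_ms[grid_df$window_idx]
    grid_df$lambda <- dec$grid$lambdas[grid_df$lambda_idx]
    ga <- Reduce(`+`, dec$accs) / nS
    gm <- Reduce(`+`, dec$mses) / nS
    grid_df$accuracy <- ga[cbind(grid_df$window_idx, grid_df$lambda_idx)]
    grid_df$mse <- gm[cbind(grid_df$window_idx, grid_df$lambda_idx)]
    write_csv_out(grid_df, file.path(out_dir, "decoding_grid.csv"))
    isc_df <- isc$result$per_subject
    isc_df$isc_left_sum <- isc$classify$scores$isc_left_sum
    isc_df$isc_right_sum <- isc$classify$scores$isc_right_sum
    write_csv_out(isc_df, file.path(out_dir, "isc_subjects.csv"))
    write_csv_out(as.data.frame(isc$patterns),
                  file.path(out_dir, "isc_patterns.csv"))
    ent_rows <- do.call(rbind, lapply(seq_len(nS), function(i) {
      df <- ent$courses[[i]]$per_segment
      df$subject <- subjects[i]
      df
    }))
    write_csv_out(ent_rows, file.path(out_dir, "entropy_segments.csv"))
    write_csv_out(rel$measures, file.path(out_dir, "measures.csv"))
    summary <- list(
      seed = seed,
      n_subjects = nS,
      decoding = list(
        chance = dec$chance,
        group_hyperparameters = as.list(dec$sel_group),
        mean_accuracy_group = mean(dec$acc_group),
        mean_accuracy_individual = mean(dec$acc_ind),
        nested = if (is.null(dec$nested)) NULL else list(
          mean_accuracy_group = mean(dec$nested$group$mean_accuracy),
          mean_accuracy_individual = mean(dec$nested$individual$mean_accuracy))),
      isc = list(
        mean_sum_same = mean(isc$result$per_subject$sum_same),
        mean_sum_other = mean(isc$result$per_subject$sum_other),
        chance_same_top3 = unname(isc$null$chance_same[1:3]),
        auc_left = isc$classify$auc_left,
        auc_right = isc$classify$auc_right,
        auc_chance = isc$classify$auc_chance,
        same_vs_other_t = rel$isc_same_vs_other$statistic,
        same_vs_other_p = rel$isc_same_vs_other$p),
      entropy = list(rho_H = ent$trend_H$rho, p_H = ent$trend_H$p,
                     rho_alpha = ent$trend_alpha$rho, p_alpha = ent$trend_alpha$p),
      relations = list(
        gain_vs_isc_rho = rel$gain_vs_isc$rho, gain_vs_isc_p = rel$gain_vs_isc$p,
        gain_vs_entropy_rho = rel$gain_vs_entropy$rho,
        isc_vs_entropy_rho = rel$isc_vs_entropy$rho))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  })

  invisible(list(cohort = cohort, decoding = dec, isc = isc, entropy = ent,
                 relations = rel, out_dir = out_dir))
}

# deterministic CSV writer (fixed significant digits, no row names)
write_csv_out <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  utils::write.csv(df, path, row.names = FALSE)
}
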