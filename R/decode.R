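#' Build time-resolved decoding windows
#'
#' Incremental mode grows a window in 100 ms steps: trial windows
#' `[0, 0.1), [0, 0.2), ...` up to `trial_end`, and baseline windows built
#' the same way from `baseline_start` up to trial onset (the two families
#' are kept separate). The per-window time cost `T` is the window end minus
#' the start of its segment. Sliding mode moves a 1 s window in 50 ms steps
#' across the whole epoch; `T` is the window end measured from
#' `baseline_start` (absolute elapsed recording time).
#'
#' @param timing epoch timing (as in [bb_epochs()]).
#' @param mode `"incremental"` or `"sliding"`.
#' @param step increment of the incremental window, s.
#' @param first first incremental window length, s.
#' @param slide_length,slide_step sliding-window length and step, s.
#' @return an object of class `bb_windows`: a data.frame with `start`,
#'   `end`, `T`, `segment`, plus the mode.
#' @export
build_windows <- function(timing, mode = c("incremental", "sliding"),
                          step = 0.1, first = 0.1,
                          slide_length = 1.0, slide_step = 0.05) {
  mode <- match.arg(mode)
  tol <- 1e-9
  if (mode == "incremental") {
    if (timing$trial_end < first - tol)
      stop("trial period shorter than the first window")
    ends_tr <- seq(first, timing$trial_end + tol, by = step)
    trial <- data.frame(start = 0, end = ends_tr, T = ends_tr,
                        segment = "trial")
    ends_bl <- seq(timing$baseline_start + first, timing$trial_onset + tol,
                   by = step)
    baseline <- data.frame(start = timing$baseline_start, end = ends_bl,
                           T = ends_bl - timing$baseline_start,
                           segment = "baseline")
    windows <- rbind(baseline, trial)
  } else {
    starts <- seq(timing$baseline_start,
                  timing$post_end - slide_length + tol, by = slide_step)
    windows <- data.frame(start = starts, end = starts + slide_length,
                          T = starts + slide_length - timing$baseline_start,
                          segment = "sliding")
  }
  if (any(windows$T <= 0)) stop("window time cost T must be > 0")
  structure(list(windows = windows, mode = mode), class = "bb_windows")
}

#' Train a two-class linear discriminant
#'
#' Classic pooled-covariance LDA: weight vector
#' `w = Sigma_pooled^-1 (mu_1 - mu_0)` with bias from the class means and
#' log prior ratio. A singular pooled covariance is ridge-regularized by
#' `1e-8 * trace`. Decision scores are monotone in the posterior
#' probability of the second (alphabetically later) class.
#'
#' @param x feature matrix `n x p`.
#' @param y two-class label vector.
#' @return an object of class `bb_lda` with `w`, `b`, `classes`;
#'   [predict()] returns decision scores.
#' @export
train_lda <- function(x, y) {
  x <- as.matrix(x)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("LDA requires exactly two classes")
  i0 <- y == classes[1]; i1 <- y == classes[2]
  mu0 <- colMeans(x[i0, , drop = FALSE])
  mu1 <- colMeans(x[i1, , drop = FALSE])
  n0 <- sum(i0); n1 <- sum(i1)
  cov_or_zero <- function(z) if (nrow(z) > 1) var(z) * (nrow(z) - 1) else
    matrix(0, ncol(z), ncol(z))
  Sp <- (cov_or_zero(x[i0, , drop = FALSE]) +
           cov_or_zero(x[i1, , drop = FALSE])) / max(n0 + n1 - 2, 1)
  dmu <- mu1 - mu0
  w <- tryCatch(solve(Sp, dmu), error = function(e) {
    solve(Sp + diag(1e-8 * sum(diag(Sp)) + 1e-300, ncol(Sp)), dmu)
  })
  b <- -sum(w * (mu0 + mu1)) / 2 + log(n1 / n0)
  structure(list(w = w, b = b, classes = classes), class = "bb_lda")
}

#' @export
predict.bb_lda <- function(object, newdata, ...) {
  as.numeric(as.matrix(newdata) %*% object$w + object$b)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of decision scores for the positive class
#' (ties share ranks).
#'
#' @param scores numeric decision scores.
#' @param y labels.
#' @param positive label treated as positive; default the alphabetically
#'   later class.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, y, positive = sort(unique(y))[2]) {
  pos <- y == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified k-fold assignment (vector of fold ids), shuffled under the
# current RNG state.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Feature pipelines for decoding
#'
#' A pipeline describes how filtered signal copies are produced before CSP:
#' `pipeline_kernels()` convolves with a fixed (calibration) kernel set;
#' `pipeline_band()` band-filters (single filter or 3 Hz bank);
#' `pipeline_kernels_cv()` re-runs kernel selection inside every
#' cross-validation fold from a precomputed burst set (burst detection is
#' label-free, so bursts may be detected once on all trials), trading a
#' large constant factor for strict separation of the label-dependent
#' kernel-selection step.
#'
#' @param kernels a `bb_kernelset`.
#' @param normalize passed to [convolve_kernels()].
#' @return a `bb_pipeline` object for [crossval_decode()].
#' @export
pipeline_kernels <- function(kernels, normalize = FALSE) {
  structure(list(type = "kernels", kernels = kernels, normalize = normalize),
            class = "bb_pipeline")
}

#' @rdname pipeline_kernels
#' @param band,bank as in [band_filter_copies()].
#' @export
pipeline_band <- function(band = "beta", bank = FALSE) {
  structure(list(type = "band", band = band, bank = bank),
            class = "bb_pipeline")
}

#' @rdname pipeline_kernels
#' @param bursts a `bb_bursts` detected on all trials.
#' @param roles a [channel_roles()].
#' @param fraction trial fraction for the in-fold [sample_bursts()] step.
#' @export
pipeline_kernels_cv <- function(bursts, roles = channel_roles(),
                                fraction = 0.5) {
  structure(list(type = "kernels_cv", bursts = bursts, roles = roles,
                 fraction = fraction),
            class = "bb_pipeline")
}

pipeline_copies <- function(pipeline, e) {
  switch(pipeline$type,
         kernels = convolve_kernels(e, pipeline$kernels,
                                    normalize = pipeline$normalize),
         band = band_filter_copies(e, pipeline$band, pipeline$bank),
         stop("pipeline type '", pipeline$type,
              "' does not produce global copies"))
}

# Covariances per (copy, window, trial): list over copies of
# list over windows of (nc x nc x n_trials) arrays.
window_covariances <- function(copies, windows) {
  lapply(copies, function(cp)
    lapply(seq_len(nrow(windows)), function(wi)
      trial_covariances(crop_epochs(cp, windows$start[wi], windows$end[wi]),
                        normalize = FALSE)))
}

decode_fold_scores <- function(cov_list, labels, folds_by_rep, n_csp) {
  n_win <- length(cov_list[[1]])
  n_trial <- dim(cov_list[[1]][[1]])[3]
  nc <- dim(cov_list[[1]][[1]])[1]
  classes <- sort(unique(labels))
  n_rep <- length(folds_by_rep)
  k <- max(folds_by_rep[[1]])
  scores <- matrix(NA_real_, n_win, n_rep * k)
  for (wi in seq_len(n_win)) {
    # flatten covariances once per (window, copy): columns are trials
    flat <- lapply(cov_list, function(cw) {
      covs <- cw[[wi]]
      raw <- matrix(covs, nrow = nc * nc)
      tr <- colSums(raw[seq(1, nc * nc, by = nc + 1), , drop = FALSE])
      norm <- sweep(raw, 2, ifelse(tr > 0, tr, 1), "/")
      list(raw = raw, norm = norm)
    })
    col <- 0L
    for (rep_folds in folds_by_rep) {
      for (fold in seq_len(k)) {
        col <- col + 1L
        test <- which(rep_folds == fold)
        train <- which(rep_folds != fold)
        ytr <- labels[train]
        feats_tr <- NULL; feats_te <- NULL
        for (cp in flat) {
          S1 <- matrix(rowMeans(cp$norm[, train[ytr == classes[1]],
                                        drop = FALSE]), nc, nc)
          S2 <- matrix(rowMeans(cp$norm[, train[ytr == classes[2]],
                                        drop = FALSE]), nc, nc)
          fit <- csp_from_covs(S1, S2, n_csp)
          # feature_j = log(w_j' C w_j) via the flattened covariances
          Wk <- fit$filters
          proj <- apply(Wk, 1, function(w) as.vector(outer(w, w)))
          fmat <- log(pmax(crossprod(proj, cp$raw), 1e-20))
          feats_tr <- cbind(feats_tr, t(fmat[, train, drop = FALSE]))
          feats_te <- cbind(feats_te, t(fmat[, test, drop = FALSE]))
        }
        lda <- train_lda(feats_tr, ytr)
        scores[wi, col] <- auc_score(predict(lda, feats_te), labels[test])
      }
    }
  }
  scores
}

#' Time-resolved repeated cross-validated decoding
#'
#' For every window the epochs are cropped, the pipeline's filtered copies
#' are spatially filtered with CSP (fitted on training trials only), the
#' concatenated log-power features feed an LDA, and the AUC is computed on
#' the held-out fold. Stratified 5-fold cross-validation is repeated
#' `n_repeats` times with reshuffled folds (seed + repeat), giving
#' `n_repeats * k` scores per window. No stage sees test trials during
#' fitting; with `pipeline_kernels_cv` even kernel selection is refit per
#' fold.
#'
#' @param e a preprocessed [bb_epochs].
#' @param pipeline a `bb_pipeline` (see [pipeline_kernels()]).
#' @param windows a [build_windows()] result.
#' @param n_repeats,k repetition and fold counts (defaults 10 and 5).
#' @param n_csp CSP components per copy (default 4).
#' @param seed integer seed for fold shuffling.
#' @return an object of class `bb_curve`: `windows`, `scores`
#'   (`n_windows x (n_repeats * k)`), `mean`, `sem`.
#' @export
crossval_decode <- function(e, pipeline, windows, n_repeats = 10, k = 5,
                            n_csp = 4, seed = 1L) {
  classes <- sort(unique(e$labels))
  if (length(classes) != 2) stop("two classes required")
  if (min(table(e$labels)) < k)
    stop("each class needs at least k trials")
  win <- windows$windows
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  folds_by_rep <- lapply(seq_len(n_repeats), function(r) {
    set.seed(seed + r)
    stratified_folds(e$labels, k)
  })
  if (pipeline$type == "kernels_cv") {
    scores <- decode_strict_cv(e, pipeline, win, folds_by_rep, n_csp, seed)
  } else {
    copies <- pipeline_copies(pipeline, e)
    cov_list <- window_covariances(copies, win)
    scores <- decode_fold_scores(cov_list, e$labels, folds_by_rep, n_csp)
  }
  structure(list(windows = windows, scores = scores,
                 mean = rowMeans(scores),
                 sem = apply(scores, 1, sd) / sqrt(ncol(scores))),
            class = "bb_curve")
}

# Strict mode: kernel selection re-run per (repeat, fold) on training
# trials only, then the usual covariance/CSP/LDA machinery per window.
decode_strict_cv <- function(e, pipeline, win, folds_by_rep, n_csp, seed) {
  n_win <- nrow(win)
  all_scores <- NULL
  for (ri in seq_along(folds_by_rep)) {
    rep_folds <- folds_by_rep[[ri]]
    k <- max(rep_folds)
    rep_scores <- matrix(NA_real_, n_win, k)
    for (fold in seq_len(k)) {
      train <- which(rep_folds != fold)
      b <- pipeline$bursts
      keep <- b$info$trial %in% train
      btr <- b
      btr$info <- b$info[keep, , drop = FALSE]
      btr$waveforms <- b$waveforms[keep, , drop = FALSE]
      etr_pool <- e
      ks <- select_kernels(btr, etr_pool, pipeline$roles,
                           fraction = pipeline$fraction,
                           seed = seed + 1000L * ri + fold)
      copies <- convolve_kernels(e, ks)
      cov_list <- window_covariances(copies, win)
      one <- decode_fold_scores(cov_list, e$labels, list(rep_folds), n_csp)
      rep_scores[, fold] <- one[, fold]
    }
    all_scores <- cbind(all_scores, rep_scores)
  }
  all_scores
}
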