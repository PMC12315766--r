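# Threshold-stepped cluster enhancement of a statistic profile: for every
# threshold in the ladder, each contiguous supra-threshold run contributes
# its summed exceedance (sum of t - h over the run) to every window it
# covers; a window's enhanced mass is the sum over thresholds.
enhance_profile <- function(t_stat, ladder) {
  out <- numeric(length(t_stat))
  for (h in ladder) {
    above <- t_stat > h
    if (!any(above)) break   # ladder is increasing; nothing above later ones
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      idx <- starts[j]:ends[j]
      out[idx] <- out[idx] + sum(t_stat[idx] - h)
    }
  }
  out
}

paired_t <- function(mean_d, ss_d, n) {
  # variance from the (sign-flip invariant) sum of squares
  v <- pmax((ss_d - n * mean_d^2) / (n - 1), 0)
  ifelse(v > 1e-24 * pmax(ss_d, 1e-300),
         mean_d / sqrt(v / n),
         ifelse(mean_d == 0, 0, sign(mean_d) * Inf))
}

#' Threshold-free cluster-based permutation test of two decoding curves
#'
#' Paired, one-sided comparison of two per-subject score curves
#' (`A - B > 0`). The observed statistic is a paired t per window; cluster
#' enhancement integrates supra-threshold cluster mass over a ladder of
#' thresholds (start 0, step 0.2, up to the observed maximum) instead of a
#' single cutoff. The null distribution is built by random sign flips of
#' the subject difference curves (exhaustive when `2^n_subjects <=
#' n_perm`); per-window p-values use the max-statistic correction across
#' windows, so they are family-wise valid.
#'
#' @param a,b matrices `n_subjects x n_windows` of per-subject mean scores,
#'   paired by row.
#' @param n_perm number of permutations (default `2^13`).
#' @param threshold_start,threshold_step the threshold ladder.
#' @param seed integer RNG seed for the sign flips.
#' @return an object of class `bb_clustertest`: `statistic` (observed t per
#'   window), `enhanced` (observed enhanced mass), `p_values`, `n_perm`,
#'   `ladder`.
#' @export
cluster_permutation_test <- function(a, b, n_perm = 8192,
                                     threshold_start = 0,
                                     threshold_step = 0.2, seed = 1L) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)))
    stop("shape error: curves must be paired (same subjects x windows)")
  n <- nrow(a)
  if (n < 2) stop("need at least 2 subjects")
  d <- a - b
  ss <- colSums(d^2)
  t_obs <- paired_t(colMeans(d), ss, n)
  t_max <- max(c(t_obs, threshold_start + threshold_step))
  ladder <- seq(threshold_start, t_max, by = threshold_step)
  enh_obs <- enhance_profile(t_obs, ladder)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  exhaustive <- 2^n <= n_perm
  if (exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                    nrow = n_perm)
  }
  mean_perm <- (signs %*% d) / n
  max_null <- vapply(seq_len(nrow(signs)), function(pi) {
    tp <- paired_t(mean_perm[pi, ], ss, n)
    max(enhance_profile(tp, ladder))
  }, numeric(1))
  p <- if (exhaustive) {
    vapply(enh_obs, function(e) mean(max_null >= e - 1e-12), numeric(1))
  } else {
    vapply(enh_obs, function(e)
      (1 + sum(max_null >= e - 1e-12)) / (nrow(signs) + 1), numeric(1))
  }
  structure(list(statistic = t_obs, enhanced = enh_obs, p_values = p,
                 n_perm = nrow(signs), ladder = ladder,
                 exhaustive = exhaustive),
            class = "bb_clustertest")
}

#' @export
print.bb_clustertest <- function(x, ...) {
  cat(sprintf("<bb_clustertest> %d windows, %d permutations%s\n",
              length(x$statistic), x$n_perm,
              if (x$exhaustive) " (exhaustive)" else ""))
  sig <- which(x$p_values < 0.05)
  if (length(sig)) cat("  windows with p < 0.05:",
                       paste(sig, collapse = ", "), "\n")
  else cat("  no windows with p < 0.05\n")
  invisible(x)
}
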