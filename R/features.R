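# "same"-aligned linear convolution with zero padding (centered odd kernel).
conv_same <- function(x, k) {
  n <- length(x); m <- length(k)
  L <- 2^ceiling(log2(n + m))
  y <- Re(fft(fft(c(x, rep(0, L - n))) * fft(c(k, rep(0, L - m))),
              inverse = TRUE)) / L
  ctr <- (m - 1L) %/% 2L
  y[(ctr + 1L):(ctr + n)]
}

#' Convolve epochs with a kernel set
#'
#' Every channel of every trial is convolved ("same" alignment, zero
#' padding) with each burst kernel, yielding one temporally filtered copy of
#' the epochs per kernel — a proxy of the waveform-resolved burst rate for
#' that kernel's shape. Kernels are applied as-is; set `normalize = TRUE`
#' to scale each kernel to unit energy first.
#'
#' @param e a [bb_epochs] object.
#' @param kernels a `bb_kernelset` (or a plain matrix, one kernel per row).
#' @param normalize scale kernels to unit energy before convolving.
#' @return named list of [bb_epochs], one per kernel.
#' @export
convolve_kernels <- function(e, kernels, normalize = FALSE) {
  km <- if (inherits(kernels, "bb_kernelset")) kernels$kernels else kernels
  if (ncol(km) >= n_samples(e))
    stop("kernel longer than the epoch (", ncol(km), " >= ", n_samples(e), ")")
  out <- vector("list", nrow(km))
  for (ki in seq_len(nrow(km))) {
    k <- km[ki, ]
    if (normalize) k <- k / sqrt(sum(k^2))
    cp <- e
    for (ti in seq_len(n_trials(e)))
      for (ci in seq_len(n_channels(e)))
        cp$data[ti, ci, ] <- conv_same(e$data[ti, ci, ], k)
    out[[ki]] <- cp
  }
  names(out) <- paste0("kernel", seq_len(nrow(km)))
  out
}

#' Band-filtered copies of the epochs
#'
#' Single-filter mode band-passes the whole band; bank mode splits it into
#' non-overlapping 3 Hz filters: mu (6-15 Hz) into 3, beta (15-30 Hz) into
#' 5, mu-beta (6-30 Hz) into the union of both (8).
#'
#' @param e a [bb_epochs] object.
#' @param band `"mu"`, `"beta"` or `"mu_beta"`.
#' @param bank use the 3 Hz filter bank instead of a single filter.
#' @return named list of band-passed [bb_epochs].
#' @export
band_filter_copies <- function(e, band = c("mu", "beta", "mu_beta"),
                               bank = FALSE) {
  band <- match.arg(band)
  edges <- switch(band, mu = c(6, 15), beta = c(15, 30), mu_beta = c(6, 30))
  bands <- if (!bank) list(edges) else {
    lows <- seq(edges[1], edges[2] - 3, by = 3)
    lapply(lows, function(lo) c(lo, lo + 3))
  }
  out <- lapply(bands, function(b)
    filter_epochs(e, filter_spec(kind = "bandpass", band = b)))
  names(out) <- vapply(bands, function(b) sprintf("%g-%gHz", b[1], b[2]),
                       character(1))
  out
}

# Per-trial channel covariances (n_chan x n_chan x n_trials), optionally
# trace-normalized.
trial_covariances <- function(e, normalize = TRUE) {
  nc <- n_channels(e)
  out <- array(0, dim = c(nc, nc, n_trials(e)))
  for (ti in seq_len(n_trials(e))) {
    X <- matrix(e$data[ti, , ], nrow = nc)
    C <- tcrossprod(X) / ncol(X)
    if (normalize) {
      tr <- sum(diag(C))
      if (tr > 0) C <- C / tr
    }
    out[, , ti] <- C
  }
  out
}

# CSP filters from two class-mean covariance matrices: solve
# S1 w = lambda (S1 + S2) w, keep the n_components/2 largest- and
# smallest-lambda eigenvectors interleaved largest-first.
csp_from_covs <- function(S1, S2, n_components = 4) {
  M <- S1 + S2
  em <- eigen(M, symmetric = TRUE)
  tol <- 1e-10 * max(em$values)
  if (any(em$values <= tol)) {
    warning("rank-deficient covariance; applying ridge regularization")
    eps <- 1e-10 * sum(diag(M))
    M <- M + diag(eps, nrow(M))
    S1 <- S1 + diag(eps / 2, nrow(M))
    em <- eigen(M, symmetric = TRUE)
  }
  W <- em$vectors %*% diag(1 / sqrt(em$values), length(em$values)) %*%
    t(em$vectors)
  B <- W %*% S1 %*% W
  eb <- eigen((B + t(B)) / 2, symmetric = TRUE)
  p <- length(eb$values)
  if (n_components %% 2 != 0) stop("n_components must be even")
  if (n_components > p) stop("n_components exceeds channel count")
  pick <- as.vector(rbind(seq_len(n_components / 2),
                          p + 1 - seq_len(n_components / 2)))
  filters <- t(W %*% eb$vectors[, pick, drop = FALSE])
  list(filters = filters, eigenvalues = eb$values[pick])
}

#' Fit common spatial patterns
#'
#' Per class, per-trial channel covariances (each trace-normalized) are
#' averaged; the generalized eigenproblem `S1 w = lambda (S1 + S2) w` is
#' solved by whitening `S1 + S2`. The `n_components/2` filters with the
#' largest eigenvalues (variance concentrated in the first class) and the
#' `n_components/2` with the smallest (second class) are kept, interleaved
#' largest-first.
#'
#' @param e a [bb_epochs] object with both classes present.
#' @param n_components even number of spatial filters (default 4).
#' @return an object of class `bb_csp`: `filters`
#'   (`n_components x n_channels`), `eigenvalues`, `class_order`.
#' @export
fit_csp <- function(e, n_components = 4) {
  classes <- sort(unique(e$labels))
  if (length(classes) != 2) stop("CSP requires exactly two classes")
  covs <- trial_covariances(e, normalize = TRUE)
  S <- lapply(classes, function(cl)
    apply(covs[, , e$labels == cl, drop = FALSE], c(1, 2), mean))
  fit <- csp_from_covs(S[[1]], S[[2]], n_components)
  structure(list(filters = fit$filters, eigenvalues = fit$eigenvalues,
                 class_order = classes, S1 = S[[1]], S2 = S[[2]]),
            class = "bb_csp")
}

#' CSP log-power features
#'
#' Per trial and spatial filter: the log of the average power of the
#' spatially filtered signal over the epoch window. Zero-variance
#' projections are floored at `log(1e-20)` with a warning.
#'
#' @param model a [fit_csp()] result.
#' @param e a [bb_epochs] with the same channel count.
#' @return matrix `n_trials x n_components`.
#' @export
csp_features <- function(model, e) {
  if (ncol(model$filters) != n_channels(e))
    stop("shape error: channel count does not match the CSP model")
  nt <- n_trials(e)
  out <- matrix(0, nt, nrow(model$filters))
  floored <- FALSE
  for (ti in seq_len(nt)) {
    X <- matrix(e$data[ti, , ], nrow = n_channels(e))
    P <- rowMeans((model$filters %*% X)^2)
    if (any(P <= 0)) { floored <- TRUE; P <- pmax(P, 1e-20) }
    out[ti, ] <- log(P)
  }
  if (floored) warning("zero-variance projection floored at log(1e-20)")
  out
}

#' Concatenate per-copy CSP features into one feature matrix
#'
#' @param copies list of filtered [bb_epochs] (one per kernel or band).
#' @param models list of matching [fit_csp()] models.
#' @return an object of class `bb_features`: `values`
#'   (`n_trials x n_features`), `feature_names`, `labels`.
#' @export
assemble_features <- function(copies, models) {
  if (length(copies) != length(models))
    stop("one CSP model per filtered copy required")
  nt <- vapply(copies, n_trials, integer(1))
  if (length(unique(nt)) != 1) stop("shape error: trial counts differ")
  blocks <- Map(function(cp, md) csp_features(md, cp), copies, models)
  values <- do.call(cbind, blocks)
  cn <- names(copies) %||% paste0("copy", seq_along(copies))
  feature_names <- unlist(Map(function(name, md)
    paste0(name, "_csp", seq_len(nrow(md$filters))), cn, models))
  structure(list(values = values, feature_names = feature_names,
                 labels = copies[[1]]$labels),
            class = "bb_features")
}
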