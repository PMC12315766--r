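#' Sample whole trials of bursts for kernel fitting
#'
#' Selects `ceil(fraction * n_trials)` trials uniformly without replacement
#' (both classes pooled) and returns every burst detected in them. Sampling
#' whole trials rather than individual bursts keeps within-trial burst
#' correlations intact.
#'
#' @param bursts a `bb_bursts` from [detect_all()].
#' @param e the [bb_epochs] the bursts came from (defines the trial pool).
#' @param fraction fraction of trials to sample, in (0, 1].
#' @param seed integer RNG seed.
#' @return a `bb_bursts` restricted to the sampled trials.
#' @export
sample_bursts <- function(bursts, e, fraction = 0.10, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  nt <- n_trials(e)
  n_take <- ceiling(fraction * nt)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  trials <- sort(sample.int(nt, n_take))
  keep <- bursts$info$trial %in% trials
  if (!any(keep))
    stop("empty sample: no bursts in the ", n_take, " sampled trials")
  out <- bursts
  out$info <- bursts$info[keep, , drop = FALSE]
  out$waveforms <- bursts$waveforms[keep, , drop = FALSE]
  rownames(out$info) <- NULL
  attr(out, "sampled_trials") <- trials
  out
}

#' Fit the burst waveform-shape space
#'
#' Robust-scales each time sample of the waveform matrix
#' (`(x - median) / IQR`, IQR floored at 1e-12) and extracts principal axes
#' of the scaled matrix. The space origin corresponds to the average
#' waveform (score 0 on every axis). Components use a deterministic sign
#' convention: the largest-magnitude coefficient of each axis is positive.
#'
#' @param waveforms matrix `n_bursts x n_samples` of raw waveforms.
#' @param n_axes_min minimum number of axes kept; the default keeps
#'   `max(9, axes needed for 90% explained variance)` (capped by rank).
#' @return an object of class `bb_wavespace` with fields `center`, `scale`,
#'   `mean_waveform`, `mean_scaled`, `components` (orthonormal rows),
#'   `explained_variance`, `n_axes`.
#' @export
fit_waveform_space <- function(waveforms, n_axes_min = 9) {
  if (!is.matrix(waveforms) || nrow(waveforms) < 2)
    stop("need at least 2 waveforms")
  ctr <- apply(waveforms, 2, median)
  iqr <- pmax(apply(waveforms, 2, function(x)
    diff(quantile(x, c(0.25, 0.75), names = FALSE))), 1e-12)
  z <- sweep(sweep(waveforms, 2, ctr), 2, iqr, "/")
  pc <- prcomp(z, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  cum <- if (sum(ev) > 0) cumsum(ev) / sum(ev) else rep(1, length(ev))
  n_axes <- min(max(n_axes_min, which(cum >= 0.9)[1]), ncol(pc$rotation))
  comps <- t(pc$rotation[, seq_len(n_axes), drop = FALSE])
  for (i in seq_len(nrow(comps))) {
    j <- which.max(abs(comps[i, ]))
    if (comps[i, j] < 0) comps[i, ] <- -comps[i, ]
  }
  structure(list(center = ctr, scale = iqr,
                 mean_waveform = colMeans(waveforms),
                 mean_scaled = colMeans(z),
                 components = comps,
                 explained_variance = ev[seq_len(n_axes)],
                 n_axes = n_axes),
            class = "bb_wavespace")
}

#' Project waveforms into a fitted shape space
#'
#' @param space a [fit_waveform_space()] result.
#' @param waveforms matrix `n_bursts x n_samples` (same length as the
#'   fitting set).
#' @return score matrix `n_bursts x n_axes`.
#' @export
score_waveforms <- function(space, waveforms) {
  if (is.vector(waveforms)) waveforms <- matrix(waveforms, nrow = 1)
  if (ncol(waveforms) != length(space$center))
    stop("shape error: waveform length does not match the space")
  z <- sweep(sweep(waveforms, 2, space$center), 2, space$scale, "/")
  zc <- sweep(z, 2, space$mean_scaled)
  zc %*% t(space$components)
}

# The four (channel, laterality) cells of the lateralized modulation index.
modulation_cells <- function(info, roles) {
  list(
    ipsi_C3   = info$channel == roles$left_motor  & info$class == "left_hand",
    contra_C4 = info$channel == roles$right_motor & info$class == "left_hand",
    ipsi_C4   = info$channel == roles$right_motor & info$class == "right_hand",
    contra_C3 = info$channel == roles$left_motor  & info$class == "right_hand")
}

#' Lateralized modulation index of one waveform axis
#'
#' For each of the four (motor channel, laterality) cells — C3 ipsilateral
#' (left-hand trials), C4 contralateral (left-hand), C4 ipsilateral
#' (right-hand), C3 contralateral (right-hand) — compute
#' `u = |mean axis score over task-period bursts - mean over baseline
#' bursts|`, then
#' `I_m = |(u_ipsi^C3 - u_contra^C4) - (u_ipsi^C4 - u_contra^C3)|`.
#' Large values flag axes along which the average burst shape shifts between
#' baseline and task in a hemisphere-by-class (lateralized) pattern.
#'
#' @param scores score matrix aligned with `bursts` rows.
#' @param bursts a `bb_bursts` restricted (or restrictable) to the motor
#'   channels.
#' @param roles a [channel_roles()].
#' @param m axis index (column of `scores`).
#' @return `list(I, u)` with `u` the named four cell values.
#' @export
modulation_index <- function(scores, bursts, roles, m) {
  info <- bursts$info
  s <- scores[, m]
  cells <- modulation_cells(info, roles)
  u <- vapply(names(cells), function(cn) {
    sel <- cells[[cn]]
    task <- sel & info$period == "task"
    base <- sel & info$period == "baseline"
    if (!any(task) || !any(base))
      stop("insufficient bursts: cell '", cn,
           "' lacks ", if (!any(task)) "task" else "baseline", "-period bursts")
    abs(mean(s[task]) - mean(s[base]))
  }, numeric(1))
  list(I = abs((u[["ipsi_C3"]] - u[["contra_C4"]]) -
                 (u[["ipsi_C4"]] - u[["contra_C3"]])),
       u = u)
}

#' Modulation profile over candidate axes
#'
#' @inheritParams modulation_index
#' @param axes candidate axes (default components 2 to 9; component 1 is
#'   excluded throughout because it predominantly encodes temporal skew).
#' @return an object of class `bb_modprofile`: `I` (named by axis),
#'   `u_terms` (4 x n_axes matrix), `axes`.
#' @export
modulation_profile <- function(scores, bursts, roles, axes = 2:9) {
  axes <- axes[axes <= ncol(scores)]
  res <- lapply(axes, function(m) modulation_index(scores, bursts, roles, m))
  I <- vapply(res, `[[`, numeric(1), "I")
  names(I) <- axes
  u <- vapply(res, `[[`, numeric(4), "u")
  colnames(u) <- axes
  structure(list(I = I, u_terms = u, axes = axes), class = "bb_modprofile")
}

#' Select the three most lateralized waveform axes
#'
#' Picks the three axes with the largest modulation index among components
#' 2-9 (component 1 is never eligible); ties break toward the lower axis
#' index. The result is sorted by descending index value.
#'
#' @param profile a [modulation_profile()].
#' @return integer vector of 3 axis indices.
#' @export
select_axes <- function(profile) {
  axes <- profile$axes
  I <- profile$I
  ok <- is.finite(I) & axes >= 2
  if (sum(ok) < 3) stop("fewer than 3 finite modulation values among axes 2..9")
  axes <- axes[ok]; I <- I[ok]
  ord <- order(-I, axes)
  axes[ord[1:3]]
}

#' Derive convolution kernels from the extreme waveform groups
#'
#' For each selected axis the score range `[min, max]` is split into seven
#' equal-width groups; the two outermost groups (furthest from the origin)
#' each yield one kernel: the element-wise average of the raw (unscaled)
#' waveforms in the group. Three axes give exactly six kernels.
#'
#' @param scores score matrix of the kernel-fitting burst set.
#' @param waveforms matching raw waveform matrix.
#' @param axes 3 axis indices from [select_axes()].
#' @return an object of class `bb_kernelset`: `kernels`
#'   (`6 x waveform_length` matrix) and `provenance` (axis, extreme, n).
#' @export
derive_kernels <- function(scores, waveforms, axes) {
  stopifnot(length(axes) == 3)
  kernels <- list(); prov <- list()
  for (m in axes) {
    s <- scores[, m]
    rng <- range(s)
    if (diff(rng) <= 0)
      stop("empty extreme bin on axis ", m,
           ": degenerate score range; provide more input bursts")
    edges <- seq(rng[1], rng[2], length.out = 8)
    for (extreme in c("low", "high")) {
      sel <- if (extreme == "low") s <= edges[2] else s >= edges[7]
      if (!any(sel))
        stop("empty extreme bin on axis ", m, "; provide more input bursts")
      kernels[[length(kernels) + 1L]] <-
        colMeans(waveforms[sel, , drop = FALSE])
      prov[[length(prov) + 1L]] <- data.frame(
        axis = m, extreme = extreme, n_bursts = sum(sel),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(kernels = do.call(rbind, kernels),
                 provenance = do.call(rbind, prov)),
            class = "bb_kernelset")
}

#' @export
print.bb_kernelset <- function(x, ...) {
  cat(sprintf("<bb_kernelset> %d kernels of length %d\n",
              nrow(x$kernels), ncol(x$kernels)))
  print(x$provenance)
  invisible(x)
}

#' End-to-end kernel selection
#'
#' Convenience chain: sample whole trials of bursts, fit the waveform shape
#' space, score the sampled bursts, profile the lateralized modulation of
#' axes 2-9, select the top three axes, and average the extreme waveform
#' groups into six kernels. All stages use the sampled burst set.
#'
#' @param bursts a `bb_bursts` from [detect_all()].
#' @param e the source [bb_epochs].
#' @param roles a [channel_roles()].
#' @param fraction trial fraction for [sample_bursts()].
#' @param seed RNG seed for the trial sample.
#' @return a `bb_kernelset` with the fitted `space`, score matrix, and
#'   modulation `profile` attached as fields.
#' @export
select_kernels <- function(bursts, e, roles = channel_roles(),
                           fraction = 0.10, seed = 1L) {
  sampled <- sample_bursts(bursts, e, fraction, seed)
  space <- fit_waveform_space(sampled$waveforms)
  scores <- score_waveforms(space, sampled$waveforms)
  motor <- sampled$info$channel %in% c(roles$left_motor, roles$right_motor)
  motor_bursts <- sampled
  motor_bursts$info <- sampled$info[motor, , drop = FALSE]
  profile <- modulation_profile(scores[motor, , drop = FALSE], motor_bursts,
                                roles)
  axes <- select_axes(profile)
  ks <- derive_kernels(scores, sampled$waveforms, axes)
  ks$space <- space
  ks$profile <- profile
  ks$axes <- axes
  ks
}
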