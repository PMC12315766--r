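#' Full width at half maximum of a peak in a 1-d profile
#'
#' Walks outward from `peak_index` to the first crossings of half the peak
#' value, linearly interpolated between samples. A side that never crosses
#' before the vector boundary reports the distance to the boundary and is
#' flagged as truncated.
#'
#' @param profile nonnegative numeric vector.
#' @param peak_index index of a local maximum with positive value.
#' @return `list(left, right, left_truncated, right_truncated)`; widths in
#'   (fractional) samples.
#' @export
fwhm_1d <- function(profile, peak_index) {
  pk <- profile[peak_index]
  if (!is.finite(pk) || pk <= 0) stop("peak value must be > 0")
  half <- pk / 2
  walk <- function(idx_seq) {
    prev <- pk
    for (j in seq_along(idx_seq)) {
      cur <- profile[idx_seq[j]]
      if (cur <= half) {
        frac <- if (prev == cur) 0 else (prev - half) / (prev - cur)
        return(list(width = (j - 1) + frac, truncated = FALSE))
      }
      prev <- cur
    }
    list(width = length(idx_seq), truncated = TRUE)
  }
  left <- walk(rev(seq_len(peak_index - 1L)))
  right <- walk(seq.int(peak_index + 1L, length.out = length(profile) - peak_index))
  list(left = left$width, right = right$width,
       left_truncated = left$truncated, right_truncated = right$truncated)
}

#' Extract a trough-centered burst waveform
#'
#' Locates the deepest local minimum of the (low-passed) signal within
#' 30 ms of `peak_time` and returns the window of half-width 130 ms (odd
#' length `round(0.260 * fs)` rounded to odd) centered on that trough.
#' Returns `NULL` — absence, not an error — when no local minimum exists in
#' the search window or when the waveform window would clip the epoch edge.
#'
#' @param raw signal vector covering `peak_time`.
#' @param fs sampling rate, Hz.
#' @param peak_time time of the TF amplitude peak, s.
#' @param t0 time of `raw[1]`, s.
#' @return `NULL`, or `list(waveform, trough_index, trough_time)`.
#' @export
extract_waveform <- function(raw, fs, peak_time, t0 = 0) {
  n <- length(raw)
  ctr <- round((peak_time - t0) * fs) + 1L
  if (ctr < 1L || ctr > n) stop("peak_time outside the signal span")
  search <- round(0.030 * fs)
  lo <- max(2L, ctr - search)
  hi <- min(n - 1L, ctr + search)
  if (lo > hi) return(NULL)
  cand <- lo:hi
  is_min <- raw[cand] < raw[cand - 1L] & raw[cand] < raw[cand + 1L]
  if (!any(is_min)) return(NULL)
  cand <- cand[is_min]
  trough <- cand[which.min(raw[cand])]
  half <- (odd_window_length(0.260, fs) - 1L) / 2L
  if (trough - half < 1L || trough + half > n) return(NULL)
  list(waveform = raw[(trough - half):(trough + half)],
       trough_index = trough,
       trough_time = t0 + (trough - 1L) / fs)
}

empty_bursts <- function(wlen) {
  structure(list(
    info = data.frame(trial = integer(0), channel = character(0),
                      peak_time = numeric(0), peak_freq = numeric(0),
                      peak_amp = numeric(0), fwhm_time = numeric(0),
                      fwhm_freq = numeric(0), trough_time = numeric(0),
                      period = character(0), class = character(0),
                      stringsAsFactors = FALSE),
    waveforms = matrix(numeric(0), nrow = 0, ncol = wlen)),
    class = "bb_bursts")
}

bind_bursts <- function(lst) {
  lst <- Filter(function(b) nrow(b$info) > 0, lst)
  if (!length(lst)) return(NULL)
  structure(list(info = do.call(rbind, lapply(lst, `[[`, "info")),
                 waveforms = do.call(rbind, lapply(lst, `[[`, "waveforms"))),
            class = "bb_bursts")
}

#' @export
print.bb_bursts <- function(x, ...) {
  cat(sprintf("<bb_bursts> %d bursts, waveform length %d\n",
              nrow(x$info), ncol(x$waveforms)))
  if (nrow(x$info) > 0)
    print(table(x$info$period, x$info$class))
  invisible(x)
}

#' Iterative burst detection on one TF matrix
#'
#' Repeatedly removes the largest peak of the TF amplitude residual: the
#' peak's time/frequency FWHM is measured on the current residual, a
#' separable 2D Gaussian with matching amplitude, center and per-axis
#' `sigma = FWHM / (2 sqrt(2 ln 2))` is subtracted, and the residual is
#' clipped at zero. Detection stops when no residual value exceeds the
#' noise floor — twice the standard deviation of the initial TF amplitudes,
#' fixed across iterations. Peaks inside the beta `band` whose waveform
#' extraction succeeds are emitted as bursts (sorted by peak time); peaks
#' in the TF edge zone or outside the band are subtracted without emission.
#'
#' @param tf a [superlet_tf()] result.
#' @param raw the low-passed signal on the same time grid (waveform source).
#' @param fs sampling rate, Hz.
#' @param band frequency band for emitted bursts, Hz (default beta, 15-30).
#' @param diagnostics attach a `diagnostics` attribute (iteration count,
#'   minimum residual value, floor) to the result.
#' @return a `bb_bursts` object (trial/channel/class fields unset).
#' @export
detect_bursts <- function(tf, raw, fs, band = c(15, 30),
                          diagnostics = FALSE) {
  if (length(raw) != length(tf$times))
    stop("shape error: raw signal and TF matrix time grids differ")
  amp <- tf$amp
  nf <- nrow(amp); nt <- ncol(amp)
  floor_amp <- 2 * sd(amp)
  residual <- amp
  df <- tf$freqs[2] - tf$freqs[1]
  t0 <- tf$times[1]
  wlen <- odd_window_length(0.260, fs)
  out <- list()
  max_iter <- nf * nt
  for (iter in seq_len(max_iter)) {
    idx <- which.max(residual)
    pk <- residual[idx]
    if (pk <= floor_amp) break
    ij <- arrayInd(idx, dim(residual))
    fi <- ij[1]; ti <- ij[2]
    wt <- fwhm_1d(residual[fi, ], ti)
    wf <- fwhm_1d(residual[, ti], fi)
    # per-side sigmas: a half-width of w samples corresponds to
    # sigma = w / sqrt(2 ln 2), so skewed blobs are modeled per side
    s2 <- sqrt(2 * log(2))
    sig_tl <- max(wt$left, 0.5) / s2;  sig_tr <- max(wt$right, 0.5) / s2
    sig_fl <- max(wf$left, 0.5) / s2;  sig_fr <- max(wf$right, 0.5) / s2
    sig_t <- (sig_tl + sig_tr) / 2; sig_f <- (sig_fl + sig_fr) / 2
    tspan <- max(1L, ti - ceiling(4 * sig_tl)):min(nt, ti + ceiling(4 * sig_tr))
    fspan <- max(1L, fi - ceiling(4 * sig_fl)):min(nf, fi + ceiling(4 * sig_fr))
    gt <- ifelse(tspan < ti, exp(-(tspan - ti)^2 / (2 * sig_tl^2)),
                 exp(-(tspan - ti)^2 / (2 * sig_tr^2)))
    gf <- ifelse(fspan < fi, exp(-(fspan - fi)^2 / (2 * sig_fl^2)),
                 exp(-(fspan - fi)^2 / (2 * sig_fr^2)))
    g <- pk * gf %o% gt
    residual[fspan, tspan] <- pmax(residual[fspan, tspan] - g, 0)
    in_band <- tf$freqs[fi] >= band[1] && tf$freqs[fi] <= band[2]
    margin <- tf$valid_margin[fi]
    in_valid <- ti > margin && ti <= nt - margin
    if (in_band && in_valid) {
      w <- extract_waveform(raw, fs, tf$times[ti], t0 = t0)
      if (!is.null(w)) {
        out[[length(out) + 1L]] <- list(
          info = data.frame(trial = NA_integer_, channel = NA_character_,
                            peak_time = tf$times[ti], peak_freq = tf$freqs[fi],
                            peak_amp = pk,
                            fwhm_time = (wt$left + wt$right) / fs,
                            fwhm_freq = (wf$left + wf$right) * df,
                            trough_time = w$trough_time,
                            period = NA_character_, class = NA_character_,
                            stringsAsFactors = FALSE),
          waveforms = matrix(w$waveform, nrow = 1))
      }
    }
  }
  res <- bind_bursts(out)
  if (is.null(res)) res <- empty_bursts(wlen)
  else {
    ord <- order(res$info$peak_time)
    res$info <- res$info[ord, , drop = FALSE]
    res$waveforms <- res$waveforms[ord, , drop = FALSE]
    rownames(res$info) <- NULL
  }
  if (diagnostics)
    attr(res, "diagnostics") <- list(iterations = iter, max_iter = max_iter,
                                     min_residual = min(residual),
                                     floor = floor_amp)
  res
}

#' Detect bursts across all trials of the burst-detection channel cluster
#'
#' Runs the superlet transform and [detect_bursts()] for every
#' (trial, cluster channel) pair, annotating each burst with its trial,
#' channel, class label and epoch period (baseline / task / post).
#'
#' @param e a (low-passed) [bb_epochs] object.
#' @param roles a [channel_roles()]; detection runs on `roles$burst_cluster`.
#' @param cfg a [superlet_config()].
#' @param band beta band bounds, Hz.
#' @return a `bb_bursts` object.
#' @export
detect_all <- function(e, roles = channel_roles(), cfg = superlet_config(),
                       band = c(15, 30)) {
  check_roles(roles, e)
  fs <- e$fs
  times <- epoch_times(e)
  freqs <- superlet_freqs(cfg)
  margin <- superlet_valid_margin(cfg, fs)
  wlen <- odd_window_length(0.260, fs)
  out <- list()
  for (ch in roles$burst_cluster) {
    ci <- chan_index(e, ch)
    if (n_trials(e) == 0) next
    sig <- matrix(e$data[, ci, ], nrow = n_trials(e))
    tfs <- superlet_tf_batch(sig, fs, cfg)
    for (ti in seq_len(n_trials(e))) {
      tf <- new_tf(tfs[, , ti], freqs, times, margin, channel = ch,
                   trial = ti)
      b <- detect_bursts(tf, sig[ti, ], fs, band)
      if (nrow(b$info) > 0) {
        b$info$trial <- ti
        b$info$channel <- ch
        b$info$class <- e$labels[ti]
        b$info$period <- time_period(b$info$peak_time, e$timing)
        out[[length(out) + 1L]] <- b
      }
    }
  }
  res <- bind_bursts(out)
  if (is.null(res)) return(empty_bursts(wlen))
  ord <- order(res$info$trial, res$info$peak_time)
  res$info <- res$info[ord, , drop = FALSE]
  res$waveforms <- res$waveforms[ord, , drop = FALSE]
  rownames(res$info) <- NULL
  res
}
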