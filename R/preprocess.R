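#' FIR filter specification
#'
#' @param cutoff low-pass cutoff in Hz (used when `kind = "lowpass"`).
#' @param transition_fraction transition bandwidth as a fraction of the
#'   relevant band edge (default 0.25, i.e. 25% of the low-pass frequency).
#' @param kind `"lowpass"` or `"bandpass"`.
#' @param band `c(low, high)` in Hz for bandpass.
#' @return an object of class `bb_filterspec`.
#' @export
filter_spec <- function(cutoff = 120, transition_fraction = 0.25,
                        kind = c("lowpass", "bandpass"), band = NULL) {
  kind <- match.arg(kind)
  if (transition_fraction <= 0 || transition_fraction > 1)
    stop("transition_fraction must be in (0, 1]")
  if (kind == "bandpass") {
    if (is.null(band) || length(band) != 2 || band[1] >= band[2])
      stop("bandpass requires band = c(low, high) with low < high")
  }
  structure(list(cutoff = cutoff, transition_fraction = transition_fraction,
                 kind = kind, band = band), class = "bb_filterspec")
}

#' Design a windowed linear-phase FIR filter
#'
#' Hamming-windowed design (via `signal::fir1`) with the filter order chosen
#' from the transition bandwidth (a fraction of the band edge), mirroring
#' the usual windowed-design rule of thumb (transition width ~ 3.3 / N
#' normalized). The returned coefficient vector has odd length and is
#' symmetric (linear phase); the -6 dB point of a lowpass sits at the
#' nominal cutoff.
#'
#' @param spec a [filter_spec()].
#' @param fs sampling rate, Hz.
#' @return numeric coefficient vector.
#' @export
design_fir <- function(spec, fs) {
  nyq <- fs / 2
  if (spec$kind == "lowpass") {
    if (spec$cutoff <= 0 || spec$cutoff >= nyq)
      stop("cutoff must satisfy 0 < cutoff < fs/2 (fs = ", fs,
           "); lower the cutoff below Nyquist")
    tw <- spec$transition_fraction * spec$cutoff
    order <- ceiling(3.3 * fs / tw)
    if (order %% 2 == 1) order <- order + 1   # even order -> odd length
    b <- signal::fir1(order, spec$cutoff / nyq, type = "low")
    b <- b / sum(b)                 # exact unit DC gain
  } else {
    band <- spec$band
    if (band[1] <= 0 || band[2] >= nyq)
      stop("band must lie strictly inside (0, fs/2)")
    tw <- spec$transition_fraction * band[1]
    order <- ceiling(3.3 * fs / tw)
    if (order %% 2 == 1) order <- order + 1
    b <- signal::fir1(order, band / nyq, type = "pass")
  }
  as.numeric(b)
}

# Zero-phase FIR filtering of one signal with mirror-reflection padding.
filtfilt_reflect <- function(x, b) {
  n <- length(x)
  pad <- min(3L * (length(b) - 1L), n - 1L)
  xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  fwd <- as.numeric(signal::filter(b, 1, xp))
  bwd <- rev(as.numeric(signal::filter(b, 1, rev(fwd))))
  bwd[(pad + 1L):(pad + n)]
}

#' Zero-phase filter all epochs
#'
#' Applies the FIR filter forward and backward (zero net phase, magnitude
#' response squared) to every trial and channel; epoch edges are handled by
#' mirror-reflection padding of length three times the filter order.
#'
#' @param e a [bb_epochs] object.
#' @param spec a [filter_spec()].
#' @return a filtered [bb_epochs] of the same shape.
#' @export
filter_epochs <- function(e, spec) {
  b <- design_fir(spec, e$fs)
  out <- e
  for (ti in seq_len(n_trials(e)))
    for (ci in seq_len(n_channels(e)))
      out$data[ti, ci, ] <- filtfilt_reflect(e$data[ti, ci, ], b)
  out
}

#' Remove a narrow-band interference tone
#'
#' Spectral-interpolation notch: per trial and channel the amplitude
#' spectrum inside `[f0 - width/2, f0 + width/2]` is replaced by a linear
#' interpolation of the median amplitude in the flanking bands of the same
#' width, preserving the original phases. Power outside the band is
#' untouched. This targets the same contract as DSS-based line-noise
#' removers (suppress a narrow, high-power artifact, leave the broadband
#' signal alone) with a far simpler mechanism.
#'
#' @param e a [bb_epochs] object.
#' @param f0 center frequency of the artifact, Hz.
#' @param width full width of the notch band, Hz.
#' @return a cleaned [bb_epochs].
#' @export
remove_line_noise <- function(e, f0, width = 2) {
  nyq <- e$fs / 2
  if (f0 - width / 2 <= 0 || f0 + width / 2 >= nyq)
    stop("notch band must lie strictly inside (0, fs/2)")
  ns <- n_samples(e)
  freqs <- (0:(ns - 1)) * e$fs / ns
  half <- floor(ns / 2)
  pos <- 2:(half + 1)                      # positive-frequency bins
  fpos <- freqs[pos]
  in_band <- fpos >= f0 - width / 2 & fpos <= f0 + width / 2
  lo_flank <- fpos >= f0 - 1.5 * width & fpos < f0 - width / 2
  hi_flank <- fpos > f0 + width / 2 & fpos <= f0 + 1.5 * width
  if (!any(in_band)) return(e)
  out <- e
  band_idx <- which(in_band)
  w_interp <- (fpos[band_idx] - (f0 - width)) / (2 * width)
  for (ti in seq_len(n_trials(e)))
    for (ci in seq_len(n_channels(e))) {
      X <- fft(e$data[ti, ci, ])
      amp <- Mod(X[pos])
      a_lo <- if (any(lo_flank)) median(amp[lo_flank]) else median(amp)
      a_hi <- if (any(hi_flank)) median(amp[hi_flank]) else median(amp)
      target <- a_lo * (1 - w_interp) + a_hi * w_interp
      scale <- ifelse(amp[band_idx] > 0, target / amp[band_idx], 1)
      gi <- pos[band_idx]
      X[gi] <- X[gi] * scale
      X[ns - gi + 2L] <- Conj(X[gi])       # keep Hermitian symmetry
      out$data[ti, ci, ] <- Re(fft(X, inverse = TRUE)) / ns
    }
  out
}

#' Reject high-amplitude trials
#'
#' Drops trials whose maximum peak-to-peak amplitude over channels exceeds a
#' threshold. With `ptp_threshold = "auto"` the threshold is
#' `Q3 + 3 * IQR` of the per-trial maxima — a robust outlier rule standing
#' in for cross-validated rejection-threshold searches. Surviving trials
#' keep their order and labels.
#'
#' @param e a [bb_epochs] object.
#' @param ptp_threshold microvolts, or `"auto"`.
#' @return `list(epochs = bb_epochs, kept = logical mask of length n_trials,`
#'   `threshold = value used)`.
#' @export
reject_trials <- function(e, ptp_threshold = "auto") {
  if (n_trials(e) < 1) stop("need at least one trial")
  ptp <- vapply(seq_len(n_trials(e)), function(ti) {
    max(apply(e$data[ti, , , drop = FALSE], 2,
              function(x) diff(range(x))))
  }, numeric(1))
  thr <- if (identical(ptp_threshold, "auto")) {
    q <- quantile(ptp, c(0.25, 0.75), names = FALSE)
    q[2] + 3 * (q[2] - q[1])
  } else as.numeric(ptp_threshold)
  kept <- ptp <= thr
  if (!any(kept))
    stop("empty result: all trials exceed the rejection threshold")
  out <- e
  out$data <- e$data[kept, , , drop = FALSE]
  out$labels <- e$labels[kept]
  list(epochs = out, kept = kept, threshold = thr)
}
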