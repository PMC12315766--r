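#' Superlet transform configuration
#'
#' The superlet estimator computes, at each frequency `f`, the geometric
#' mean of complex Morlet wavelet amplitudes with cycle counts
#' `k * c, k = 1..o(f)`, where the order grows linearly across the band:
#' `o(f) = o_min + round((o_max - o_min) * (f - f_min) / (f_max - f_min))`.
#' Defaults follow the standard motor-imagery setting: 1-43 Hz at 0.5 Hz
#' resolution, orders 1 to 40, base cycle count 4.
#'
#' @param f_min,f_max,f_step frequency grid, Hz.
#' @param o_min,o_max integer superlet order range.
#' @param c base cycle count (> 0).
#' @return an object of class `bb_superletconfig`.
#' @export
superlet_config <- function(f_min = 1, f_max = 43, f_step = 0.5,
                            o_min = 1, o_max = 40, c = 4) {
  if (f_min >= f_max) stop("f_min must be < f_max")
  if (o_min > o_max) stop("o_min must be <= o_max")
  if (c <= 0 || f_step <= 0) stop("c and f_step must be > 0")
  structure(list(f_min = f_min, f_max = f_max, f_step = f_step,
                 o_min = as.integer(o_min), o_max = as.integer(o_max), c = c),
            class = "bb_superletconfig")
}

superlet_freqs <- function(cfg) seq(cfg$f_min, cfg$f_max, by = cfg$f_step)

superlet_orders <- function(cfg) {
  f <- superlet_freqs(cfg)
  as.integer(cfg$o_min + round((cfg$o_max - cfg$o_min) *
                                 (f - cfg$f_min) / (cfg$f_max - cfg$f_min)))
}

# Longest wavelet half-support (samples) in the bank; also the minimum
# signal length the transform accepts.
superlet_max_half <- function(cfg, fs) {
  f <- superlet_freqs(cfg)
  o <- superlet_orders(cfg)
  max(ceiling(3 * (o * cfg$c / (2 * pi * f)) * fs))
}

# Per-frequency edge margin (samples) of the TF "valid region": half a
# standard deviation of the longest wavelet at that frequency. Peaks whose
# time center falls inside the margin are treated as edge artifacts.
superlet_valid_margin <- function(cfg, fs) {
  f <- superlet_freqs(cfg)
  o <- superlet_orders(cfg)
  as.integer(round(0.5 * (o * cfg$c / (2 * pi * f)) * fs))
}

#' Morlet wavelet amplitude envelope
#'
#' Amplitude of the complex Morlet convolution of a signal at one frequency
#' (Gaussian sd `n_cycles / (2 pi f)`, support +/- 3 sd, unit-energy
#' normalization, zero padding at the edges). This plain-R single-wavelet
#' transform is the building block the superlet generalizes, and serves as
#' its reference implementation at order 1.
#'
#' @param signal numeric vector.
#' @param f analysis frequency, Hz (< fs/2).
#' @param n_cycles cycle count (>= 1).
#' @param fs sampling rate, Hz.
#' @return nonnegative envelope, same length as `signal`.
#' @export
morlet_response <- function(signal, f, n_cycles, fs) {
  if (f >= fs / 2) stop("f must be below Nyquist (fs/2)")
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  n <- length(signal)
  sigma <- n_cycles / (2 * pi * f)
  half <- ceiling(3 * sigma * fs)
  t <- (-half:half) / fs
  psi <- exp(-t^2 / (2 * sigma^2)) * exp(2i * pi * f * t)
  psi <- psi / sqrt(sum(Mod(psi)^2))
  L <- 2^ceiling(log2(n + 2 * half + 1))
  xs <- complex(real = c(signal, rep(0, L - n)))
  pw <- complex(length.out = L)
  pw[1:(half + 1)] <- psi[(half + 1):(2 * half + 1)]
  pw[(L - half + 1):L] <- psi[1:half]
  conv <- fft(fft(xs) * fft(pw), inverse = TRUE) / L
  Mod(conv[1:n])
}

#' Superlet time-frequency decomposition of one signal
#'
#' @param signal numeric vector; must be at least as long as the longest
#'   wavelet support of the configuration.
#' @param fs sampling rate, Hz.
#' @param cfg a [superlet_config()].
#' @param t0 time of the first sample, s (for the `times` axis).
#' @return an object of class `bb_tf` with fields `freqs` (Hz), `times` (s),
#'   `amp` (`n_freqs x n_samples`, nonnegative), and `valid_margin`
#'   (per-frequency edge-zone width in samples).
#' @export
superlet_tf <- function(signal, fs, cfg = superlet_config(), t0 = 0) {
  min_len <- superlet_max_half(cfg, fs)
  if (length(signal) < min_len)
    stop("signal too short for the superlet bank: need at least ",
         min_len, " samples at fs = ", fs)
  amp <- superlet_tf_batch(matrix(signal, nrow = 1), fs, cfg)[, , 1]
  new_tf(amp, superlet_freqs(cfg), t0 + (seq_along(signal) - 1) / fs,
         superlet_valid_margin(cfg, fs))
}

# Batched transform: signals as rows; returns n_freqs x n_samples x n_signals.
superlet_tf_batch <- function(signals, fs, cfg = superlet_config()) {
  if (any(superlet_freqs(cfg) >= fs / 2))
    stop("f_max must be below Nyquist (fs/2)")
  cpp_superlet(signals, fs, superlet_freqs(cfg), superlet_orders(cfg),
               cfg$c, .Machine$double.eps)
}

new_tf <- function(amp, freqs, times, valid_margin, channel = NA,
                   trial = NA) {
  structure(list(amp = amp, freqs = freqs, times = times,
                 valid_margin = valid_margin, channel = channel,
                 trial = trial),
            class = "bb_tf")
}

#' @export
print.bb_tf <- function(x, ...) {
  cat(sprintf("<bb_tf> %d freqs [%g, %g] Hz x %d samples [%g, %g] s\n",
              length(x$freqs), min(x$freqs), max(x$freqs), length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}
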