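# Shared fixtures built in code.

default_timing <- function(trial_end = 4, post_end = 5) {
  list(baseline_start = -1, trial_onset = 0, trial_end = trial_end,
       post_end = post_end)
}

# Small random epochs object on the standard grid.
make_test_epochs <- function(n_trials = 4, n_channels = 3, fs = 100,
                             timing = default_timing(), seed = 99) {
  set.seed(seed)
  ns <- round((timing$post_end - timing$baseline_start) * fs)
  data <- array(rnorm(n_trials * n_channels * ns), c(n_trials, n_channels, ns))
  labels <- rep_len(c("left_hand", "right_hand"), n_trials)
  ch <- c("C3", "C4", paste0("ch", seq_len(max(0, n_channels - 2))))
  bb_epochs(data, fs, ch[seq_len(n_channels)], labels, timing, "test")
}

# Epochs with a pure sinusoid on every channel.
tone_epochs <- function(freq, fs = 250, amp = 1, n_trials = 1,
                        n_channels = 1, timing = default_timing()) {
  ns <- round((timing$post_end - timing$baseline_start) * fs)
  t <- (seq_len(ns) - 1) / fs
  x <- amp * sin(2 * pi * freq * t)
  data <- array(rep(x, each = n_trials * n_channels),
                c(n_trials, n_channels, ns))
  bb_epochs(data, fs, paste0("ch", seq_len(n_channels)),
            rep_len(c("left_hand", "right_hand"), n_trials), timing, "tone")
}

# A bb_bursts object built directly from a waveform matrix and metadata.
fake_bursts <- function(trial, channel, period, class, waveforms,
                        peak_time = NULL, peak_freq = 20) {
  n <- length(trial)
  structure(list(
    info = data.frame(trial = trial, channel = channel,
                      peak_time = peak_time %||% seq_len(n) * 0.1,
                      peak_freq = rep_len(peak_freq, n),
                      peak_amp = rep(1, n), fwhm_time = rep(0.1, n),
                      fwhm_freq = rep(2, n),
                      trough_time = peak_time %||% seq_len(n) * 0.1,
                      period = period, class = class,
                      stringsAsFactors = FALSE),
    waveforms = waveforms), class = "bb_bursts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Simple smoothed amplitude spectrum (for PSD-style checks).
amp_spectrum <- function(x, fs) {
  n <- length(x)
  a <- Mod(fft(x))[1:(n %/% 2)]
  f <- (0:(n %/% 2 - 1)) * fs / n
  list(f = f, a = a)
}
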