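#' Describe a family of synthetic beta bursts
#'
#' A burst family is a waveform archetype: a trough-centered cosine at
#' `center_freq` under an asymmetric Gaussian envelope. `n_cycles` sets the
#' envelope FWHM in oscillation periods (duration control), `skew` shifts
#' envelope energy to the left (negative) or right (positive) of the trough,
#' and realized amplitudes are drawn from
#' `Normal(amplitude_mean, amplitude_sd)`.
#'
#' @param center_freq burst frequency in Hz, within the beta band [15, 30].
#' @param n_cycles envelope FWHM in periods (> 0).
#' @param skew temporal asymmetry; 0 is symmetric.
#' @param amplitude_mean,amplitude_sd trough amplitude distribution, microvolts.
#' @return an object of class `bb_family`.
#' @export
burst_family <- function(center_freq, n_cycles = 3, skew = 0,
                         amplitude_mean = 10, amplitude_sd = 1.5) {
  if (center_freq < 15 || center_freq > 30)
    stop("center_freq must lie in the beta band [15, 30] Hz")
  if (n_cycles <= 0) stop("n_cycles must be > 0")
  structure(list(center_freq = center_freq, n_cycles = n_cycles, skew = skew,
                 amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
                 polarity = "negative_trough"),
            class = "bb_family")
}

# Odd window length for a nominal duration at a given rate.
odd_window_length <- function(duration, fs) {
  n <- round(duration * fs)
  if (n %% 2 == 0) n + 1L else as.integer(n)
}

#' Render one burst waveform
#'
#' Deterministic shape for the family (the amplitude is the only random
#' element and is supplied explicitly). The output is zero-mean, of odd
#' length `round(0.260 * fs)` (rounded to odd), with its deepest trough at
#' the center sample.
#'
#' @param family a [burst_family()].
#' @param fs sampling rate, Hz; must be at least `2.5 * center_freq`.
#' @param amplitude trough depth in microvolts (default: the family mean).
#' @return numeric waveform vector.
#' @export
make_burst_waveform <- function(family, fs, amplitude = family$amplitude_mean) {
  if (fs < 2.5 * family$center_freq)
    stop("fs must be >= 2.5 * center_freq (got fs = ", fs, ")")
  len <- odd_window_length(0.260, fs)
  half <- (len - 1L) / 2L
  t <- (-half:half) / fs
  sigma <- family$n_cycles / (family$center_freq * 2 * sqrt(2 * log(2)))
  s_left <- sigma * exp(-family$skew / 2)
  s_right <- sigma * exp(family$skew / 2)
  env <- ifelse(t < 0, exp(-t^2 / (2 * s_left^2)), exp(-t^2 / (2 * s_right^2)))
  w <- -amplitude * env * cos(2 * pi * family$center_freq * t)
  w - mean(w)
}

#' Default burst-rate table
#'
#' Burst rates (events/s) per (channel, class, period, family). Motor
#' channels express the ERD-like lateralization the pipeline assumes: during
#' the task, total burst rate on the channel contralateral to the imagined
#' hand drops from 0.6/s to 0.25/s while the ipsilateral channel stays near
#' baseline (0.55/s). The modulation is family-specific — family 1 carries
#' the suppression — so the *composition* of waveform shapes, not just the
#' overall rate, is lateralized. Non-motor channels get a class-independent
#' 0.4/s.
#'
#' @param channel_names all channel names of the simulation.
#' @param roles a [channel_roles()] naming the motor channels.
#' @param n_families number of burst families the rates are split over.
#' @return data.frame with columns `channel`, `class`, `period`, `family`,
#'   `rate`.
#' @export
default_rate_table <- function(channel_names, roles = channel_roles(),
                               n_families = 2) {
  rows <- list()
  add <- function(channel, class, period, rates) {
    for (f in seq_len(n_families))
      rows[[length(rows) + 1L]] <<- data.frame(
        channel = channel, class = class, period = period, family = f,
        rate = rates[f], stringsAsFactors = FALSE)
  }
  split_even <- function(total) rep(total / n_families, n_families)
  contra_task <- c(0.05, rep(0.20 / max(1, n_families - 1), n_families - 1))
  ipsi_task <- c(0.35, rep(0.20 / max(1, n_families - 1), n_families - 1))
  if (n_families == 1) { contra_task <- 0.25; ipsi_task <- 0.55 }
  for (cls in c("left_hand", "right_hand")) {
    contra <- if (cls == "left_hand") roles$right_motor else roles$left_motor
    ipsi <- if (cls == "left_hand") roles$left_motor else roles$right_motor
    for (period in c("baseline", "post")) {
      add(contra, cls, period, split_even(0.6))
      add(ipsi, cls, period, split_even(0.6))
    }
    add(contra, cls, "task", contra_task)
    add(ipsi, cls, "task", ipsi_task)
    for (ch in setdiff(channel_names, c(roles$left_motor, roles$right_motor)))
      for (period in c("baseline", "task", "post"))
        add(ch, cls, period, split_even(0.4))
  }
  do.call(rbind, rows)
}

#' Hemisphere-asymmetric burst-rate table
#'
#' A rate table in which the two burst families are contralaterally
#' suppressed with *unequal* strengths: family 1 is strongly suppressed on
#' the left motor channel during right-hand trials, family 2 weakly
#' suppressed on the right motor channel during left-hand trials. The
#' lateralized modulation index takes absolute baseline-to-task shifts per
#' (channel, laterality) cell and contrasts their hemispheric asymmetry
#' between classes, so any mirror-symmetric modulation — including the
#' classic ERD of [default_rate_table()] and equal-strength two-family
#' suppression — cancels in expectation. A nonzero index requires exactly
#' what this table provides: shift magnitudes that differ between the two
#' (class, hemisphere) pairings.
#'
#' @param channel_names all channel names of the simulation.
#' @param roles a [channel_roles()].
#' @param base baseline rate per family per motor channel, events/s.
#' @param contra_strong task-period rate of family 1 on the left motor
#'   channel when contralateral (strong suppression), events/s.
#' @param contra_weak task-period rate of family 2 on the right motor
#'   channel when contralateral (weak suppression), events/s.
#' @param other_rate rate per family on non-motor channels, events/s.
#' @return data.frame as [default_rate_table()]; requires exactly 2 families.
#' @export
lateralized_rate_table <- function(channel_names, roles = channel_roles(),
                                   base = 0.4, contra_strong = 0.02,
                                   contra_weak = 0.25, other_rate = 0.2) {
  rows <- list()
  add <- function(channel, class, period, family, rate)
    rows[[length(rows) + 1L]] <<- data.frame(
      channel = channel, class = class, period = period, family = family,
      rate = rate, stringsAsFactors = FALSE)
  for (cls in c("left_hand", "right_hand")) {
    for (period in c("baseline", "task", "post")) {
      # family 1: strong contralateral suppression on the left motor channel
      r1 <- if (period == "task" && cls == "right_hand") contra_strong else
        base
      add(roles$left_motor, cls, period, 1L, r1)
      add(roles$left_motor, cls, period, 2L, base)
      # family 2: weak contralateral suppression on the right motor channel
      r2 <- if (period == "task" && cls == "left_hand") contra_weak else base
      add(roles$right_motor, cls, period, 2L, r2)
      add(roles$right_motor, cls, period, 1L, base)
      for (ch in setdiff(channel_names,
                         c(roles$left_motor, roles$right_motor))) {
        add(ch, cls, period, 1L, other_rate)
        add(ch, cls, period, 2L, other_rate)
      }
    }
  }
  do.call(rbind, rows)
}

#' Build a simulation configuration
#'
#' Defines everything [simulate_epochs()] needs: trial counts, channel
#' layout, timing, burst families and rates, and the background model
#' (1/f noise, a 10 Hz mu rhythm, optional line noise).
#'
#' @param n_trials_per_class trials per class.
#' @param channel_names channel labels; must include the motor channels of
#'   `roles`.
#' @param fs sampling rate, Hz.
#' @param timing epoch timing as for [bb_epochs()].
#' @param roles a [channel_roles()].
#' @param families list of [burst_family()] objects.
#' @param rate_table as [default_rate_table()]; `NULL` uses the default.
#' @param noise_exponent 1/f spectral slope of the background (PSD ~
#'   f^-noise_exponent).
#' @param noise_scale background standard deviation, microvolts.
#' @param mu_freq,mu_amp mu-rhythm frequency (Hz) and amplitude (microvolts);
#'   `mu_amp = 0` disables it.
#' @param line_freq,line_amp optional narrow-band interference tone
#'   (`line_freq = NULL` disables it).
#' @param edge_margin minimum distance of burst peaks from the epoch edges, s.
#' @param seed integer RNG seed.
#' @return an object of class `bb_simconfig`.
#' @export
simulation_config <- function(n_trials_per_class = 20,
                              channel_names = c("C3", "C4", "Cz", "Pz"),
                              fs = 250,
                              timing = list(baseline_start = -1,
                                            trial_onset = 0, trial_end = 4,
                                            post_end = 5),
                              roles = channel_roles(),
                              families = list(
                                burst_family(19, n_cycles = 3, skew = -1),
                                burst_family(26, n_cycles = 4, skew = 1)),
                              rate_table = NULL,
                              noise_exponent = 1, noise_scale = 6,
                              mu_freq = 10, mu_amp = 4,
                              line_freq = NULL, line_amp = 10,
                              edge_margin = 0.35,
                              seed = 1L) {
  if (is.null(rate_table))
    rate_table <- default_rate_table(channel_names, roles, length(families))
  if (any(rate_table$rate < 0)) stop("rates must be >= 0")
  structure(list(n_trials_per_class = n_trials_per_class,
                 channel_names = channel_names, fs = fs, timing = timing,
                 roles = roles, families = families, rate_table = rate_table,
                 noise_exponent = noise_exponent, noise_scale = noise_scale,
                 mu_freq = mu_freq, mu_amp = mu_amp,
                 line_freq = line_freq, line_amp = line_amp,
                 edge_margin = edge_margin, seed = as.integer(seed)),
            class = "bb_simconfig")
}

# Colored (1/f^a PSD) Gaussian noise, unit variance in expectation, length n.
colored_noise <- function(n, fs, exponent) {
  nf <- n %/% 2
  f <- (1:nf) * fs / n
  gain <- f^(-exponent / 2)
  # unit expected variance: each rfft bin contributes 2*gain^2/n^2 * (n/2)
  gain <- gain / sqrt(sum(gain^2) / nf)
  z <- complex(real = rnorm(nf), imaginary = rnorm(nf)) / sqrt(2)
  spec <- complex(real = rep(0, n))
  spec[2:(nf + 1)] <- z * gain
  if (n %% 2 == 0) spec[nf + 1] <- complex(real = rnorm(1)) * gain[nf]
  x <- Re(fft(spec, inverse = TRUE)) * sqrt(2 / n)
  x
}

segment_bounds <- function(timing) {
  list(baseline = c(timing$baseline_start, timing$trial_onset),
       task = c(timing$trial_onset, timing$trial_end),
       post = c(timing$trial_end, timing$post_end))
}

rate_lookup <- function(rate_table, channel, class, period, family) {
  r <- rate_table$rate[rate_table$channel == channel &
                       rate_table$class == class &
                       rate_table$period == period &
                       rate_table$family == family]
  if (length(r) == 0) 0 else r[1]
}

#' Simulate epoched EEG with ground-truth bursts
#'
#' Each trial/channel is 1/f background noise plus a mu-rhythm sinusoid
#' (random phase per trial/channel), an optional line tone, and beta bursts
#' placed by a Poisson process at the configured per-(channel, class,
#' period, family) rates. Burst peaks keep at least 130 ms separation on a
#' channel (placement is re-drawn, so realized counts stay Poisson-like at
#' the configured rates) and stay `edge_margin` away from the epoch edges.
#' Class labels are exactly balanced and shuffled under the seed.
#'
#' @param config a [simulation_config()].
#' @return `list(epochs = bb_epochs, truth = data.frame)`; `truth` has one
#'   row per injected event: `trial`, `channel` (index), `channel_name`,
#'   `peak_time` (s), `family`, `amplitude`, `class`, `period`.
#' @export
simulate_epochs <- function(config) {
  if (config$n_trials_per_class < 1) stop("need at least one trial per class")
  if (length(config$channel_names) < 1) stop("need at least one channel")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  fs <- config$fs; tm <- config$timing
  nchan <- length(config$channel_names)
  ntr <- 2L * config$n_trials_per_class
  ns <- round((tm$post_end - tm$baseline_start) * fs)
  labels <- sample(rep(c("left_hand", "right_hand"),
                       config$n_trials_per_class))
  times <- tm$baseline_start + (seq_len(ns) - 1) / fs
  segs <- segment_bounds(tm)
  waveforms <- lapply(config$families, make_burst_waveform, fs = fs)
  half <- (length(waveforms[[1]]) - 1L) / 2L

  data <- array(0, dim = c(ntr, nchan, ns))
  truth <- list()
  min_sep <- 0.130
  lo_t <- tm$baseline_start + config$edge_margin
  hi_t <- tm$post_end - config$edge_margin

  for (ti in seq_len(ntr)) {
    cls <- labels[ti]
    for (ci in seq_len(nchan)) {
      chname <- config$channel_names[ci]
      x <- colored_noise(ns, fs, config$noise_exponent) * config$noise_scale
      if (config$mu_amp > 0)
        x <- x + config$mu_amp * sin(2 * pi * config$mu_freq * times +
                                     runif(1, 0, 2 * pi))
      if (!is.null(config$line_freq))
        x <- x + config$line_amp * sin(2 * pi * config$line_freq * times +
                                       runif(1, 0, 2 * pi))
      placed <- numeric(0)
      for (seg in names(segs)) {
        b <- segs[[seg]]
        for (fi in seq_along(config$families)) {
          rate <- rate_lookup(config$rate_table, chname, cls, seg, fi)
          if (rate <= 0) next
          n_ev <- rpois(1, rate * (b[2] - b[1]))
          for (k in seq_len(n_ev)) {
            for (try in 1:20) {
              pt <- runif(1, max(b[1], lo_t), min(b[2], hi_t))
              if (!length(placed) || min(abs(placed - pt)) >= min_sep) {
                placed <- c(placed, pt)
                amp <- max(0.1, rnorm(1, config$families[[fi]]$amplitude_mean,
                                      config$families[[fi]]$amplitude_sd))
                ctr <- round((pt - tm$baseline_start) * fs) + 1L
                idx <- (ctr - half):(ctr + half)
                keep <- idx >= 1L & idx <= ns
                w <- waveforms[[fi]] *
                  (amp / config$families[[fi]]$amplitude_mean)
                x[idx[keep]] <- x[idx[keep]] + w[keep]
                truth[[length(truth) + 1L]] <- data.frame(
                  trial = ti, channel = ci, channel_name = chname,
                  peak_time = times[ctr], family = fi, amplitude = amp,
                  class = cls, period = seg, stringsAsFactors = FALSE)
                break
              }
            }
          }
        }
      }
      data[ti, ci, ] <- x
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(trial = integer(0), channel = integer(0),
               channel_name = character(0), peak_time = numeric(0),
               family = integer(0), amplitude = numeric(0),
               class = character(0), period = character(0))
  epochs <- bb_epochs(data, fs, config$channel_names, labels, tm,
                      dataset_id = "synthetic")
  list(epochs = epochs, truth = truth)
}

#' Simulate label-null epochs
#'
#' Identical generative model to [simulate_epochs()] except that burst rates
#' are first averaged across the two classes for every (channel, period,
#' family) cell, so labels carry no information. Used to test type-I error
#' of decoding and statistics.
#'
#' @inheritParams simulate_epochs
#' @return as [simulate_epochs()].
#' @export
null_epochs <- function(config) {
  rt <- config$rate_table
  pooled <- aggregate(rate ~ channel + period + family, data = rt, FUN = mean)
  merged <- merge(rt[, c("channel", "class", "period", "family")], pooled,
                  by = c("channel", "period", "family"), sort = FALSE)
  config$rate_table <- merged[, c("channel", "class", "period", "family",
                                  "rate")]
  simulate_epochs(config)
}
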