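# Study conditions for the simulation-based validation checks. These are
# fixed experimental designs, not tunable knobs: each block of checks uses
# one generator configuration chosen to express the condition it validates.

# Detector-recovery condition: default lateralized rates, every burst at a
# fixed 10 uV trough (time-frequency SNR ~ 4, above the 3x floor the
# recovery contract assumes).
detection_study_config <- function(seed = 1, n_trials_per_class = 10) {
  simulation_config(
    n_trials_per_class = n_trials_per_class, seed = seed,
    families = list(burst_family(19, n_cycles = 3, skew = -1,
                                 amplitude_mean = 10, amplitude_sd = 0),
                    burst_family(26, n_cycles = 4, skew = 1,
                                 amplitude_mean = 10, amplitude_sd = 0)))
}

# Kernel-recovery condition: two families whose rates are class- and
# hemisphere-modulated with unequal contralateral suppression (the
# interaction the modulation index detects), fixed 12 uV amplitude,
# 60 trials per class.
recovery_study_config <- function(seed, n_trials_per_class = 60) {
  roles <- channel_roles()
  chn <- c("C3", "C4", "Cz", "Pz")
  simulation_config(
    n_trials_per_class = n_trials_per_class, seed = seed,
    channel_names = chn,
    families = list(burst_family(19, n_cycles = 3, skew = -1,
                                 amplitude_mean = 12, amplitude_sd = 0),
                    burst_family(26, n_cycles = 4, skew = 1,
                                 amplitude_mean = 12, amplitude_sd = 0)),
    rate_table = lateralized_rate_table(chn, roles))
}

# Decoding condition: strongly lateralized rates (task-period contralateral
# suppression to 0.05/s total against 0.7/s ipsilateral), 15 uV bursts.
high_contrast_table <- function(chn, roles) {
  rt <- default_rate_table(chn, roles)
  for (cls in c("left_hand", "right_hand")) {
    contra <- if (cls == "left_hand") roles$right_motor else roles$left_motor
    ipsi <- if (cls == "left_hand") roles$left_motor else roles$right_motor
    rt$rate[rt$channel == contra & rt$class == cls &
              rt$period == "task"] <- c(0.025, 0.025)
    rt$rate[rt$channel == ipsi & rt$class == cls &
              rt$period == "task"] <- c(0.35, 0.35)
  }
  rt
}

decoding_study_config <- function(seed, n_trials_per_class) {
  roles <- channel_roles()
  chn <- c("C3", "C4", "Cz", "Pz")
  simulation_config(
    n_trials_per_class = n_trials_per_class, seed = seed,
    channel_names = chn,
    families = list(burst_family(19, n_cycles = 3, skew = -1,
                                 amplitude_mean = 15),
                    burst_family(26, n_cycles = 4, skew = 1,
                                 amplitude_mean = 15)),
    rate_table = high_contrast_table(chn, roles))
}

study_templates <- function(cfg, fs = 250) {
  lapply(cfg$families, make_burst_waveform, fs = fs)
}

# Match detections to ground truth within +/- 50 ms and +/- 3 Hz; returns
# recall over truth events and the false-discovery rate over detections.
match_detections <- function(bursts, truth, families,
                             channels = c("C3", "C4"),
                             dt = 0.05, df = 3) {
  fam_f <- vapply(families, `[[`, numeric(1), "center_freq")
  tr <- truth[truth$channel_name %in% channels, ]
  info <- bursts$info
  hit <- vapply(seq_len(nrow(tr)), function(i) {
    ev <- tr[i, ]
    cand <- info[info$trial == ev$trial & info$channel == ev$channel_name, ]
    nrow(cand) > 0 && any(abs(cand$peak_time - ev$peak_time) <= dt &
                            abs(cand$peak_freq - fam_f[ev$family]) <= df)
  }, logical(1))
  fd <- vapply(seq_len(nrow(info)), function(i) {
    d <- info[i, ]
    cand <- tr[tr$trial == d$trial & tr$channel_name == d$channel, ]
    nrow(cand) == 0 || !any(abs(cand$peak_time - d$peak_time) <= dt &
                              abs(fam_f[cand$family] - d$peak_freq) <= df)
  }, logical(1))
  list(recall = mean(hit), fdr = mean(fd), n_truth = nrow(tr),
       n_detected = nrow(info))
}
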