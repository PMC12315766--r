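#' Epoched multichannel EEG container
#'
#' `bb_epochs` holds a trial tensor (`n_trials x n_channels x n_samples`,
#' microvolts) together with the sampling rate, channel names, per-trial class
#' labels and the epoch timing. Time is expressed in seconds relative to trial
#' onset (`trial_onset = 0`), so the baseline starts at a negative time.
#' Sample indexing is 0-based internally and windows are half-open
#' `[start, end)`: a window of `w` seconds always contains `round(w * fs)`
#' samples regardless of where it sits on the grid.
#'
#' @param data numeric array `n_trials x n_channels x n_samples` (microvolts).
#' @param fs sampling rate in Hz.
#' @param channel_names character vector of channel labels.
#' @param labels per-trial class labels; exactly two distinct classes are
#'   allowed (canonically `"left_hand"` / `"right_hand"`).
#' @param timing named list with `baseline_start`, `trial_onset` (must be 0),
#'   `trial_end` and `post_end`, all in seconds relative to trial onset.
#' @param dataset_id free-text identifier.
#'
#' @return an object of class `bb_epochs`.
#' @export
bb_epochs <- function(data, fs, channel_names, labels, timing,
                      dataset_id = "unnamed") {
  e <- new_bb_epochs(data, fs, channel_names, labels, timing, dataset_id)
  validate_bb_epochs(e)
  e
}

# Low-level constructor: no ordering checks, used for cropped views.
new_bb_epochs <- function(data, fs, channel_names, labels, timing,
                          dataset_id = "unnamed", cropped = FALSE) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (trials x channels x samples)")
  structure(
    list(data = data, fs = as.numeric(fs),
         channel_names = as.character(channel_names),
         labels = as.character(labels),
         timing = timing, dataset_id = dataset_id, cropped = cropped),
    class = "bb_epochs")
}

validate_bb_epochs <- function(e) {
  d <- dim(e$data)
  tm <- e$timing
  req <- c("baseline_start", "trial_onset", "trial_end", "post_end")
  if (!all(req %in% names(tm)))
    stop("timing must contain ", paste(req, collapse = ", "))
  if (!is.finite(e$fs) || e$fs <= 0) stop("fs must be > 0")
  if (!e$cropped) {
    if (tm$trial_onset != 0) stop("trial_onset must be 0")
    if (!(tm$baseline_start < 0 && 0 < tm$trial_end &&
          tm$trial_end <= tm$post_end))
      stop("timing must satisfy baseline_start < 0 < trial_end <= post_end")
  }
  n_expect <- round((tm$post_end - tm$baseline_start) * e$fs)
  if (d[3] != n_expect)
    stop(sprintf("n_samples (%d) != round((post_end - baseline_start) * fs) = %d",
                 d[3], n_expect))
  if (length(e$channel_names) != d[2])
    stop("channel_names length must equal n_channels")
  if (length(e$labels) != d[1])
    stop("labels length must equal n_trials")
  if (d[1] > 0 && length(unique(e$labels)) > 2L)
    stop("at most two classes allowed")
  invisible(e)
}

#' @export
print.bb_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bb_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  span [%g, %g) s, trial [%g, %g] s; dataset '%s'\n",
              x$timing$baseline_start, x$timing$post_end,
              x$timing$trial_onset, x$timing$trial_end, x$dataset_id))
  if (d[1] > 0) {
    tab <- table(x$labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

n_trials <- function(e) dim(e$data)[1]
n_channels <- function(e) dim(e$data)[2]
n_samples <- function(e) dim(e$data)[3]

#' Time axis of an epochs object
#'
#' @param e a [bb_epochs] object.
#' @return numeric vector of sample times in seconds (left edges of the
#'   sampling grid), relative to trial onset.
#' @export
epoch_times <- function(e) {
  e$timing$baseline_start + (seq_len(n_samples(e)) - 1L) / e$fs
}

#' Crop epochs to a time window
#'
#' Returns a copy restricted to the half-open window `[t_start, t_end)`.
#' Trials, channels, sampling rate and labels are unchanged.
#'
#' @param e a [bb_epochs] object.
#' @param t_start,t_end window bounds in seconds relative to trial onset;
#'   must satisfy `baseline_start <= t_start < t_end <= post_end`.
#' @return a cropped [bb_epochs].
#' @export
crop_epochs <- function(e, t_start, t_end) {
  tm <- e$timing
  if (!(t_start < t_end))
    stop("t_start must be < t_end")
  tol <- 1e-9
  if (t_start < tm$baseline_start - tol || t_end > tm$post_end + tol)
    stop(sprintf("crop window [%g, %g) outside epoch span [%g, %g)",
                 t_start, t_end, tm$baseline_start, tm$post_end))
  i0 <- round((t_start - tm$baseline_start) * e$fs)
  n <- round((t_end - t_start) * e$fs)
  if (n < 1L) stop("crop window shorter than one sample")
  idx <- seq.int(i0 + 1L, i0 + n)
  new_timing <- list(baseline_start = t_start, trial_onset = tm$trial_onset,
                     trial_end = tm$trial_end, post_end = t_end)
  new_bb_epochs(e$data[, , idx, drop = FALSE], e$fs, e$channel_names,
                e$labels, new_timing, e$dataset_id, cropped = TRUE)
}

#' Channel role map
#'
#' Associates scalp roles with channel names: the left and right motor
#' channels (over the sensorimotor cortex, conventionally `"C3"` / `"C4"`)
#' and the cluster of channels used for burst detection. Datasets without
#' 10-20 names (e.g. numeric labels where channel 43 plays the role of C3)
#' are handled by pointing the roles at whatever labels the recording uses.
#'
#' @param left_motor channel name over the left motor cortex (default "C3").
#' @param right_motor channel name over the right motor cortex (default "C4").
#' @param burst_cluster channels used for burst detection; defaults to the
#'   two motor channels.
#' @return an object of class `bb_roles`.
#' @export
channel_roles <- function(left_motor = "C3", right_motor = "C4",
                          burst_cluster = c(left_motor, right_motor)) {
  structure(list(left_motor = left_motor, right_motor = right_motor,
                 burst_cluster = burst_cluster),
            class = "bb_roles")
}

check_roles <- function(roles, e) {
  need <- unique(c(roles$left_motor, roles$right_motor, roles$burst_cluster))
  missing <- setdiff(need, e$channel_names)
  if (length(missing))
    stop("channels not present in epochs: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

chan_index <- function(e, name) {
  i <- match(name, e$channel_names)
  if (is.na(i)) stop("unknown channel: ", name)
  i
}

# Period of a time point relative to the epoch timing.
time_period <- function(t, timing) {
  ifelse(t < timing$trial_onset, "baseline",
         ifelse(t < timing$trial_end, "task", "post"))
}
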