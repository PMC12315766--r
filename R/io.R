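#' Read epoched EEG from disk
#'
#' Supported formats:
#' \describe{
#'   \item{`native`}{the package's lossless container: a gzip-compressed
#'     little-endian float64 array file plus a JSON sidecar
#'     (`<path>.json`) holding sampling rate, channel names, labels and
#'     timing. Round-trips bit-for-bit.}
#'   \item{`edf`}{European Data Format; one EDF data record per trial.
#'     Class labels and timing are read from the JSON sidecar
#'     `<path>.json` (EDF itself stores neither). EDF quantizes samples to
#'     16-bit integers; see [edf_quantization_step()].}
#'   \item{`brainvision`}{BrainVision `.vhdr`/`.eeg`/`.vmrk` triplet
#'     (binary IEEE float32 / int16 or ASCII, multiplexed). Trials are cut
#'     around `Stimulus` markers; the JSON sidecar supplies `timing` and a
#'     `label_map` from marker description to class label.}
#' }
#'
#' @param path file path (for BrainVision, the `.vhdr` file; for the other
#'   formats, the data file written by [write_epochs()]).
#' @param format one of `"native"`, `"edf"`, `"brainvision"`.
#' @return a [bb_epochs] object.
#' @export
read_epochs <- function(path, format = c("native", "edf", "brainvision")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         native = read_epochs_native(path),
         edf = read_epochs_edf(path),
         brainvision = read_epochs_brainvision(path))
}

#' Write epoched EEG to disk
#'
#' @param e a [bb_epochs] object.
#' @param path output path; a JSON sidecar `<path>.json` is written next to
#'   the data file.
#' @param format `"native"` (lossless) or `"edf"` (16-bit quantized).
#' @return `path`, invisibly.
#' @export
write_epochs <- function(e, path, format = c("native", "edf")) {
  format <- match.arg(format)
  validate_bb_epochs(e)
  switch(format,
         native = write_epochs_native(e, path),
         edf = write_epochs_edf(e, path))
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

epochs_metadata <- function(e) {
  list(fs = e$fs, channel_names = e$channel_names, labels = e$labels,
       timing = e$timing[c("baseline_start", "trial_onset", "trial_end",
                           "post_end")],
       dataset_id = e$dataset_id,
       n_trials = n_trials(e), n_channels = n_channels(e),
       n_samples = n_samples(e))
}

write_sidecar <- function(e, path, extra = list()) {
  meta <- c(epochs_metadata(e), extra)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

read_sidecar <- function(path, require = c("fs", "labels", "timing")) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("metadata error: sidecar not found: ", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (f in require)
    if (is.null(meta[[f]]))
      stop("metadata error: sidecar missing field '", f, "'")
  meta$timing <- as.list(meta$timing)
  meta
}

# ---- native container ------------------------------------------------------

write_epochs_native <- function(e, path) {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(e$data, c(3, 2, 1))), con, size = 8,
           endian = "little")
  write_sidecar(e, path, extra = list(container = "burstconv-native-v1"))
}

read_epochs_native <- function(path) {
  meta <- read_sidecar(path)
  nt <- meta$n_trials; nc <- meta$n_channels; ns <- meta$n_samples
  con <- gzfile(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "numeric", n = nt * nc * ns + 1L, size = 8,
                  endian = "little")
  if (length(vals) != nt * nc * ns)
    stop("shape error: expected ", nt * nc * ns, " samples, found ",
         length(vals))
  data <- aperm(array(vals, dim = c(ns, nc, nt)), c(3, 2, 1))
  bb_epochs(data, meta$fs, meta$channel_names, meta$labels, meta$timing,
            meta$dataset_id %||% "unnamed")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
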