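# Minimal EDF support. Each trial is stored as one EDF data record (record
# duration = epoch length in seconds); samples are quantized to int16 against
# per-channel physical ranges, exactly as re-read (the physical limits are
# first rounded to their 8-character ASCII header representation, and the
# quantizer uses those rounded values, so the round-trip error is bounded by
# half a quantization step). Labels and timing live in the JSON sidecar.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

# Shortest ASCII form of a number that fits in `width` chars and reparses.
edf_num <- function(x, width = 8) {
  for (digits in seq(10, 0)) {
    s <- formatC(x, digits = digits, format = "g", width = 1)
    if (nchar(s) <= width) return(s)
  }
  stop("cannot represent ", x, " in ", width, " characters")
}

edf_phys_range <- function(x) {
  if (length(x) == 0 || !any(is.finite(x))) return(c(-1, 1))
  r <- range(x, finite = TRUE)
  if (r[1] == r[2]) r <- r + c(-1, 1)
  # round limits to their on-disk ASCII form so quantization is consistent
  c(as.numeric(edf_num(r[1])), as.numeric(edf_num(r[2])))
}

#' EDF quantization step
#'
#' EDF stores samples as 16-bit integers scaled to a per-channel physical
#' range; this returns the worst-case (largest) quantization step across
#' channels for an epochs object, i.e. the resolution limit of an EDF
#' round-trip. The round-trip error of [write_epochs()] with
#' `format = "edf"` is at most half this value.
#'
#' @param e a [bb_epochs] object.
#' @return quantization step in microvolts.
#' @export
edf_quantization_step <- function(e) {
  steps <- vapply(seq_len(n_channels(e)), function(ci) {
    r <- edf_phys_range(e$data[, ci, ])
    (r[2] - r[1]) / 65535
  }, numeric(1))
  max(steps)
}

write_epochs_edf <- function(e, path) {
  nt <- n_trials(e); nc <- n_channels(e); ns <- n_samples(e)
  ranges <- lapply(seq_len(nc), function(ci) edf_phys_range(e$data[, ci, ]))
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  put("0", 8)
  put("X X X X", 80)
  put(paste("Startdate X X X X", e$dataset_id), 80)
  put("01.01.00", 8)
  put("00.00.00", 8)
  put(256 + nc * 256, 8)
  put("", 44)
  put(nt, 8)
  put(edf_num(ns / e$fs), 8)
  put(nc, 4)
  for (ci in seq_len(nc)) put(e$channel_names[ci], 16)
  for (ci in seq_len(nc)) put("", 80)
  for (ci in seq_len(nc)) put("uV", 8)
  for (ci in seq_len(nc)) put(edf_num(ranges[[ci]][1]), 8)
  for (ci in seq_len(nc)) put(edf_num(ranges[[ci]][2]), 8)
  for (ci in seq_len(nc)) put("-32768", 8)
  for (ci in seq_len(nc)) put("32767", 8)
  for (ci in seq_len(nc)) put("", 80)
  for (ci in seq_len(nc)) put(ns, 8)
  for (ci in seq_len(nc)) put("", 32)
  for (ti in seq_len(nt)) {
    for (ci in seq_len(nc)) {
      r <- ranges[[ci]]
      x <- e$data[ti, ci, ]
      dig <- round((x - r[1]) / (r[2] - r[1]) * 65535 - 32768)
      dig <- pmin(pmax(dig, -32768), 32767)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  write_sidecar(e, path, extra = list(container = "edf"))
}

read_epochs_edf <- function(path) {
  meta <- read_sidecar(path)
  con <- file(path, "rb")
  on.exit(close(con))
  get <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- get(8)
  if (!identical(version, "0")) stop("not an EDF file (version '", version, "')")
  get(80); get(80); get(8); get(8)
  header_bytes <- as.integer(get(8)); get(44)
  nt <- as.integer(get(8))
  rec_dur <- as.numeric(get(8))
  nc <- as.integer(get(4))
  labels <- vapply(seq_len(nc), function(i) get(16), character(1))
  for (i in seq_len(nc)) get(80)            # transducer
  for (i in seq_len(nc)) get(8)             # physical dimension
  pmin <- vapply(seq_len(nc), function(i) as.numeric(get(8)), numeric(1))
  pmax <- vapply(seq_len(nc), function(i) as.numeric(get(8)), numeric(1))
  dmin <- vapply(seq_len(nc), function(i) as.numeric(get(8)), numeric(1))
  dmax <- vapply(seq_len(nc), function(i) as.numeric(get(8)), numeric(1))
  for (i in seq_len(nc)) get(80)            # prefiltering
  nsamp <- vapply(seq_len(nc), function(i) as.integer(get(8)), integer(1))
  for (i in seq_len(nc)) get(32)
  if (length(unique(nsamp)) != 1L)
    stop("shape error: channels with different samples-per-record")
  ns <- nsamp[1]
  data <- array(0, dim = c(nt, nc, ns))
  if (nt > 0) {
    raw <- readBin(con, "integer", n = nt * nc * ns, size = 2, signed = TRUE,
                   endian = "little")
    if (length(raw) != nt * nc * ns)
      stop("shape error: truncated EDF data section")
    k <- 0L
    for (ti in seq_len(nt)) {
      for (ci in seq_len(nc)) {
        dig <- raw[(k + 1):(k + ns)]; k <- k + ns
        data[ti, ci, ] <- (dig - dmin[ci]) * (pmax[ci] - pmin[ci]) /
          (dmax[ci] - dmin[ci]) + pmin[ci]
      }
    }
  }
  if (length(meta$labels) != nt)
    stop("metadata error: sidecar labels do not match EDF record count")
  bb_epochs(data, meta$fs, labels, meta$labels, meta$timing,
            meta$dataset_id %||% "unnamed")
}
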