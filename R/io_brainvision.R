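# Minimal BrainVision reader: .vhdr INI header, multiplexed binary
# (IEEE_FLOAT_32 / INT_16) or ASCII data, .vmrk stimulus markers. The
# recording is treated as continuous; trials are cut around each Stimulus
# marker using the timing in the JSON sidecar (`<base>.json`), whose
# `label_map` translates marker descriptions (e.g. "S  1") to class labels.

parse_vhdr_ini <- function(lines) {
  sec <- NULL
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nchar(ln)) next
    m <- regmatches(ln, regexec("^\\[(.+)\\]$", ln))[[1]]
    if (length(m)) { sec <- m[2]; out[[sec]] <- list(); next }
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) && !is.null(sec))
      out[[sec]][[trimws(kv[2])]] <- trimws(kv[3])
  }
  out
}

read_epochs_brainvision <- function(path) {
  if (!grepl("\\.vhdr$", path))
    stop("usage error: brainvision format expects the .vhdr file")
  base <- sub("\\.vhdr$", "", path)
  meta <- read_sidecar(base, require = "timing")
  ini <- parse_vhdr_ini(readLines(path, warn = FALSE))
  ci <- ini[["Common Infos"]]
  if (is.null(ci)) stop("metadata error: [Common Infos] missing in .vhdr")
  nc <- as.integer(ci$NumberOfChannels)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)   # interval is in microseconds
  orientation <- toupper(ci$DataOrientation %||% "MULTIPLEXED")
  if (orientation != "MULTIPLEXED")
    stop("usage error: only MULTIPLEXED orientation supported")
  data_file <- file.path(dirname(path), ci$DataFile)
  marker_file <- file.path(dirname(path), ci$MarkerFile)
  chinfo <- ini[["Channel Infos"]]
  ch_names <- character(nc); resolution <- rep(1, nc)
  for (i in seq_len(nc)) {
    parts <- strsplit(chinfo[[paste0("Ch", i)]] %||% sprintf("Ch%d,,1", i),
                      ",")[[1]]
    ch_names[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3]))
      resolution[i] <- as.numeric(parts[3])
  }
  fmt <- toupper(ci$DataFormat %||% "BINARY")
  if (fmt == "BINARY") {
    bfmt <- toupper(ini[["Binary Infos"]]$BinaryFormat %||% "IEEE_FLOAT_32")
    sz <- file.info(data_file)$size
    con <- file(data_file, "rb")
    on.exit(close(con))
    if (bfmt == "IEEE_FLOAT_32") {
      raw <- readBin(con, "numeric", n = sz / 4, size = 4, endian = "little")
    } else if (bfmt == "INT_16") {
      raw <- readBin(con, "integer", n = sz / 2, size = 2, signed = TRUE,
                     endian = "little")
    } else stop("usage error: unsupported BinaryFormat ", bfmt)
  } else if (fmt == "ASCII") {
    raw <- as.numeric(t(as.matrix(utils::read.table(data_file))))
  } else stop("usage error: unsupported DataFormat ", fmt)
  n_total <- length(raw) %/% nc
  sig <- matrix(raw[seq_len(n_total * nc)], nrow = nc)   # multiplexed
  sig <- sig * resolution
  mk <- parse_vhdr_ini(readLines(marker_file, warn = FALSE))[["Marker Infos"]]
  onsets <- integer(0); descr <- character(0)
  for (key in names(mk)) {
    parts <- strsplit(mk[[key]], ",")[[1]]
    if (length(parts) >= 3 && identical(parts[1], "Stimulus")) {
      onsets <- c(onsets, as.integer(parts[3]))
      descr <- c(descr, parts[2])
    }
  }
  if (!length(onsets)) stop("metadata error: no Stimulus markers in .vmrk")
  label_map <- meta$label_map
  if (is.null(label_map))
    stop("metadata error: sidecar must provide label_map for brainvision")
  labels <- unlist(label_map[descr], use.names = FALSE)
  if (length(labels) != length(onsets))
    stop("metadata error: marker description missing from label_map")
  tm <- meta$timing
  ns <- round((tm$post_end - tm$baseline_start) * fs)
  off0 <- round(tm$baseline_start * fs)
  data <- array(0, dim = c(length(onsets), nc, ns))
  for (ti in seq_along(onsets)) {
    idx <- onsets[ti] + off0 + seq_len(ns) - 1L
    if (idx[1] < 1L || idx[length(idx)] > n_total)
      stop("shape error: trial ", ti, " extends beyond the recording")
    data[ti, , ] <- sig[, idx]
  }
  bb_epochs(data, fs, ch_names, labels, tm, meta$dataset_id %||% "unnamed")
}
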