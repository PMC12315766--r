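test_that("native container round-trips bit-for-bit on random epochs", {
  for (seed in 1:3) {
    e <- make_test_epochs(n_trials = 2 + seed, n_channels = 2, fs = 50,
                          seed = seed)
    path <- file.path(tempdir(), paste0("e", seed, ".bin.gz"))
    write_epochs(e, path, "native")
    r <- read_epochs(path, "native")
    expect_identical(r$data, e$data)
    expect_identical(r$labels, e$labels)
    expect_identical(r$channel_names, e$channel_names)
    expect_equal(r$timing, e$timing)
    expect_equal(r$fs, e$fs)
  }
})

test_that("native container handles zero-trial epochs", {
  tm <- default_timing()
  e <- bb_epochs(array(0, c(0, 2, 600)), 100, c("C3", "C4"), character(0),
                 tm, "empty")
  path <- file.path(tempdir(), "empty.bin.gz")
  write_epochs(e, path, "native")
  r <- read_epochs(path, "native")
  expect_equal(dim(r$data), c(0, 2, 600))
  expect_equal(r$timing$baseline_start, tm$baseline_start)
})

test_that("reading a nonexistent path errors without partial objects", {
  expect_error(read_epochs(file.path(tempdir(), "nope.bin.gz"), "native"),
               "not found")
})

test_that("EDF round-trip error is bounded by the quantization step", {
  e <- make_test_epochs(n_trials = 3, n_channels = 3, fs = 100, seed = 5)
  e$data <- e$data * 40   # tens of microvolts, realistic EEG scale
  path <- file.path(tempdir(), "trip.edf")
  write_epochs(e, path, "edf")
  r <- read_epochs(path, "edf")
  step <- edf_quantization_step(e)
  expect_lt(max(abs(r$data - e$data)), step / 2 + 1e-12)
  expect_identical(r$labels, e$labels)
  expect_identical(r$channel_names, e$channel_names)
})

test_that("an independent reader (python mne) agrees with the EDF writer", {
  e <- make_test_epochs(n_trials = 2, n_channels = 3, fs = 100, seed = 6)
  e$data <- e$data * 25
  path <- file.path(tempdir(), "xcheck.edf")
  write_epochs(e, path, "edf")
  script <- paste(
    "import sys, numpy as np, mne",
    "raw = mne.io.read_raw_edf(sys.argv[1], preload=True, verbose='ERROR')",
    "d = raw.get_data() * 1e6",  # mne scales EDF uV to volts
    "print(len(raw.ch_names)); print(','.join(raw.ch_names))",
    "print(d.shape[1]); print(np.round(d[0, :5], 3).tolist())",
    sep = "\n")
  sf <- file.path(tempdir(), "readedf.py")
  writeLines(script, sf)
  out <- system2("python", c(sf, path), stdout = TRUE, stderr = FALSE)
  expect_gte(length(out), 4)
  expect_equal(as.integer(out[1]), 3L)
  expect_equal(strsplit(out[2], ",")[[1]], e$channel_names)
  # continuous length = trials x samples-per-trial
  expect_equal(as.integer(out[3]), 2L * dim(e$data)[3])
  got <- as.numeric(strsplit(gsub("\\[|\\]", "", out[4]), ",")[[1]])
  expect_equal(got, round(e$data[1, 1, 1:5], 3),
               tolerance = edf_quantization_step(e))
})

test_that("BrainVision triplets written by an independent helper are read", {
  # helper writes the .vhdr/.eeg/.vmrk set directly from the format spec
  fs <- 100
  tm <- default_timing(trial_end = 1, post_end = 1)
  ns_epoch <- round((tm$post_end - tm$baseline_start) * fs)
  n_total <- 1000
  set.seed(7)
  sig <- matrix(rnorm(2 * n_total), nrow = 2)   # channels x samples
  onsets <- c(201, 501)                          # marker positions, 1-based
  base <- file.path(tempdir(), "bv")
  writeLines(c("Brain Vision Data Exchange Header File Version 1.0",
               "[Common Infos]", "DataFile=bv.eeg", "MarkerFile=bv.vmrk",
               "DataFormat=BINARY", "DataOrientation=MULTIPLEXED",
               "NumberOfChannels=2",
               sprintf("SamplingInterval=%d", as.integer(1e6 / fs)),
               "[Binary Infos]", "BinaryFormat=IEEE_FLOAT_32",
               "[Channel Infos]", "Ch1=C3,,1,uV", "Ch2=C4,,1,uV"),
             paste0(base, ".vhdr"))
  con <- file(paste0(base, ".eeg"), "wb")
  writeBin(as.numeric(sig), con, size = 4, endian = "little")  # multiplexed
  close(con)
  writeLines(c("[Marker Infos]",
               sprintf("Mk1=Stimulus,S  1,%d,1,0", onsets[1]),
               sprintf("Mk2=Stimulus,S  2,%d,1,0", onsets[2])),
             paste0(base, ".vmrk"))
  jsonlite::write_json(list(timing = tm,
                            label_map = list("S  1" = "left_hand",
                                             "S  2" = "right_hand")),
                       paste0(base, ".json"), auto_unbox = TRUE)
  e <- read_epochs(paste0(base, ".vhdr"), "brainvision")
  expect_equal(dim(e$data), c(2, 2, ns_epoch))
  expect_equal(e$labels, c("left_hand", "right_hand"))
  expect_equal(e$fs, fs)
  # trial 1 starts baseline_start before its marker
  i0 <- onsets[1] + round(tm$baseline_start * fs)
  expect_equal(e$data[1, 1, ], sig[1, i0:(i0 + ns_epoch - 1)],
               tolerance = 1e-6)
})

test_that("crop_epochs windows are half-open and compose", {
  e <- make_test_epochs(n_trials = 3, n_channels = 2, fs = 250)
  full <- crop_epochs(e, e$timing$baseline_start, e$timing$post_end)
  expect_equal(full$data, e$data)
  c1 <- crop_epochs(e, 0, 0.1)
  expect_equal(dim(c1$data)[3], 25)
  # crop twice equals one crop to the intersection
  a <- crop_epochs(crop_epochs(e, 0, 3), 1, 2)
  b <- crop_epochs(e, 1, 2)
  expect_equal(a$data, b$data)
  expect_identical(a$labels, e$labels)
  expect_equal(a$fs, e$fs)
  expect_error(crop_epochs(e, 2, 1), "t_start")
  expect_error(crop_epochs(e, -5, 1), "outside")
})

test_that("epochs validation enforces the timing and label contract", {
  tm <- default_timing()
  d <- array(0, c(2, 1, 600))
  expect_error(bb_epochs(d, 100, "C3", c("a", "b", "c"), tm), "labels")
  expect_error(bb_epochs(d, -1, "C3", c("a", "b"), tm), "fs")
  bad <- tm; bad$trial_onset <- 0.5
  expect_error(bb_epochs(d, 100, "C3", c("a", "b"), bad), "trial_onset")
  expect_error(bb_epochs(array(0, c(2, 1, 599)), 100, "C3", c("a", "b"), tm),
               "n_samples")
})

test_that("config files merge over package defaults", {
  p <- file.path(tempdir(), "cfg.yaml")
  writeLines(c("roles:", "  left_motor: '43'", "  right_motor: '44'",
               "  burst_cluster: ['43', '44']", "n_csp: 6"), p)
  cfg <- read_config(p)
  expect_equal(cfg$roles$left_motor, "43")      # channel aliasing via roles
  expect_equal(cfg$n_csp, 6)
  expect_equal(cfg$superlet$o_max, 40)          # untouched defaults survive
  expect_equal(cfg$bands$beta, c(15, 30))
  pj <- file.path(tempdir(), "cfg.json")
  jsonlite::write_json(list(sample_fraction = 0.05), pj, auto_unbox = TRUE)
  expect_equal(read_config(pj)$sample_fraction, 0.05)
  expect_error(read_config(file.path(tempdir(), "missing.yaml")), "not found")
})
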