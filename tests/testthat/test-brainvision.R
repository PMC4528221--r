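make_small_recording <- function(fs = 2500, n = 1000, nch = 4, seed = 2) {
  labels <- c("C3", "C4", "EMG1", "EMG2")[seq_len(nch)]
  data <- brainswitch:::with_seed(seed, matrix(rnorm(nch * n), nch,
                                               dimnames = list(labels, NULL)))
  structure(list(data = data, sample_rate_hz = fs, channel_labels = labels,
                 channel_kinds = ifelse(grepl("^EMG", labels), "EMG", "EEG"),
                 start_time = 0),
            class = "raw_recording")
}

test_that("header encodes rate and layout; binary size is float32-exact", {
  rec <- make_small_recording(fs = 2500, n = 1000, nch = 4)
  ev <- data.frame(onset_s = c(0.1, 0.2), duration_s = 0.05,
                   condition = c("actual", "none"))
  base <- file.path(withr::local_tempdir(), "rec")
  write_brainvision(rec, ev, base)
  hdr <- readLines(paste0(base, ".vhdr"))
  expect_true("SamplingInterval=400" %in% hdr)       # 1e6 / 2500 us
  expect_true("NumberOfChannels=4" %in% hdr)
  expect_equal(file.size(paste0(base, ".eeg")), 4 * 1000 * 4)
})

test_that("write -> read round-trips data, channel order and markers", {
  rec <- make_small_recording(fs = FIXTURE_FS, n = 5000)
  ev <- data.frame(onset_s = c(1, 8, 15), duration_s = 3,
                   condition = c("attempted", "none", "attempted"))
  base <- file.path(withr::local_tempdir(), "rt")
  write_brainvision(rec, ev, base)
  back <- read_brainvision(base)
  expect_equal(back$recording$channel_labels, rec$channel_labels)
  expect_equal(back$recording$sample_rate_hz, FIXTURE_FS)
  # float32 precision round trip
  expect_equal(back$recording$data, rec$data, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(back$recording$data, rec$data, tolerance = 0)))
  expect_equal(back$events$onset_s, ev$onset_s)
  expect_equal(back$events$condition, ev$condition)
  expect_equal(back$events$duration_s, ev$duration_s)
})

test_that("marker sample positions map onsets through the sampling rate", {
  rec <- make_small_recording(fs = 2500, n = 20000)
  ev <- data.frame(onset_s = 7, duration_s = 3, condition = "actual")
  base <- file.path(withr::local_tempdir(), "mk")
  write_brainvision(rec, ev, base)
  mk <- grep("^Mk1=", readLines(paste0(base, ".vmrk")), value = TRUE)
  expect_equal(mk, "Mk1=Stimulus,actual,17500,7500,0")
  expect_equal(read_brainvision(base)$events$onset_s, 7)
})

test_that("corrupt or unsupported triplets are rejected loudly", {
  rec <- make_small_recording(fs = FIXTURE_FS, n = 500)
  ev <- data.frame(onset_s = 0.5, duration_s = 0.1, condition = "none")
  base <- file.path(withr::local_tempdir(), "bad")
  write_brainvision(rec, ev, base)

  # truncated binary: no longer a whole number of multiplexed frames
  bin <- readBin(paste0(base, ".eeg"), "raw", n = 4 * 4 * 500)
  writeBin(bin[seq_len(length(bin) - 5)], paste0(base, ".eeg"))
  expect_error(read_brainvision(base), "not a multiple")

  # unsupported encoding
  hdr <- readLines(paste0(base, ".vhdr"))
  writeLines(sub("IEEE_FLOAT_32", "INT_16", hdr), paste0(base, ".vhdr"))
  expect_error(read_brainvision(base), "unsupported BinaryFormat")

  expect_error(read_brainvision(file.path(tempdir(), "nope")), "missing header")
})
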