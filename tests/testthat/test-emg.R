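test_that("the Hilbert envelope of a sinusoid is its amplitude", {
  fs <- 1000
  t <- (0:(4 * fs - 1)) / fs
  for (A in c(1, 2.5)) {
    env <- hilbert_envelope(A * sin(2 * pi * 50 * t))
    interior <- seq(fs / 2, length(t) - fs / 2)
    expect_equal(mean(env[interior]), A, tolerance = 0.01)
  }
})

test_that("a 50 Hz sinusoid on the bipolar pair reads back as its amplitude", {
  fs <- FIXTURE_FS
  n <- 10 * fs
  t <- (0:(n - 1)) / fs
  A <- 3
  data <- matrix(0, 3, n, dimnames = list(c("C3", "EMG1", "EMG2"), NULL))
  data["EMG1", ] <- A / 2 * sin(2 * pi * 50 * t)
  data["EMG2", ] <- -A / 2 * sin(2 * pi * 50 * t)
  rec <- structure(list(data = data, sample_rate_hz = fs,
                        channel_labels = rownames(data),
                        channel_kinds = c("EEG", "EMG", "EMG"), start_time = 0),
                   class = "raw_recording")
  ev <- data.frame(onset_s = c(1, 5), duration_s = 3,
                   condition = c("actual", "none"))
  es <- emg_power_summary(rec, ev, percent_of = NA)
  expect_equal(es$envelope_mean, c(A, A), tolerance = 0.01)
})

test_that("the actual-movement condition self-normalizes to 100 percent", {
  sess <- memoize("emg_recovery", tiny_session(1, seed = 31, profiles = {
    p <- default_condition_profiles(); p$isometric$emg_percent <- 0.8; p
  }))
  es <- emg_power_summary(sess$rec, sess$plan)
  expect_equal(es$percent[es$condition == "actual"], 100)
  ## magnitude statistic: percentages are sqrt-compressed relative to power
  esm <- emg_power_summary(sess$rec, sess$plan, statistic = "magnitude")
  expect_equal(esm$percent[esm$condition == "actual"], 100)
  iso_p <- es$percent[es$condition == "isometric"]
  iso_m <- esm$percent[esm$condition == "isometric"]
  expect_equal(iso_m^2 / 100, iso_p, tolerance = 1e-9)
})

test_that("percent computation without the reference condition errors", {
  sess <- memoize("p2_default", tiny_session(2, seed = 11))
  expect_error(emg_power_summary(sess$rec, sess$plan), "actual")
  ## but an external reference level works (cross-phase normalization)
  es <- emg_power_summary(sess$rec, sess$plan, reference_level = 50)
  expect_true("percent" %in% names(es))
})

test_that("exactly two EMG channels are required", {
  data <- matrix(0, 2, 100, dimnames = list(c("C3", "C4"), NULL))
  rec <- structure(list(data = data, sample_rate_hz = FIXTURE_FS,
                        channel_labels = rownames(data),
                        channel_kinds = c("EEG", "EEG"), start_time = 0),
                   class = "raw_recording")
  expect_error(emg_power_summary(rec, data.frame(onset_s = 0.1, duration_s = 0.1,
                                                 condition = "actual")),
               "2 EMG channels")
})
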