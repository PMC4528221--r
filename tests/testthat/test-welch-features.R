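test_that("the 8-24 Hz band at 4 Hz resolution keeps exactly 5 bins", {
  x <- brainswitch:::with_seed(1, rnorm(3 * FIXTURE_FS))
  p <- welch_psd(x, FIXTURE_FS)
  expect_equal(attr(p, "freqs"), c(8, 12, 16, 20, 24))
  expect_equal(ncol(p), 5)
  expect_true(all(p >= 0))
})

test_that("Welch equals the average of single-window Hanning periodograms", {
  fs <- FIXTURE_FS
  x <- brainswitch:::with_seed(2, rnorm(3 * fs)) + sin(2 * pi * 12 * (0:(3 * fs - 1)) / fs)
  p <- welch_psd(x, fs)
  ## oracle: independent periodogram per 250 ms slice, 125 ms hop, averaged
  nwin <- fs / 4; hop <- nwin / 2
  starts <- seq(1, length(x) - nwin + 1, by = hop)
  expect_equal(length(starts), 23)  # (3000 - 250)/125 + 1 window count
  oracle <- rowMeans(vapply(starts, function(s) {
    pg <- periodogram_psd(x[s:(s + nwin - 1)], fs)
    pg$psd[pg$freq %in% c(8, 12, 16, 20, 24)]
  }, numeric(5)))
  expect_equal(drop(p), oracle, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a pure tone peaks in its own bin with the Hanning leakage pattern", {
  fs <- FIXTURE_FS
  x <- sin(2 * pi * 12 * (0:(3 * fs - 1)) / fs)
  p <- drop(welch_psd(x, fs))
  expect_equal(unname(which.max(p)), 2L)  # the 12 Hz bin
  ## bin-centered tone under a Hanning taper: adjacent bins hold half the
  ## amplitude (a quarter of the power; slightly more for the symmetric
  ## window), everything beyond the adjacent bins is negligible
  expect_equal(p[["8Hz"]] / p[["12Hz"]], 0.25, tolerance = 0.1)
  expect_lt(p[["20Hz"]] / p[["12Hz"]], 1e-3)
})

test_that("short segments and off-grid frequencies are rejected", {
  expect_error(welch_psd(rnorm(30), FIXTURE_FS), "shorter than one window")
  expect_error(welch_psd(rnorm(600), FIXTURE_FS, band = c(9, 25)), "bin grid")
})

test_that("white noise is flat across the retained bins", {
  fs <- FIXTURE_FS
  x <- brainswitch:::with_seed(3, rnorm(100 * fs))  # ~800 averaged windows
  p <- drop(welch_psd(x, fs))
  expect_lt(max(abs(p / mean(p) - 1)), 0.10)
})

test_that("feature layout follows (channel, frequency, window) with 10 per channel", {
  sess <- memoize("p2_default", tiny_session(2, seed = 11))
  ep <- extract_epochs(sess$rec, sess$plan)
  fm9 <- extract_features(ep, channels = motor_channels())
  expect_equal(dim(fm9$values), c(108, 90))
  expect_equal(nrow(fm9$meta), 90)
  expect_equal(fm9$meta$channel[1:10], rep("C3", 10))
  expect_equal(fm9$meta$freq_hz[1:4], c(8, 8, 12, 12))
  expect_equal(fm9$meta$window[1:2], c("ERD", "ERS"))
  fm30 <- extract_features(ep)
  expect_equal(ncol(fm30$values), 300)
  expect_error(extract_features(ep, channels = c("C3", "QQ1")), "QQ1")
})

test_that("features are trial-permutation equivariant and scale as power", {
  data <- array(rnorm(6 * 2 * 7 * 100), dim = c(6, 2, 700))
  ep <- epochs_from_array(data, 100, labels = rep(c("a", "b"), 3),
                          channels = c("C3", "C4"))
  fm <- extract_features(ep, log10_transform = FALSE)
  perm <- c(4, 1, 6, 2, 3, 5)
  ep_p <- subset_epochs(ep, perm)
  fm_p <- extract_features(ep_p, log10_transform = FALSE)
  expect_equal(fm_p$values, fm$values[perm, ], tolerance = 1e-12)
  expect_equal(fm_p$labels, fm$labels[perm])
  ## doubling amplitude quadruples power
  ep2 <- ep; ep2$data <- ep$data * 2
  fm2 <- extract_features(ep2, log10_transform = FALSE)
  expect_equal(fm2$values, 4 * fm$values, tolerance = 1e-10)
  ## log transform is elementwise log10
  fml <- extract_features(ep, log10_transform = TRUE)
  expect_equal(fml$values, log10(fm$values), tolerance = 1e-12)
})

test_that("time-frequency maps are relative-baseline with unit time mean", {
  ## 54 trials: the phase-2 per-condition design count; per-frame relative
  ## sd of mean-of-54 exponential periodogram values is ~1/sqrt(54) = 0.14
  data <- brainswitch:::with_seed(8,
    array(rnorm(54 * 2 * 7 * FIXTURE_FS), dim = c(54, 2, 7 * FIXTURE_FS)))
  ep <- epochs_from_array(data, FIXTURE_FS, labels = rep("none", 54),
                          channels = c("C3", "C4"))
  tf <- tf_map(ep, "none")
  ## per channel-frequency the baseline mean is 1 by construction
  expect_equal(max(abs(apply(tf$values, c(1, 2), mean) - 1)), 0, tolerance = 1e-9)
  ## stationary noise: no time structure beyond sampling error (~4 sd max)
  expect_lt(max(abs(tf$values - 1)), 4.5 / sqrt(54))
  expect_lt(mean(abs(tf$values - 1)), 2 / sqrt(54))
  ## relative units: invariant to amplitude scaling
  ep2 <- ep; ep2$data <- ep$data * 3
  expect_equal(tf_map(ep2, "none")$values, tf$values, tolerance = 1e-12)
  expect_error(tf_map(ep, "attempted"), "no trials")
})

test_that("synthetic movement trials show ERD then ERS at C3 in the map", {
  sess <- memoize("p2_default", tiny_session(2, seed = 11))
  ep <- linear_detrend(extract_epochs(sess$rec, sess$plan))
  tf <- tf_map(ep, "attempted")
  c3 <- which(tf$channel_labels == "C3")
  mu <- which(tf$freqs %in% c(8, 12))
  erd <- mean(tf$values[c3, mu, tf$times > 0.2 & tf$times < 2.8])
  ers <- mean(tf$values[c3, mu, tf$times > 3.7 & tf$times < 5.8])
  expect_lt(erd, 1)
  expect_gt(ers, 1)
})
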