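test_that("default profiles encode the study's effect structure", {
  pr <- default_condition_profiles()
  expect_equal(pr$none$erd_depth, 0)
  expect_equal(pr$actual$emg_percent, 100)
  expect_lt(pr$imagined$erd_depth, pr$attempted$erd_depth)
  expect_true(all(vapply(pr, function(p) p$erd_depth >= 0 && p$erd_depth <= 1, logical(1))))
})

test_that("profile validation rejects out-of-range effects", {
  expect_error(condition_profile(erd_depth = 1.5), "erd_depth")
  expect_error(condition_profile(emg_percent = -1), "emg_percent")
  expect_error(synthetic_config(sample_rate_hz = 30), "twice the beta")
})

test_that("generation is bit-reproducible from the seed", {
  plan <- build_session_plan(2, 3, sample_rate_hz = FIXTURE_FS)
  cfg <- synthetic_config(sample_rate_hz = FIXTURE_FS, seed = 9)
  r1 <- generate_recording(plan, cfg)
  r2 <- generate_recording(plan, cfg)
  expect_identical(r1$data, r2$data)
  cfg2 <- synthetic_config(sample_rate_hz = FIXTURE_FS, seed = 10)
  expect_false(identical(generate_recording(plan, cfg2)$data, r1$data))
})

test_that("sample-rate mismatch and missing profiles are rejected", {
  plan <- build_session_plan(2, 3, sample_rate_hz = 250)
  cfg <- synthetic_config(sample_rate_hz = FIXTURE_FS, seed = 9)
  expect_error(generate_recording(plan, cfg), "sample rates")
  plan2 <- build_session_plan(2, 3, sample_rate_hz = FIXTURE_FS)
  cfg2 <- synthetic_config(profiles = list(none = condition_profile()),
                           sample_rate_hz = FIXTURE_FS)
  expect_error(generate_recording(plan2, cfg2), "attempted")
})

test_that("null profiles leave the rhythm envelope flat", {
  plan <- build_session_plan(2, 3, sample_rate_hz = FIXTURE_FS)
  env <- brainswitch:::rhythm_envelope(plan, null_condition_profiles(),
                                       round(attr(plan, "duration_s") * FIXTURE_FS),
                                       FIXTURE_FS, 0.2)
  expect_equal(range(env), c(1, 1))
})

test_that("ERD depth 0.5 quarters the cue-window mu power at the focal channel", {
  ## pure oscillator (no background): amplitude scaling (1 - 0.5) means
  ## power scaling 0.25, measured through the Welch stage
  sess <- memoize("pure_oscillator", tiny_session(2, seed = 21, noise_scale = 0))
  ep <- extract_epochs(sess$rec, sess$plan)
  fm <- extract_features(ep, channels = "C3", log10_transform = FALSE)
  mu <- fm$values[, fm$meta$freq_hz %in% c(8, 12) & fm$meta$window == "ERD"]
  ratio <- mean(rowSums(mu[fm$labels == "attempted", ])) /
    mean(rowSums(mu[fm$labels == "none", ]))
  expect_gt(ratio, 0.25 * 0.8)
  expect_lt(ratio, 0.25 * 1.2)
})

test_that("EMG envelope-power percentages recover the configured levels", {
  ## per-condition EMG percentage structure: one condition at 0.8% of actual
  profiles <- default_condition_profiles()
  profiles$isometric$emg_percent <- 0.8
  sess <- memoize("emg_recovery", tiny_session(1, seed = 31, profiles = profiles))
  es <- emg_power_summary(sess$rec, sess$plan)
  expect_equal(es$percent[es$condition == "actual"], 100)
  iso <- es$percent[es$condition == "isometric"]
  expect_gt(iso, 0.8 * 0.8)
  expect_lt(iso, 0.8 * 1.2)
  ## envelope-power ratio vs actual ~ 0.008
  expect_equal(iso / 100, 0.008, tolerance = 0.2)
})

test_that("recordings carry 30 EEG + 2 EMG channels with unique labels", {
  sess <- memoize("p2_default", tiny_session(2, seed = 11))
  expect_equal(sum(sess$rec$channel_kinds == "EEG"), 30)
  expect_equal(sum(sess$rec$channel_kinds == "EMG"), 2)
  expect_false(any(duplicated(sess$rec$channel_labels)))
  expect_false(any(is.na(sess$rec$data)))
})
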