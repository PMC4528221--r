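## End-to-end orchestration over synthetic subjects: simulate -> detrend ->
## surface Laplacian -> Welch ERD/ERS features -> rLLR classification ->
## confidence intervals, for within-condition cross-validation (per-subject accuracy
## tables), cross-condition transfer, and the sequential
## brain-switch detector.

#' Pipeline configuration
#'
#' @param n_subjects Number of synthetic subjects (default 4).
#' @param seed Top-level integer seed; every stage derives its own stream.
#' @param sample_rate_hz Simulation sampling rate (default 2500; analyses of
#'   rhythms below 40 Hz are unchanged at lower rates, which run much
#'   faster).
#' @param profiles Condition profiles for the generator.
#' @param channel_sets Subset of c("all30", "motor9").
#' @param conditions Movement conditions to analyze (each vs its phase's
#'   no-movement condition).
#' @param k Cross-validation folds (default 10).
#' @param selection Lambda-selection mode ("nested" or "flat").
#' @param noise_scale,rhythm_amp Generator amplitudes (uV).
#' @param spline Spline parameters for the Laplacian.
#' @param log10_features Log-transform band-power features (default TRUE).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_subjects = 4, seed = 1,
                            sample_rate_hz = 2500,
                            profiles = default_condition_profiles(),
                            channel_sets = c("all30", "motor9"),
                            conditions = c("actual", "isometric", "imagined", "attempted"),
                            k = 10, selection = "nested",
                            noise_scale = 10, rhythm_amp = 10,
                            spline = spline_params(),
                            log10_features = TRUE) {
  bad <- setdiff(channel_sets, c("all30", "motor9"))
  if (length(bad)) stop_invalid(sprintf("unknown channel set(s): %s", paste(bad, collapse = ", ")))
  bad <- setdiff(conditions, c("actual", "isometric", "imagined", "attempted"))
  if (length(bad)) stop_invalid(sprintf("unknown analysis condition(s): %s", paste(bad, collapse = ", ")))
  structure(list(n_subjects = n_subjects, seed = as.integer(seed),
                 sample_rate_hz = sample_rate_hz, profiles = profiles,
                 channel_sets = channel_sets, conditions = conditions,
                 k = k, selection = selection,
                 noise_scale = noise_scale, rhythm_amp = rhythm_amp,
                 spline = spline, log10_features = log10_features),
            class = "pipeline_config")
}

#' Channel labels of a named channel set
#' @param set "all30" or "motor9".
#' @return Character vector of labels.
#' @export
channel_set_labels <- function(set) {
  switch(set,
         all30 = default_eeg_labels(),
         motor9 = motor_channels(),
         stop_invalid(sprintf("unknown channel set '%s'", set)))
}

#' Preprocess a continuous recording into ERD/ERS features
#'
#' Epoch extraction, per-epoch linear detrending, spherical-spline surface
#' Laplacian over the full montage, then Welch band-power features on the
#' requested channel subset.
#'
#' @param rec A `raw_recording`.
#' @param events Events (`session_plan` or data.frame).
#' @param channels Channel subset for the features.
#' @param spline Spline parameters.
#' @param log10_transform Log-transform features.
#' @return A `feature_matrix`.
#' @export
preprocess_recording <- function(rec, events, channels = motor_channels(),
                                 spline = spline_params(),
                                 log10_transform = TRUE) {
  epochs <- extract_epochs(rec, events)
  epochs <- linear_detrend(epochs)
  epochs <- spherical_spline_laplacian(epochs, params = spline)
  extract_features(epochs, channels = channels, log10_transform = log10_transform)
}

## simulate one subject's session for one phase and return preprocessed
## epochs (detrended + Laplacian), the plan, and the raw recording if asked
simulate_subject_epochs <- function(config, subject, phase, keep_raw = FALSE) {
  seed_sp <- derive_seed(config$seed, sprintf("subject%d-phase%d", subject, phase))
  plan <- build_session_plan(phase, seed = seed_sp,
                             sample_rate_hz = config$sample_rate_hz)
  scfg <- synthetic_config(profiles = config$profiles,
                           sample_rate_hz = config$sample_rate_hz,
                           noise_scale = config$noise_scale,
                           rhythm_amp = config$rhythm_amp,
                           seed = derive_seed(seed_sp, "recording"))
  rec <- generate_recording(plan, scfg)
  epochs <- linear_detrend(extract_epochs(rec, plan))
  epochs <- spherical_spline_laplacian(epochs, params = config$spline)
  out <- list(plan = plan, epochs = epochs)
  if (keep_raw) out$rec <- rec
  out
}

## features per channel set from preprocessed epochs
features_per_set <- function(epochs, config) {
  stats::setNames(lapply(config$channel_sets, function(set) {
    extract_features(epochs, channels = channel_set_labels(set),
                     log10_transform = config$log10_features)
  }), config$channel_sets)
}

## rows of cond-vs-none trials as a feature matrix with levels (none, cond)
condition_subset <- function(fm, cond, none = "none") {
  idx <- which(fm$labels %in% c(cond, none))
  structure(list(values = fm$values[idx, , drop = FALSE],
                 meta = fm$meta,
                 labels = factor(fm$labels[idx], levels = c(none, cond))),
            class = "feature_matrix")
}

append_mean_rows <- function(df, by_cols) {
  groups <- unique(df[, by_cols, drop = FALSE])
  means <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- df
    for (cc in by_cols) sel <- sel[sel[[cc]] == groups[[cc]][i], ]
    out <- groups[i, , drop = FALSE]
    out$subject <- "mean"
    out$accuracy <- mean(sel$accuracy)
    if (nrow(sel) >= 2) {
      ci <- group_mean_ci(sel$accuracy)
      out$ci_lower <- ci$lower
      out$ci_upper <- ci$upper
    } else {
      out$ci_lower <- NA_real_
      out$ci_upper <- NA_real_
    }
    out$n_trials <- NA_integer_
    out
  })
  rbind(df, do.call(rbind, means)[, names(df)])
}

#' Within-condition cross-validated accuracy table
#'
#' For every synthetic subject, movement condition and channel set:
#' stratified ten-fold CV accuracy of condition-vs-no-movement, with its
#' binomial CI; group mean rows (subject = "mean") carry the t-based CI.
#'
#' @param config A [pipeline_config()].
#' @return A `results_table` data.frame: subject, condition, channel_set,
#'   accuracy, ci_lower, ci_upper, n_trials; attributes `seed` and
#'   `config_hash`.
#' @export
run_within_condition <- function(config) {
  rows <- list()
  phase1_conds <- intersect(config$conditions, c("actual", "isometric", "imagined"))
  for (s in seq_len(config$n_subjects)) {
    for (phase in c(if (length(phase1_conds)) 1, if ("attempted" %in% config$conditions) 2)) {
      sim <- simulate_subject_epochs(config, s, phase)
      fsets <- features_per_set(sim$epochs, config)
      conds <- if (phase == 1) phase1_conds else "attempted"
      for (cond in conds) {
        for (set in config$channel_sets) {
          fm <- condition_subset(fsets[[set]], cond)
          cv <- crossval_accuracy(fm, fm$labels, k = config$k,
                                  seed = derive_seed(config$seed,
                                                     sprintf("cv-s%d-%s-%s", s, cond, set)),
                                  selection = config$selection)
          n <- length(fm$labels)
          ci <- binomial_ci(round(cv$overall_accuracy * n), n)
          rows[[length(rows) + 1L]] <- data.frame(
            subject = as.character(s), condition = cond, channel_set = set,
            accuracy = ci$accuracy, ci_lower = ci$lower, ci_upper = ci$upper,
            n_trials = n, stringsAsFactors = FALSE)
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  df <- append_mean_rows(df, c("condition", "channel_set"))
  finalize_results(df, config)
}

#' Cross-condition transfer accuracy table
#'
#' Trains on each phase-1 movement condition (vs phase-1 no-movement) and
#' tests on attempted movement (vs phase-2 no-movement), per subject and
#' channel set.
#'
#' @param config A [pipeline_config()]; training conditions are the phase-1
#'   entries of `config$conditions`.
#' @return A `results_table` data.frame (subject, train_condition,
#'   channel_set, accuracy, ci_lower, ci_upper, n_trials) with mean rows.
#' @export
run_transfer <- function(config) {
  train_conds <- intersect(config$conditions, c("actual", "isometric", "imagined"))
  if (!length(train_conds)) stop_invalid("no phase-1 training conditions in config")
  rows <- list()
  for (s in seq_len(config$n_subjects)) {
    sim1 <- simulate_subject_epochs(config, s, 1)
    f1 <- features_per_set(sim1$epochs, config)
    rm(sim1)
    sim2 <- simulate_subject_epochs(config, s, 2)
    f2 <- features_per_set(sim2$epochs, config)
    rm(sim2)
    for (cond in train_conds) {
      for (set in config$channel_sets) {
        tr <- condition_subset(f1[[set]], cond)
        te <- condition_subset(f2[[set]], "attempted")
        res <- transfer_accuracy(tr, tr$labels, te, te$labels,
                                 seed = derive_seed(config$seed,
                                                    sprintf("tr-s%d-%s-%s", s, cond, set)))
        n <- length(te$labels)
        ci <- binomial_ci(round(res$accuracy * n), n)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = as.character(s), train_condition = cond, channel_set = set,
          accuracy = ci$accuracy, ci_lower = ci$lower, ci_upper = ci$upper,
          n_trials = n, stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  df <- append_mean_rows(df, c("train_condition", "channel_set"))
  finalize_results(df, config)
}

#' Brain-switch detector characterization over synthetic subjects
#'
#' Per subject: train on phase-1 actual-vs-none, score the phase-2 trials in
#' time order, combine `window_trials` consecutive scores, calibrate the
#' threshold for `target_fa` on half of the no-movement windows, and report
#' the held-out false-alarm and true-positive rates.
#'
#' @param config A [pipeline_config()].
#' @param window_trials Trials per detector window (default 8, about one
#'   minute at the 7 s trial pacing).
#' @param target_fa Target false-alarm percent (default 0).
#' @param channel_set Channel set for the detector (default "motor9").
#' @param train_condition Phase-1 training condition (default "actual").
#' @return A `results_table` data.frame: subject, false_alarm_rate,
#'   true_positive_rate, threshold, window_trials; plus a mean row.
#' @export
run_detector <- function(config, window_trials = 8, target_fa = 0,
                         channel_set = "motor9", train_condition = "actual") {
  rows <- list()
  for (s in seq_len(config$n_subjects)) {
    sim1 <- simulate_subject_epochs(config, s, 1)
    f1 <- extract_features(sim1$epochs, channels = channel_set_labels(channel_set),
                           log10_transform = config$log10_features)
    rm(sim1)
    sim2 <- simulate_subject_epochs(config, s, 2)
    f2 <- extract_features(sim2$epochs, channels = channel_set_labels(channel_set),
                           log10_transform = config$log10_features)
    rm(sim2)
    tr <- condition_subset(f1, train_condition)
    res <- transfer_accuracy(tr, tr$labels, f2, factor(f2$labels),
                             seed = derive_seed(config$seed, sprintf("det-s%d", s)))
    mv <- res$decision_values[f2$labels == "attempted"]
    nu <- res$decision_values[f2$labels == "none"]
    op <- detector_operating_point(mv, nu, window_trials, target_fa)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = as.character(s),
      false_alarm_rate = op$false_alarm_rate,
      true_positive_rate = op$true_positive_rate,
      threshold = op$threshold, window_trials = window_trials,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  mean_row <- data.frame(subject = "mean",
                         false_alarm_rate = mean(df$false_alarm_rate),
                         true_positive_rate = mean(df$true_positive_rate),
                         threshold = NA_real_, window_trials = window_trials,
                         stringsAsFactors = FALSE)
  finalize_results(rbind(df, mean_row), config)
}

## attach reproducibility metadata to a results table
finalize_results <- function(df, config) {
  rownames(df) <- NULL
  attr(df, "seed") <- config$seed
  attr(df, "config_hash") <- config_hash(config)
  attr(df, "package_version") <- as.character(utils::packageVersion("brainswitch"))
  class(df) <- c("results_table", "data.frame")
  df
}

#' Hash of a pipeline configuration
#' @param config Any serializable object.
#' @return MD5 hex string.
#' @export
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' Write a results table as JSON and TSV
#'
#' `<basepath>.json` carries the rows plus seed/config-hash/version
#' metadata; `<basepath>.tsv` the rows alone.
#'
#' @param df A `results_table`.
#' @param basepath Output path without extension.
#' @return The two paths, invisibly.
#' @export
write_results_report <- function(df, basepath) {
  payload <- list(seed = attr(df, "seed"),
                  config_hash = attr(df, "config_hash"),
                  package_version = attr(df, "package_version"),
                  rows = as.data.frame(df))
  jsonlite::write_json(payload, paste0(basepath, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.table(as.data.frame(df), paste0(basepath, ".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(json = paste0(basepath, ".json"), tsv = paste0(basepath, ".tsv")))
}

#' Detection of attempted movement on null-effect synthetic data
#'
#' Convenience wrapper for the chance-level check: generates a phase-2
#' session with zero-effect profiles and returns the cross-validated
#' accuracy of attempted-vs-none.
#'
#' @param seed Integer seed.
#' @param sample_rate_hz Simulation rate.
#' @param channels Feature channel subset (default motor 9).
#' @param k CV folds.
#' @param selection Lambda-selection mode.
#' @return The `cv_result`.
#' @export
null_pipeline_cv <- function(seed, sample_rate_hz = 200,
                             channels = motor_channels(), k = 10,
                             selection = "nested") {
  config <- pipeline_config(n_subjects = 1, seed = seed,
                            sample_rate_hz = sample_rate_hz,
                            profiles = null_condition_profiles(),
                            channel_sets = "motor9", conditions = "attempted",
                            k = k, selection = selection)
  sim <- simulate_subject_epochs(config, 1, 2)
  fm <- extract_features(sim$epochs, channels = channels)
  fm <- condition_subset(fm, "attempted")
  crossval_accuracy(fm, fm$labels, k = k,
                    seed = derive_seed(seed, "null-cv"), selection = selection)
}
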