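## Epoch extraction: cut [-1, 6) s windows (half-open) around cue onsets.
## The ERS feature window ends at 6 s and the next cue starts at 7 s, so
## windows never overlap the following trial.

#' Extract condition-labeled epochs around cue onsets
#'
#' Cuts the per-trial slice `[onset + tmin, onset + tmax)` (half-open) from
#' the EEG channels of a continuous recording.
#'
#' @param rec A `raw_recording`.
#' @param events A `session_plan` or event data.frame with `onset_s` and
#'   `condition`.
#' @param tmin,tmax Window relative to cue onset in seconds (defaults -1, 6).
#' @return An `epoch_set`: list with `data` (trials x channels x samples
#'   array), `times` (seconds relative to onset), `labels` (condition per
#'   trial), `sample_rate_hz`, `channel_labels`.
#' @export
extract_epochs <- function(rec, events, tmin = -1, tmax = 6) {
  if (tmax <= tmin) stop_invalid("`tmax` must exceed `tmin`")
  fs <- rec$sample_rate_hz
  eeg_idx <- which(rec$channel_kinds == "EEG")
  n_per <- round((tmax - tmin) * fs)
  n_total <- ncol(rec$data)
  n_trials <- nrow(events)

  data <- array(NA_real_, dim = c(n_trials, length(eeg_idx), n_per),
                dimnames = list(NULL, rec$channel_labels[eeg_idx], NULL))
  for (i in seq_len(n_trials)) {
    start <- round((events$onset_s[i] + tmin) * fs) + 1L
    stop_ <- start + n_per - 1L
    if (start < 1L || stop_ > n_total) {
      stop_invalid(sprintf(
        "epoch window [%g, %g) s for trial %d (onset %g s) exceeds the recording bounds",
        tmin, tmax, i, events$onset_s[i]))
    }
    data[i, , ] <- rec$data[eeg_idx, start:stop_]
  }
  structure(list(data = data,
                 times = tmin + (seq_len(n_per) - 1) / fs,
                 labels = events$condition,
                 sample_rate_hz = fs,
                 channel_labels = rec$channel_labels[eeg_idx]),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz, t in [%g, %g) s\n",
              d[1], d[2], d[3], x$sample_rate_hz, x$times[1],
              x$times[length(x$times)] + 1 / x$sample_rate_hz))
  tab <- table(x$labels)
  cat("  trials per condition:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Subset an epoch set by trials
#' @param epochs An `epoch_set`.
#' @param idx Trial indices.
#' @return An `epoch_set`.
#' @export
subset_epochs <- function(epochs, idx) {
  structure(list(data = epochs$data[idx, , , drop = FALSE],
                 times = epochs$times,
                 labels = epochs$labels[idx],
                 sample_rate_hz = epochs$sample_rate_hz,
                 channel_labels = epochs$channel_labels),
            class = "epoch_set")
}
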