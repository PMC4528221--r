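## EMG quantification: bipolar re-reference, 10 Hz high-pass, Hilbert
## envelope, per-trial mean over 0.1-3.5 s, per-condition mean, percent of
## the actual-movement condition.

#' Analytic-signal magnitude (Hilbert envelope)
#'
#' FFT implementation of the analytic signal; returns its modulus, the
#' instantaneous amplitude of a band-limited signal.
#'
#' @param x Numeric vector.
#' @return Envelope vector of the same length.
#' @export
hilbert_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Per-condition EMG power summary
#'
#' Bipolar difference of the two EMG channels, zero-phase 4th-order
#' Butterworth high-pass at `highpass_hz`, Hilbert envelope, per-trial mean
#' envelope over 0.1-3.5 s after cue onset, averaged per condition. When
#' `percent_of = "actual"` (the default), each condition's statistic is
#' expressed as a percentage of the actual-movement condition; percentages
#' are computed on squared envelope means (`statistic = "power"`) or on the
#' means themselves (`statistic = "magnitude"`).
#'
#' @param rec A `raw_recording` with exactly 2 EMG channels.
#' @param events Event data.frame (`onset_s`, `condition`).
#' @param percent_of Reference condition for percentages, or NA to return
#'   raw per-condition envelope means.
#' @param reference_level Optional externally supplied reference envelope
#'   mean (e.g. the actual-movement level from another recording); overrides
#'   `percent_of` lookup.
#' @param statistic "power" (squared envelope means; default) or "magnitude".
#' @param highpass_hz High-pass cutoff (default 10).
#' @param t_from,t_to Averaging window relative to onset (defaults 0.1, 3.5).
#' @return data.frame with `condition`, `envelope_mean`, `n_trials` and,
#'   when a reference is available, `percent`.
#' @export
emg_power_summary <- function(rec, events, percent_of = "actual",
                              reference_level = NULL,
                              statistic = c("power", "magnitude"),
                              highpass_hz = 10, t_from = 0.1, t_to = 3.5) {
  statistic <- match.arg(statistic)
  emg_idx <- which(rec$channel_kinds == "EMG")
  if (length(emg_idx) != 2L) stop_invalid("recording must have exactly 2 EMG channels")
  fs <- rec$sample_rate_hz
  bip <- rec$data[emg_idx[1], ] - rec$data[emg_idx[2], ]
  bf <- signal::butter(4, highpass_hz / (fs / 2), type = "high")
  filt <- signal::filtfilt(bf, bip)
  env <- hilbert_envelope(filt)

  trial_mean <- vapply(seq_len(nrow(events)), function(i) {
    a <- round((events$onset_s[i] + t_from) * fs) + 1L
    b <- round((events$onset_s[i] + t_to) * fs)
    mean(env[a:b])
  }, numeric(1))

  agg <- stats::aggregate(trial_mean, by = list(condition = events$condition), FUN = mean)
  names(agg)[2] <- "envelope_mean"
  agg$n_trials <- as.vector(table(events$condition)[agg$condition])

  ref <- reference_level
  if (is.null(ref) && !is.na(percent_of)) {
    if (!percent_of %in% agg$condition) {
      stop_invalid(sprintf("reference condition '%s' has no trials; supply `reference_level`",
                           percent_of))
    }
    ref <- agg$envelope_mean[agg$condition == percent_of]
  }
  if (!is.null(ref)) {
    agg$percent <- if (statistic == "power") {
      100 * (agg$envelope_mean / ref)^2
    } else {
      100 * agg$envelope_mean / ref
    }
  }
  agg
}
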