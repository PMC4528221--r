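## Welch band-power features. The pinned convention: 250 ms Hanning-tapered
## windows, 50% overlap (125 ms hop), modified periodograms averaged, PSD
## normalization 1 / (fs * sum(w^2)), one-sided doubling for interior bins.
## A 250 ms window gives a 4 Hz bin grid, so the 8-24 Hz band retains
## exactly the bins 8, 12, 16, 20, 24 Hz (5 frequencies).

## windowed periodogram matrix: for one channel vector x, returns
## n_windows x n_freq_bins of PSD values at bins `bins` (FFT bin indices,
## 1-based). Shared by welch_psd and tf_map.
windowed_psd <- function(x, w, hop, bins, fs, two_sided_correction) {
  nwin <- length(w)
  n <- length(x)
  starts <- seq(1, n - nwin + 1, by = hop)
  seg <- matrix(x[outer(seq_len(nwin) - 1L, starts, "+")], nrow = nwin)
  seg <- seg * w
  X <- stats::mvfft(seg)[bins, , drop = FALSE]
  p <- (Mod(X)^2) / (fs * sum(w^2)) * two_sided_correction
  t(p)                                      # windows x bins
}

#' Welch power spectral density over a fixed band
#'
#' Hanning-tapered windows of `win_s` seconds with `overlap` fractional
#' overlap; periodograms averaged; only bins at `seq(band[1], band[2], res)`
#' retained (endpoints inclusive).
#'
#' @param segment channels x samples matrix (or a vector for one channel).
#' @param fs Sampling rate, Hz.
#' @param win_s Window length in seconds (default 0.25). `win_s * fs` must
#'   be an integer number of samples and `1 / win_s` must resolve `res`.
#' @param overlap Fractional overlap (default 0.5).
#' @param band Frequency band in Hz, endpoints inclusive (default c(8, 24)).
#' @param res Frequency resolution in Hz (default 4).
#' @return channels x frequencies matrix of power (uV^2/Hz); frequency bin
#'   centers in `attr(, "freqs")`.
#' @export
welch_psd <- function(segment, fs, win_s = 0.25, overlap = 0.5,
                      band = c(8, 24), res = 4) {
  if (is.null(dim(segment))) segment <- matrix(segment, nrow = 1)
  nwin <- round(win_s * fs)
  if (abs(nwin - win_s * fs) > 1e-9) {
    stop_invalid("`win_s * fs` must be an integer number of samples")
  }
  if (ncol(segment) < nwin) {
    stop_invalid(sprintf("segment (%d samples) shorter than one window (%d samples)",
                         ncol(segment), nwin))
  }
  df <- 1 / win_s
  freqs <- seq(band[1], band[2], by = res)
  k <- freqs / df
  if (any(abs(k - round(k)) > 1e-9)) {
    stop_invalid("requested frequencies do not fall on the window's bin grid")
  }
  bins <- as.integer(round(k)) + 1L
  nyq_bin <- nwin / 2 + 1
  corr <- ifelse(bins == 1L | bins == nyq_bin, 1, 2)   # one-sided doubling
  w <- signal::hanning(nwin)
  hop <- round(nwin * (1 - overlap))
  out <- t(apply(segment, 1, function(x) {
    colMeans(windowed_psd(x, w, hop, bins, fs, corr))
  }))
  if (nrow(segment) == 1L) out <- matrix(out, nrow = 1)
  dimnames(out) <- list(rownames(segment), paste0(freqs, "Hz"))
  attr(out, "freqs") <- freqs
  out
}

#' ERD/ERS band-power feature matrix
#'
#' Per trial, Welch PSD of the 0-3 s slice (ERD window, during the cue) and
#' of the 3.5-6 s slice (ERS window, post-movement rebound), for the
#' requested channel subset. Columns are ordered (channel, frequency,
#' window), channel slowest. With the default 4 Hz resolution over 8-24 Hz
#' this is `n_channels * 5 * 2` features (90 for the 9-channel motor set).
#'
#' @param epochs An `epoch_set` spanning at least [0, 6] s.
#' @param channels Channel subset (default: all epoch channels).
#' @param band,res Welch band and resolution (defaults 8-24 Hz, 4 Hz).
#' @param log10_transform Log-transform the power features (default TRUE;
#'   improves classifier conditioning).
#' @return A `feature_matrix`: list with `values` (trials x features),
#'   `meta` (data.frame: channel, freq_hz, window), `labels` (condition per
#'   trial).
#' @export
extract_features <- function(epochs, channels = epochs$channel_labels,
                             band = c(8, 24), res = 4,
                             log10_transform = TRUE) {
  unknown <- setdiff(channels, epochs$channel_labels)
  if (length(unknown)) {
    stop_invalid(sprintf("unknown channel(s) in subset: %s", paste(unknown, collapse = ", ")))
  }
  if (epochs$times[1] > 0 || max(epochs$times) < 6 - 1.5 / epochs$sample_rate_hz) {
    stop_invalid("epochs must span at least [0, 6] s for ERD/ERS features")
  }
  fs <- epochs$sample_rate_hz
  ch_idx <- match(channels, epochs$channel_labels)
  erd_idx <- which(epochs$times >= 0 & epochs$times < 3)
  ers_idx <- which(epochs$times >= 3.5 & epochs$times < 6)
  n_trials <- dim(epochs$data)[1]

  one_trial <- function(i) {
    erd <- welch_psd(matrix(epochs$data[i, ch_idx, erd_idx], nrow = length(ch_idx)),
                     fs, band = band, res = res)
    ers <- welch_psd(matrix(epochs$data[i, ch_idx, ers_idx], nrow = length(ch_idx)),
                     fs, band = band, res = res)
    ## column order (channel, frequency, window): window varies fastest
    a <- array(0, dim = c(2, ncol(erd), nrow(erd)))
    a[1, , ] <- t(erd)
    a[2, , ] <- t(ers)
    as.vector(a)
  }
  freqs <- seq(band[1], band[2], by = res)
  meta <- data.frame(
    channel = rep(channels, each = length(freqs) * 2),
    freq_hz = rep(rep(freqs, each = 2), times = length(channels)),
    window = rep(c("ERD", "ERS"), times = length(freqs) * length(channels)),
    stringsAsFactors = FALSE
  )
  values <- t(vapply(seq_len(n_trials), one_trial, numeric(nrow(meta))))
  if (log10_transform) values <- log10(values)
  colnames(values) <- paste(meta$channel, paste0(meta$freq_hz, "Hz"), meta$window, sep = "_")
  structure(list(values = values, meta = meta, labels = epochs$labels),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d trials x %d features (%d channels x %d freqs x 2 windows)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$meta$channel)), length(unique(x$meta$freq_hz))))
  invisible(x)
}

#' Write a feature matrix as TSV
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_features_tsv <- function(fm, path) {
  df <- data.frame(condition = fm$labels, fm$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Relative-baseline time-frequency map for one condition
#'
#' Short-time Welch power (same windowing as the features, sliding with a
#' 125 ms hop across the whole epoch), averaged across the condition's
#' trials, then divided per channel-frequency by its mean over the whole
#' epoch (relative baseline over -1..6 s): 1 = average power, < 1 = ERD,
#' > 1 = ERS.
#'
#' @param epochs An `epoch_set`.
#' @param condition Condition whose trials to average.
#' @param band Frequency range (default c(4, 40); the 250 ms window's 4 Hz
#'   grid bounds the lowest resolvable bin).
#' @param res Frequency resolution (default 4 Hz).
#' @return A `tf_map`: list with `values` (channels x frequencies x frames),
#'   `freqs`, `times` (frame centers, s relative to onset), `condition`.
#' @export
tf_map <- function(epochs, condition, band = c(4, 40), res = 4) {
  idx <- which(epochs$labels == condition)
  if (!length(idx)) stop_invalid(sprintf("no trials of condition '%s'", condition))
  fs <- epochs$sample_rate_hz
  win_s <- 0.25
  nwin <- round(win_s * fs)
  w <- signal::hanning(nwin)
  hop <- round(nwin / 2)
  freqs <- seq(band[1], band[2], by = res)
  bins <- as.integer(round(freqs * win_s)) + 1L
  nyq_bin <- nwin / 2 + 1
  corr <- ifelse(bins == 1L | bins == nyq_bin, 1, 2)

  d <- dim(epochs$data)
  n_frames <- floor((d[3] - nwin) / hop) + 1
  acc <- array(0, dim = c(d[2], length(freqs), n_frames))
  for (i in idx) {
    for (ch in seq_len(d[2])) {
      acc[ch, , ] <- acc[ch, , ] +
        t(windowed_psd(epochs$data[i, ch, ], w, hop, bins, fs, corr))
    }
  }
  acc <- acc / length(idx)
  base <- apply(acc, c(1, 2), mean)
  vals <- sweep(acc, c(1, 2), base, "/")
  starts <- seq(1, d[3] - nwin + 1, by = hop)
  structure(list(values = vals, freqs = freqs,
                 times = epochs$times[starts] + win_s / 2,
                 channel_labels = epochs$channel_labels,
                 condition = condition),
            class = "tf_map")
}
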