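## Sequential brain-switch detector: combine consecutive per-trial decision
## values into windowed scores, calibrate a detection threshold for a target
## false-alarm rate on null (no-movement) windows, and characterize the
## false-alarm / true-positive trade-off.

#' Combine consecutive per-trial decision values into windowed scores
#'
#' Sliding window of `window_trials` consecutive values, stride 1; the
#' combined score is their mean (default) or the majority of their signs.
#' With the study's 7 s trial pacing, 8 trials is roughly one minute of
#' data.
#'
#' @param decision_values Ordered per-trial classifier scores.
#' @param window_trials Window length in trials (default 8).
#' @param combine "mean" (default) or "vote".
#' @return Numeric vector of windowed scores, length
#'   `length(decision_values) - window_trials + 1`.
#' @export
accumulate_decisions <- function(decision_values, window_trials = 8,
                                 combine = c("mean", "vote")) {
  combine <- match.arg(combine)
  n <- length(decision_values)
  if (window_trials < 1) stop_invalid("`window_trials` must be >= 1")
  if (window_trials > n) {
    stop_invalid(sprintf("window of %d trials exceeds the %d available values",
                         window_trials, n))
  }
  x <- if (combine == "vote") sign(decision_values) else decision_values
  if (window_trials == 1) return(x)
  cs <- cumsum(c(0, x))
  (cs[(window_trials + 1):(n + 1)] - cs[1:(n - window_trials + 1)]) / window_trials
}

#' Calibrate the detection threshold for a target false-alarm rate
#'
#' Smallest threshold such that the fraction of null (no-movement) windowed
#' scores exceeding it is at most `target_fa` percent. For `target_fa = 0`
#' the threshold is the observed null maximum plus a small epsilon, so the
#' empirical false-alarm rate on the calibration set is exactly zero.
#'
#' @param null_scores Windowed scores from no-movement data (>= 20).
#' @param target_fa Target false-alarm rate in percent (default 0).
#' @return Threshold (scores strictly above it raise the alarm).
#' @export
calibrate_threshold <- function(null_scores, target_fa = 0) {
  if (length(null_scores) < 20) stop_invalid("need at least 20 null windows to calibrate")
  check_number(target_fa, "target_fa", nonneg = TRUE)
  if (target_fa <= 0) {
    scale <- max(abs(null_scores), 1e-12)
    return(max(null_scores) + 1e-9 * scale)
  }
  ## smallest threshold with FA <= target: the appropriate order statistic
  s <- sort(null_scores, decreasing = TRUE)
  n_allow <- floor(length(s) * target_fa / 100)
  if (n_allow == 0) return(max(null_scores) + 1e-9 * max(abs(null_scores), 1e-12))
  s[n_allow + 1]
}

#' Characterize the detector over a configuration grid
#'
#' For each `window_trials` and each threshold, the false-alarm rate on the
#' null windows and the true-positive rate on the movement windows. When
#' `thresholds` is NULL, each window size uses the full set of its observed
#' windowed scores as candidate thresholds, tracing the trade-off curve.
#'
#' @param movement_scores Ordered per-trial decision values from movement
#'   trials.
#' @param null_scores Ordered per-trial decision values from no-movement
#'   trials.
#' @param window_trials Vector of window sizes (default 8).
#' @param thresholds Optional explicit thresholds.
#' @param combine Combination rule, see [accumulate_decisions()].
#' @return A `detector_report` data.frame: window_trials, threshold,
#'   false_alarm_rate, true_positive_rate (rates in percent).
#' @export
characterize_detector <- function(movement_scores, null_scores,
                                  window_trials = 8, thresholds = NULL,
                                  combine = "mean") {
  if (!length(movement_scores) || !length(null_scores)) {
    stop_invalid("both score sets must be nonempty")
  }
  rows <- list()
  for (wt in window_trials) {
    mv <- accumulate_decisions(movement_scores, wt, combine)
    nu <- accumulate_decisions(null_scores, wt, combine)
    th <- if (is.null(thresholds)) sort(unique(c(mv, nu))) else thresholds
    for (t_ in th) {
      rows[[length(rows) + 1L]] <- data.frame(
        window_trials = wt, threshold = t_,
        false_alarm_rate = 100 * mean(nu > t_),
        true_positive_rate = 100 * mean(mv > t_))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("detector_report", "data.frame")
  out
}

#' Evaluate the detector at a calibrated zero-false-alarm operating point
#'
#' Splits the null windows into disjoint calibration and evaluation halves,
#' calibrates the threshold on the first half, and reports the false-alarm
#' rate on the held-out half and the true-positive rate on the movement
#' windows.
#'
#' @param movement_scores,null_scores Ordered per-trial decision values.
#' @param window_trials Window size (default 8).
#' @param target_fa Target false-alarm percent (default 0).
#' @param combine Combination rule.
#' @return List: threshold, false_alarm_rate, true_positive_rate,
#'   window_trials (rates in percent; FA on held-out null windows).
#' @export
detector_operating_point <- function(movement_scores, null_scores,
                                     window_trials = 8, target_fa = 0,
                                     combine = "mean") {
  nu <- accumulate_decisions(null_scores, window_trials, combine)
  mv <- accumulate_decisions(movement_scores, window_trials, combine)
  half <- floor(length(nu) / 2)
  cal <- nu[seq_len(half)]
  eval_ <- nu[(half + 1):length(nu)]
  th <- calibrate_threshold(cal, target_fa)
  list(threshold = th,
       false_alarm_rate = 100 * mean(eval_ > th),
       true_positive_rate = 100 * mean(mv > th),
       window_trials = window_trials)
}
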