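## Synthetic EEG/EMG generator. Emulates the signal structure the analysis
## assumes: 1/f Gaussian background per channel, left-lateralized mu and beta
## rhythm sources whose amplitude drops during each cue (ERD) and rebounds
## 3.5-6 s after cue onset (ERS), and a bipolar EMG pair carrying >20 Hz
## noise bursts during cues with condition-dependent power.

#' Condition effect profile
#'
#' @param erd_depth Fractional amplitude reduction of the mu/beta rhythm
#'   during the cue (0 = no effect, 1 = complete suppression).
#' @param ers_gain Fractional amplitude increase during the post-movement
#'   rebound window (3.5-6 s after cue onset).
#' @param emg_percent EMG power during the cue as a percentage of the
#'   actual-movement condition's EMG power.
#' @return A `condition_profile` list.
#' @export
condition_profile <- function(erd_depth = 0, ers_gain = 0, emg_percent = 0.5) {
  check_number(erd_depth, "erd_depth", nonneg = TRUE)
  if (erd_depth > 1) stop_invalid("`erd_depth` must be in [0, 1]")
  check_number(ers_gain, "ers_gain", nonneg = TRUE)
  check_number(emg_percent, "emg_percent", nonneg = TRUE)
  structure(list(erd_depth = erd_depth, ers_gain = ers_gain,
                 emg_percent = emg_percent),
            class = "condition_profile")
}

#' Default condition profiles
#'
#' Effect sizes chosen to match the study's qualitative structure: executed,
#' isometric and attempted movement carry a strong ERD with a clear rebound;
#' imagery a weaker one; no-movement none. EMG percentages follow the
#' reported per-condition levels (actual 100, other conditions around or
#' below 1 percent of actual).
#'
#' @return Named list mapping every condition (both phases) to a
#'   [condition_profile()].
#' @export
default_condition_profiles <- function() {
  list(
    actual    = condition_profile(erd_depth = 0.5,  ers_gain = 0.4,  emg_percent = 100),
    isometric = condition_profile(erd_depth = 0.5,  ers_gain = 0.4,  emg_percent = 1.2),
    imagined  = condition_profile(erd_depth = 0.25, ers_gain = 0.15, emg_percent = 0.5),
    attempted = condition_profile(erd_depth = 0.5,  ers_gain = 0.4,  emg_percent = 1.0),
    none      = condition_profile(erd_depth = 0,    ers_gain = 0,    emg_percent = 0.5)
  )
}

#' Null condition profiles (no condition effect anywhere)
#'
#' Zero ERD/ERS for every condition and identical EMG levels, so labels are
#' independent of the signal; used for chance-level verification.
#' @return Named list of [condition_profile()]s.
#' @export
null_condition_profiles <- function() {
  conds <- c("actual", "isometric", "imagined", "attempted", "none")
  stats::setNames(lapply(conds, function(c.) condition_profile(0, 0, 1)), conds)
}

#' Synthetic recording configuration
#'
#' @param profiles Named list of [condition_profile()]s keyed by condition.
#' @param sample_rate_hz Sampling rate in Hz (default 2500, the acquisition
#'   rate of the emulated system).
#' @param noise_scale RMS amplitude of the 1/f background per channel, in uV.
#' @param rhythm_amp RMS amplitude of each rhythm source at its focal
#'   channel, in uV. `rhythm_amp / noise_scale` sets the rhythm SNR.
#' @param mu_hz,beta_hz Rhythm center frequencies (defaults 10 and 20 Hz).
#' @param rhythm_bw_hz Bandwidth of the narrowband rhythm sources (default 2).
#' @param focal_channel Channel where the rhythm topography peaks (default
#'   C3: right-hand task, contralateral cortex).
#' @param mirror_gain Relative topography amplitude at the mirrored site
#'   (default 0.25 at C4).
#' @param topo_sigma_rad Angular width (radians) of the Gaussian topography.
#' @param ramp_s Raised-cosine ERD/ERS transition time (default 0.2 s).
#' @param emg_amp RMS amplitude (uV) of the actual-movement EMG burst.
#' @param emg_noise RMS of the EMG sensor noise floor (uV).
#' @param seed Integer seed; the recording is bit-reproducible from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(profiles = default_condition_profiles(),
                             sample_rate_hz = 2500,
                             noise_scale = 10, rhythm_amp = 10,
                             mu_hz = 10, beta_hz = 20, rhythm_bw_hz = 2,
                             focal_channel = "C3", mirror_gain = 0.25,
                             topo_sigma_rad = 0.45,
                             ramp_s = 0.2,
                             emg_amp = 50, emg_noise = 0.05,
                             seed = 1) {
  check_number(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  if (sample_rate_hz <= 2 * beta_hz) {
    stop_invalid("`sample_rate_hz` must exceed twice the beta frequency")
  }
  check_number(noise_scale, "noise_scale", nonneg = TRUE)
  check_number(rhythm_amp, "rhythm_amp", nonneg = TRUE)
  check_number(emg_amp, "emg_amp", nonneg = TRUE)
  structure(list(profiles = profiles, sample_rate_hz = sample_rate_hz,
                 noise_scale = noise_scale, rhythm_amp = rhythm_amp,
                 mu_hz = mu_hz, beta_hz = beta_hz, rhythm_bw_hz = rhythm_bw_hz,
                 focal_channel = focal_channel, mirror_gain = mirror_gain,
                 topo_sigma_rad = topo_sigma_rad, ramp_s = ramp_s,
                 emg_amp = emg_amp, emg_noise = emg_noise,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

## 1/f ("pink") Gaussian noise, unit RMS. White noise shaped by the
## classic 3-pole/3-zero pink approximation (-3 dB/octave over the usable
## band), an O(n) recursive filter.
pink_noise <- function(n, fs) {
  b <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
  a <- c(2.494956002, -2.017265875, 0.522189400)   # recursive part, negated
  x <- stats::rnorm(n + 2000)
  xb <- as.numeric(stats::filter(x, b, sides = 1))
  xb[seq_len(length(b) - 1)] <- 0                  # one-sided convolution edge
  y <- as.numeric(stats::filter(xb, a, method = "recursive"))
  y <- y[-seq_len(2000)]                           # drop the filter transient
  y / stats::sd(y)
}

## Band-limited Gaussian noise (flat in [lo, hi]), unit RMS.
band_noise <- function(n, fs, lo, hi) {
  m <- stats::nextn(n, c(2, 3, 5))
  x <- stats::rnorm(m)
  X <- stats::fft(x)
  f <- seq(0, m - 1) / m * fs
  f <- pmin(f, fs - f)
  keep <- f >= lo & f <= hi
  y <- Re(stats::fft(X * keep, inverse = TRUE)) / m
  y <- y[seq_len(n)]
  y / stats::sd(y)
}

## Smooth 0->1->0 bump over [a, b] with raised-cosine edges of length r.
raised_cosine_bump <- function(t, a, b, r) {
  out <- numeric(length(t))
  up <- t >= a & t < a + r
  out[up] <- 0.5 * (1 - cos(pi * (t[up] - a) / r))
  flat <- t >= a + r & t <= b - r
  out[flat] <- 1
  down <- t > b - r & t <= b
  out[down] <- 0.5 * (1 - cos(pi * (b - t[down]) / r))
  out
}

## Rhythm amplitude envelope over the whole recording: 1 at rest,
## (1 - erd_depth) during cues, (1 + ers_gain) in the rebound window.
rhythm_envelope <- function(plan, profiles, n, fs, ramp_s) {
  env <- rep(1, n)
  for (i in seq_len(nrow(plan))) {
    pr <- profiles[[plan$condition[i]]]
    on <- plan$onset_s[i]
    idx <- max(1, floor((on - ramp_s) * fs)):min(n, ceiling((on + 6 + ramp_s) * fs) + 1)
    ti <- (idx - 1) / fs
    erd <- raised_cosine_bump(ti, on - ramp_s / 2, on + plan$duration_s[i] + ramp_s / 2, ramp_s)
    ers <- raised_cosine_bump(ti, on + 3.5 - ramp_s / 2, on + 6 + ramp_s / 2, ramp_s)
    env[idx] <- env[idx] + (-pr$erd_depth) * erd + pr$ers_gain * ers
  }
  env
}

## EMG burst envelope: per-cue amplitude factor sqrt(emg_percent / 100).
emg_envelope <- function(plan, profiles, n, fs, ramp_s) {
  env <- numeric(n)
  for (i in seq_len(nrow(plan))) {
    pr <- profiles[[plan$condition[i]]]
    amp <- sqrt(pr$emg_percent / 100)
    on <- plan$onset_s[i]
    idx <- max(1, floor((on - ramp_s) * fs)):min(n, ceiling((on + plan$duration_s[i] + ramp_s) * fs) + 1)
    ti <- (idx - 1) / fs
    env[idx] <- env[idx] + amp *
      raised_cosine_bump(ti, on - ramp_s / 2, on + plan$duration_s[i] + ramp_s / 2, ramp_s)
  }
  env
}

#' Generate a continuous synthetic recording for a session plan
#'
#' EEG channels are 1/f background plus amplitude-modulated narrowband mu and
#' beta sources projected through a smooth topography peaking at the focal
#' channel (weakly mirrored contralaterally). During each cue of condition c
#' the source amplitude is scaled by `1 - erd_depth(c)` for 0-3 s and by
#' `1 + ers_gain(c)` for 3.5-6 s after onset, with raised-cosine transitions.
#' EMG channels carry band-limited (>20 Hz) noise bursts during cues, scaled
#' so squared-envelope power is `emg_percent(c)` percent of the
#' actual-movement level. Bit-reproducible from `config$seed`.
#'
#' @param plan A [build_session_plan()] plan.
#' @param config A [synthetic_config()]; sampling rates must agree.
#' @return A `raw_recording`: list with `data` (channels x samples matrix,
#'   uV), `sample_rate_hz`, `channel_labels`, `channel_kinds`.
#' @export
generate_recording <- function(plan, config) {
  fs <- config$sample_rate_hz
  if (!isTRUE(all.equal(fs, attr(plan, "sample_rate_hz")))) {
    stop_invalid("plan and config sample rates disagree")
  }
  missing_prof <- setdiff(unique(plan$condition), names(config$profiles))
  if (length(missing_prof)) {
    stop_invalid(sprintf("no condition profile for: %s", paste(missing_prof, collapse = ", ")))
  }
  labels <- attr(plan, "channel_labels")
  kinds <- ifelse(grepl("^EMG", labels), "EMG", "EEG")
  eeg <- labels[kinds == "EEG"]
  emg <- labels[kinds == "EMG"]
  if (length(emg) != 2L) stop_invalid("expected exactly 2 EMG channels in the plan labels")
  duration <- attr(plan, "duration_s")
  if (max(plan$onset_s) + 6 > duration) {
    stop_invalid("plan events extend beyond the recording duration")
  }
  n <- round(duration * fs)

  mont <- standard_montage(eeg)
  gain <- exp(-montage_angles_to(mont, config$focal_channel)^2 /
                (2 * config$topo_sigma_rad^2))
  mirror <- sub("3$", "4", config$focal_channel)
  if (mirror != config$focal_channel && mirror %in% eeg && config$mirror_gain > 0) {
    gain <- gain + config$mirror_gain *
      exp(-montage_angles_to(mont, mirror)^2 / (2 * config$topo_sigma_rad^2))
  }

  with_seed(config$seed, {
    data <- matrix(0, nrow = length(labels), ncol = n,
                   dimnames = list(labels, NULL))
    for (ch in seq_along(eeg)) {
      data[eeg[ch], ] <- config$noise_scale * pink_noise(n, fs)
    }
    env <- rhythm_envelope(plan, config$profiles, n, fs, config$ramp_s)
    bw <- config$rhythm_bw_hz / 2
    mu <- band_noise(n, fs, config$mu_hz - bw, config$mu_hz + bw)
    beta <- band_noise(n, fs, config$beta_hz - bw, config$beta_hz + bw)
    src <- config$rhythm_amp * env * (mu + beta)
    data[eeg, ] <- data[eeg, ] + outer(drop(gain), src)

    benv <- emg_envelope(plan, config$profiles, n, fs, config$ramp_s)
    hi <- min(0.45 * fs, 250)
    burst <- config$emg_amp * benv * band_noise(n, fs, 20, hi)
    data[emg[1], ] <- burst / 2 + config$emg_noise * stats::rnorm(n)
    data[emg[2], ] <- -burst / 2 + config$emg_noise * stats::rnorm(n)

    structure(list(data = data, sample_rate_hz = fs,
                   channel_labels = labels, channel_kinds = kinds,
                   start_time = 0),
              class = "raw_recording")
  })
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels (%d EEG, %d EMG) x %d samples @ %g Hz (%.0f s)\n",
              nrow(x$data), sum(x$channel_kinds == "EEG"),
              sum(x$channel_kinds == "EMG"), ncol(x$data),
              x$sample_rate_hz, ncol(x$data) / x$sample_rate_hz))
  invisible(x)
}
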