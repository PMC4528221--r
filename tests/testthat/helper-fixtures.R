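## Shared fixtures and independent oracles. Everything is generated in code
## at test time; heavy synthetic-session runs are computed once per session
## and memoized so several test files can share them.

FIXTURE_FS <- 200  # Hz; preserves the 4 Hz Welch bin grid (250 ms = 50 samples)

fixture_cache <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

## small raw recording + plan: a couple of sequences, quick to generate
tiny_session <- function(phase = 2, seed = 11, profiles = default_condition_profiles(),
                         noise_scale = 10, rhythm_amp = 10) {
  plan <- build_session_plan(phase, seed, sample_rate_hz = FIXTURE_FS)
  cfg <- synthetic_config(profiles = profiles, sample_rate_hz = FIXTURE_FS,
                          noise_scale = noise_scale, rhythm_amp = rhythm_amp,
                          seed = derive_seed(seed, "rec"))
  list(plan = plan, rec = generate_recording(plan, cfg))
}

## epoch_set built directly from an array (no simulation)
epochs_from_array <- function(data, fs = FIXTURE_FS, tmin = -1,
                              labels = rep("none", dim(data)[1]),
                              channels = NULL) {
  if (is.null(channels)) channels <- default_eeg_labels()[seq_len(dim(data)[2])]
  dimnames(data) <- list(NULL, channels, NULL)
  structure(list(data = data,
                 times = tmin + (seq_len(dim(data)[3]) - 1) / fs,
                 labels = labels, sample_rate_hz = fs,
                 channel_labels = channels),
            class = "epoch_set")
}

## Gaussian two-class feature clouds with a mean shift on the first
## `n_informative` features
gaussian_features <- function(n_per_class, n_features, shift, seed,
                              n_informative = n_features) {
  brainswitch:::with_seed(seed, {
    x0 <- matrix(rnorm(n_per_class * n_features), n_per_class)
    x1 <- matrix(rnorm(n_per_class * n_features), n_per_class)
    x1[, seq_len(n_informative)] <- x1[, seq_len(n_informative)] + shift
    list(x = rbind(x0, x1),
         y = factor(rep(c("none", "move"), each = n_per_class),
                    levels = c("none", "move")))
  })
}

## ---- independent oracles -------------------------------------------------

## numerical surface Laplacian of a scalar field on the unit sphere at a
## point: second differences along two orthogonal tangent directions with
## great-circle steps (points re-projected onto the sphere)
numeric_surface_laplacian <- function(f, p, eps = 1e-3) {
  p <- p / sqrt(sum(p^2))
  seed_dir <- if (abs(p[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- seed_dir - sum(seed_dir * p) * p
  u <- u / sqrt(sum(u^2))
  v <- c(p[2] * u[3] - p[3] * u[2], p[3] * u[1] - p[1] * u[3], p[1] * u[2] - p[2] * u[1])
  move <- function(d) {
    q <- cos(eps) * p + sin(eps) * d
    q / sqrt(sum(q^2))
  }
  (f(move(u)) + f(move(-u)) + f(move(v)) + f(move(-v)) - 4 * f(p)) / eps^2
}

## single-window Hanning-tapered periodogram (PSD scaling), the oracle for
## the Welch stage
periodogram_psd <- function(x, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  X <- fft(x * w)
  p <- Mod(X)^2 / (fs * sum(w^2))
  k <- seq_len(floor(n / 2) + 1)
  corr <- rep(2, length(k)); corr[1] <- 1
  if (n %% 2 == 0) corr[length(k)] <- 1
  list(freq = (k - 1) * fs / n, psd = p[k] * corr)
}

## central-difference gradient of the penalized logistic loss
numeric_rllr_gradient <- function(par, X, y, lambda, h = 1e-6) {
  f <- function(p_) brainswitch:::rllr_objective(p_, X, y, lambda)
  vapply(seq_along(par), function(j) {
    e <- numeric(length(par)); e[j] <- h
    (f(par + e) - f(par - e)) / (2 * h)
  }, numeric(1))
}

## ---- memoized heavy runs -------------------------------------------------

## strong-ERD study-condition runs shared by the effect-recovery and
## detector acceptance checks: per seed, within-condition CV for
## attempted-vs-none (both channel sets) and actual->attempted transfer
## (both sets, with per-trial decision values for the detector)
strong_erd_runs <- function(n_seeds = 10) {
  memoize(sprintf("strong_erd_%d", n_seeds), {
    lapply(seq_len(n_seeds), function(s) {
      config <- pipeline_config(n_subjects = 1, seed = 1000 + s,
                                sample_rate_hz = FIXTURE_FS,
                                channel_sets = c("all30", "motor9"),
                                conditions = c("actual", "attempted"))
      sim1 <- brainswitch:::simulate_subject_epochs(config, 1, 1)
      keep <- sim1$epochs$labels %in% c("actual", "none")
      ep1 <- subset_epochs(sim1$epochs, which(keep))
      rm(sim1)
      sim2 <- brainswitch:::simulate_subject_epochs(config, 1, 2)
      ep2 <- sim2$epochs
      rm(sim2)
      out <- list()
      for (set in c("motor9", "all30")) {
        ch <- channel_set_labels(set)
        f1 <- extract_features(ep1, channels = ch)
        f2 <- extract_features(ep2, channels = ch)
        tr <- brainswitch:::condition_subset(f1, "actual")
        te <- brainswitch:::condition_subset(f2, "attempted")
        cv <- crossval_accuracy(te, te$labels, k = 10,
                                seed = derive_seed(config$seed, paste0("cv-", set)))
        trf <- transfer_accuracy(tr, tr$labels, te, te$labels,
                                 seed = derive_seed(config$seed, paste0("trf-", set)))
        out[[set]] <- list(cv_accuracy = cv$overall_accuracy,
                           transfer_accuracy = trf$accuracy,
                           decision_values = trf$decision_values,
                           test_labels = as.character(te$labels))
      }
      out
    })
  })
}

## null-profile chance-level runs (shared by the chance-level acceptance
## check); returns CV accuracies in percent
null_chance_runs <- function(n_seeds = 20) {
  memoize(sprintf("null_runs_%d", n_seeds), {
    vapply(seq_len(n_seeds), function(s) {
      100 * null_pipeline_cv(s, sample_rate_hz = FIXTURE_FS)$overall_accuracy
    }, numeric(1))
  })
}
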