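## Structured (YAML) configuration files: one document drives a whole run —
## generator profiles and amplitudes, spline constants, classifier options,
## channel sets. Keys mirror the constructor arguments.

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror [pipeline_config()] arguments (`n_subjects`,
#' `seed`, `sample_rate_hz`, `channel_sets`, `conditions`, `k`,
#' `selection`, `noise_scale`, `rhythm_amp`, `log10_features`). A `spline`
#' mapping (`m`, `n_terms`, `ridge`) feeds [spline_params()]; a `profiles`
#' mapping of condition name to `erd_depth`/`ers_gain`/`emg_percent` feeds
#' [condition_profile()], with unlisted conditions keeping their defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_invalid("missing config file: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop_invalid("config file must contain a YAML mapping")

  args <- raw[intersect(names(raw),
                        c("n_subjects", "seed", "sample_rate_hz",
                          "channel_sets", "conditions", "k", "selection",
                          "noise_scale", "rhythm_amp", "log10_features"))]
  unknown <- setdiff(names(raw), c(names(args), "spline", "profiles"))
  if (length(unknown)) {
    stop_invalid(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$spline)) {
    args$spline <- do.call(spline_params, raw$spline)
  }
  if (!is.null(raw$profiles)) {
    profiles <- default_condition_profiles()
    for (cond in names(raw$profiles)) {
      if (!cond %in% names(profiles)) {
        stop_invalid(sprintf("profile for unknown condition '%s'", cond))
      }
      profiles[[cond]] <- do.call(condition_profile, raw$profiles[[cond]])
    }
    args$profiles <- profiles
  }
  do.call(pipeline_config, args)
}
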