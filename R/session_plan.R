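## Experimental design: cued movement trials grouped into sequences of nine,
## sequences into blocks, blocks into two phases (before / after the
## neuromuscular block). Phase 1 has four conditions x 81 trials over three
## blocks; phase 2 has two conditions x 54 trials in a single block.

PHASE1_CONDITIONS <- c("actual", "isometric", "imagined", "none")
PHASE2_CONDITIONS <- c("attempted", "none")

#' Conditions valid in an experimental phase
#'
#' @param phase 1 or 2.
#' @return Character vector of condition names.
#' @export
phase_conditions <- function(phase) {
  if (!phase %in% c(1, 2)) stop_invalid("`phase` must be 1 or 2")
  if (phase == 1) PHASE1_CONDITIONS else PHASE2_CONDITIONS
}

check_condition <- function(condition, phase = NULL) {
  valid <- if (is.null(phase)) union(PHASE1_CONDITIONS, PHASE2_CONDITIONS) else phase_conditions(phase)
  if (!is.character(condition) || length(condition) != 1L || !condition %in% valid) {
    stop_invalid(sprintf("unknown condition '%s' (valid: %s)",
                         as.character(condition)[1], paste(valid, collapse = ", ")))
  }
  condition
}

#' Build one sequence of cued trials
#'
#' A sequence is `n_trials` consecutive trials of one condition, each an
#' auditory cue of `cue_s` seconds followed by a silent gap of `gap_s`
#' seconds, so consecutive onsets are `cue_s + gap_s` apart.
#'
#' @param condition Condition name.
#' @param n_trials Number of trials (default 9).
#' @param cue_s Cue duration in seconds (default 3).
#' @param gap_s Inter-trial silence in seconds (default 4).
#' @param t0 Onset of the first trial, seconds from recording start.
#' @param sequence_index,block_index Bookkeeping indices stored per trial.
#' @return A data.frame of trial events with columns `onset_s`, `duration_s`,
#'   `condition`, `sequence`, `block`.
#' @export
build_sequence <- function(condition, n_trials = 9, cue_s = 3, gap_s = 4, t0 = 0,
                           sequence_index = 1L, block_index = 1L) {
  check_condition(condition)
  check_number(n_trials, "n_trials", positive = TRUE)
  check_number(cue_s, "cue_s", positive = TRUE)
  check_number(gap_s, "gap_s", positive = TRUE)
  check_number(t0, "t0", nonneg = TRUE)
  onsets <- t0 + (seq_len(n_trials) - 1) * (cue_s + gap_s)
  data.frame(
    onset_s = onsets,
    duration_s = cue_s,
    condition = condition,
    sequence = as.integer(sequence_index),
    block = as.integer(block_index),
    stringsAsFactors = FALSE
  )
}

#' Build the full session plan for one experimental phase
#'
#' Phase 1: four conditions (actual, isometric, imagined, none), 81 trials
#' each, divided over 3 blocks of 12 sequences (3 sequences per condition per
#' block, 9 trials per sequence). Phase 2: two conditions (attempted, none),
#' 54 trials each in a single block of 12 sequences. Sequence order within
#' each block is a seeded permutation.
#'
#' @param phase 1 or 2.
#' @param seed Integer seed for the sequence shuffle.
#' @param cue_s,gap_s Trial timing in seconds (defaults 3 and 4).
#' @param seq_rest_s Rest between sequences in seconds (default 10; the
#'   self-paced button press in the original design has no reported duration).
#' @param block_rest_s Rest between blocks in seconds (default 30).
#' @param lead_in_s Recording time before the first cue (default 5).
#' @param lead_out_s Recording time after the last cue's analysis window
#'   (default 5).
#' @param sample_rate_hz Sampling rate the plan is intended for (default 2500).
#' @param channel_labels EEG+EMG channel labels (default the 30-channel
#'   montage plus the EMG pair).
#' @return A `session_plan`: a data.frame of trial events (`onset_s`,
#'   `duration_s`, `condition`, `sequence`, `block`) with attributes `phase`,
#'   `seed`, `sample_rate_hz`, `channel_labels`, `duration_s`.
#' @export
build_session_plan <- function(phase, seed,
                               cue_s = 3, gap_s = 4,
                               seq_rest_s = 10, block_rest_s = 30,
                               lead_in_s = 5, lead_out_s = 5,
                               sample_rate_hz = 2500,
                               channel_labels = default_channel_labels()) {
  if (!length(phase) == 1L || !phase %in% c(1, 2)) stop_invalid("`phase` must be 1 or 2")
  check_number(seed, "seed")
  conditions <- phase_conditions(phase)
  n_blocks <- if (phase == 1) 3L else 1L
  seqs_per_cond_block <- if (phase == 1) 3L else 6L
  trials_per_seq <- 9L

  events <- list()
  t <- lead_in_s
  seq_counter <- 0L
  for (b in seq_len(n_blocks)) {
    block_seqs <- rep(conditions, each = seqs_per_cond_block)
    order_b <- with_seed(derive_seed(seed, paste0("block", b)),
                         sample.int(length(block_seqs)))
    block_seqs <- block_seqs[order_b]
    for (cond in block_seqs) {
      seq_counter <- seq_counter + 1L
      ev <- build_sequence(cond, trials_per_seq, cue_s, gap_s, t0 = t,
                           sequence_index = seq_counter, block_index = b)
      events[[length(events) + 1L]] <- ev
      # sequence spans (n-1) inter-onset intervals + final cue + final gap
      t <- t + trials_per_seq * (cue_s + gap_s) + seq_rest_s
    }
    t <- t + block_rest_s
  }
  plan <- do.call(rbind, events)
  rownames(plan) <- NULL
  duration <- max(plan$onset_s) + cue_s + gap_s + lead_out_s
  structure(plan,
            phase = as.integer(phase), seed = as.integer(seed),
            cue_s = cue_s, gap_s = gap_s,
            sample_rate_hz = sample_rate_hz,
            channel_labels = channel_labels,
            duration_s = duration,
            class = c("session_plan", "data.frame"))
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf("<session_plan> phase %d: %d trials, %d sequences, %d blocks, %.0f s\n",
              attr(x, "phase"), nrow(x), length(unique(x$sequence)),
              length(unique(x$block)), attr(x, "duration_s")))
  tab <- table(x$condition)
  cat("  trials per condition:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Write a session plan as a tab-separated event file
#'
#' Columns: onset_s, duration_s, condition, sequence, block, phase.
#'
#' @param plan A `session_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(plan, path) {
  df <- as.data.frame(plan)
  df$phase <- attr(plan, "phase")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated event file
#'
#' @param path Path written by [write_events_tsv()].
#' @param sample_rate_hz,channel_labels Plan attributes not stored in the TSV.
#' @return A `session_plan`.
#' @export
read_events_tsv <- function(path, sample_rate_hz = 2500,
                            channel_labels = default_channel_labels()) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  phase <- unique(df$phase)
  if (length(phase) != 1L) stop_invalid("event file must contain a single phase")
  cue_s <- max(df$duration_s)
  plan <- df[, c("onset_s", "duration_s", "condition", "sequence", "block")]
  structure(plan,
            phase = as.integer(phase), seed = NA_integer_,
            cue_s = cue_s, gap_s = NA_real_,
            sample_rate_hz = sample_rate_hz,
            channel_labels = channel_labels,
            duration_s = max(df$onset_s) + cue_s + 9,
            class = c("session_plan", "data.frame"))
}
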