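#!/usr/bin/env Rscript
## The classification analyses: (a) within-condition ten-fold CV for every
## movement condition against its phase's no-movement trials, per channel
## set -- the synthetic analogue of the study's single-trial accuracy
## table; (b) cross-condition transfer, training on each phase-1 movement
## condition and testing on attempted movement -- the clinically relevant
## calibration-before-paralysis scenario. Per-subject accuracies carry
## exact binomial CIs, group means a t-based CI.
##
## Two synthetic subjects keep the runtime of this narrative script in the
## minutes range; the statistical acceptance checks in the test suite run
## the same pipeline over many more seeds.

library(brainswitch)

dir.create("results", showWarnings = FALSE)
config <- pipeline_config(n_subjects = 2, seed = 20260922,
                          sample_rate_hz = 200,
                          channel_sets = c("all30", "motor9"),
                          conditions = c("actual", "imagined", "attempted"))

cat("== Within-condition cross-validated accuracies ==\n")
within <- run_within_condition(config)
print(transform(as.data.frame(within),
                accuracy = round_half_up(accuracy),
                ci = sprintf("(%d-%d)", round_half_up(pmax(ci_lower, 0)),
                             round_half_up(pmin(ci_upper, 100))))[
        , c("subject", "condition", "channel_set", "accuracy", "ci")],
      row.names = FALSE)
write_results_report(within, "results/within_condition")

cat("\n== Transfer to attempted movement (trained on phase 1) ==\n")
transfer <- run_transfer(config)
print(transform(as.data.frame(transfer),
                accuracy = round_half_up(accuracy),
                ci = sprintf("(%d-%d)", round_half_up(pmax(ci_lower, 0)),
                             round_half_up(pmin(ci_upper, 100))))[
        , c("subject", "train_condition", "channel_set", "accuracy", "ci")],
      row.names = FALSE)
write_results_report(transfer, "results/transfer")

cat("\nReports written to results/within_condition.{json,tsv} and results/transfer.{json,tsv}\n")
cat("Expected pattern: strong-ERD conditions (actual, attempted) classify in\n",
    "the 90s against rest; imagery (weaker ERD) lower; actual->attempted\n",
    "transfer lands within a few points of attempted's own CV accuracy, and\n",
    "the 9-channel motor set performs on par with all 30 channels.\n")
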