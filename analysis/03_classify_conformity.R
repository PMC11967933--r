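#!/usr/bin/env Rscript

# Classify every participant in the synthetic cohort into behavioural types
# (UC / CC / FR / Uncategorized) from their linear conditional-contribution
# profile, compare against the planted ground truth, and compute the two
# conformity summaries. Requires analysis/02_synthesize_cohort.R to have run.

suppressPackageStartupMessages({
  library(tpgg)
  library(dplyr)
})

out_dir <- "results"
records <- read_records(file.path(out_dir, "cohort_records.csv"))
truth <- read.csv(file.path(out_dir, "cohort_truth.csv"), stringsAsFactors = FALSE)

classified <- classify_dataset(records)
write.csv(classified$participants, file.path(out_dir, "classification.csv"),
          row.names = FALSE)
write.csv(classified$shares, file.path(out_dir, "type_shares.csv"),
          row.names = FALSE)

cat("type shares by treatment:\n")
print(classified$shares)

recovery <- classified$participants |>
  inner_join(truth, by = c("treatment", "group_id", "participant_id"),
             suffix = c("_fit", "_true")) |>
  summarise(recovery_rate = mean(type_fit == type_true), n = n())
cat(sprintf("\nplanted-type recovery: %.3f over %d participants\n",
            recovery$recovery_rate, recovery$n))

direction <- conformity_direction(records)
write.csv(direction$rates, file.path(out_dir, "conformity_direction.csv"),
          row.names = FALSE)
cat("\ndirection-conformity rates:\n")
print(direction$rates)

rank_summary <- conformity_rank(records)
write.csv(rank_summary, file.path(out_dir, "conformity_rank.csv"),
          row.names = FALSE)
cat("\nrank-persistence summary:\n")
print(rank_summary)
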