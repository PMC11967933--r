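#!/usr/bin/env Rscript

# Behaviour around disaster checks in the synthetic cohort: post-check
# contribution trajectories by lag, near-threshold case splits, and
# cluster-robust treatment contrasts (all rounds and the pre-first-check
# subset). Requires analysis/02_synthesize_cohort.R to have run.

suppressPackageStartupMessages({
  library(tpgg)
  library(dplyr)
})

out_dir <- "results"
records <- read_records(file.path(out_dir, "cohort_records.csv"))

events <- check_events(records)
write.csv(events, file.path(out_dir, "check_events.csv"), row.names = FALSE)
cat(sprintf("%d check events, %.0f%% passed\n",
            nrow(events), 100 * mean(events$passed)))

rac <- rounds_after_check(records, max_lag = 5)
write.csv(rac$by_lag, file.path(out_dir, "rounds_after_check.csv"),
          row.names = FALSE)
cat("\nmean group total by rounds-since-check:\n")
print(rac$by_lag)

near <- near_threshold_cases(records, margin = 0.1)
cat(sprintf("\nnear-threshold cases: %d near-misses (passed within 10%%), %d almost-made-its (failed within 10%%)\n",
            nrow(near$near_miss$cases), nrow(near$almost_made_it$cases)))

contrast <- treatment_contrast(records)
write.csv(contrast$coefficients, file.path(out_dir, "treatment_contrast.csv"),
          row.names = FALSE)
cat("\ntreatment contrasts (two-way cluster-robust, group and participant):\n")
print(contrast$coefficients)

pre <- pre_first_check_contrast(records)
write.csv(pre$coefficients, file.path(out_dir, "pre_first_check_contrast.csv"),
          row.names = FALSE)
cat(sprintf("\npre-first-check contrasts (%d observations):\n", pre$n_obs))
print(pre$coefficients)
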