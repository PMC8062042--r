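#!/usr/bin/env Rscript
# Stage 2: validity filtering. Classifies every result against the three
# exclusion rules (wrong ellipse count, unresized default circles,
# non-overlapping pair) plus the multi-pair category, tabulates the counts,
# and summarises per-worker behavior.

suppressPackageStartupMessages(library(airwaycrowd))

results <- read_results("results/data/results.csv")
labels <- classify_results(results)
utils::write.csv(labels, "results/validity_labels.csv", row.names = FALSE)

tab <- tabulate_validity(labels)
cat(sprintf("results: %d total\n", tab$n_total))
print(as.data.frame(tab$by_status))
print(as.data.frame(tab$by_reason))
cat(sprintf("'no airway' corner markers: %d\n", tab$n_no_airway))
utils::write.csv(tab$by_status, "results/validity_by_status.csv",
                 row.names = FALSE)
utils::write.csv(tab$by_reason, "results/validity_by_reason.csv",
                 row.names = FALSE)

ws <- worker_statistics(labels)
utils::write.csv(ws$workers, "results/worker_summaries.csv",
                 row.names = FALSE)
utils::write.csv(ws$cumulative, "results/worker_cumulative.csv",
                 row.names = FALSE)
cat(sprintf("workers: %d; valid ~ invalid OLS slope %.3f, intercept %.2f\n",
            nrow(ws$workers), ws$fit$slope, ws$fit$intercept))
cat("a positive slope means workers tend to create more valid than invalid results\n")
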