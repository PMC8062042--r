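#!/usr/bin/env Rscript
# Stage 3: airway measures. For every valid result and every expert
# reference: inner/outer area (mm^2), equivalent-circle diameters, wall
# thickness, wall thickness ratio (WTR) and wall area percentage (WAP).

suppressPackageStartupMessages(library(airwaycrowd))

results <- read_results("results/data/results.csv")
labels <- utils::read.csv("results/validity_labels.csv")
meas <- measure_results(results, labels)
utils::write.csv(meas, "results/measurements.csv", row.names = FALSE)
cat(sprintf("measured %d valid results across %d tasks\n",
            nrow(meas), length(unique(meas$task_id))))
cat(sprintf("median WAP %.1f%%, median WTR %.3f\n",
            stats::median(meas$wap), stats::median(meas$wtr)))

experts <- read_experts("results/data/experts.csv")
em <- measure_experts(experts)
utils::write.csv(em, "results/expert_measurements.csv", row.names = FALSE)
cat(sprintf("expert references measured: %d rows, %d expert(s)\n",
            nrow(em), length(unique(em$expert_id))))
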