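#!/usr/bin/env Rscript
# Stage 4: combining and crowd-vs-expert evaluation. Produces the
# correlation table over the four strategies (none / random / median / best)
# against both experts plus the expert-vs-expert row, the per-strategy
# combined estimates, scatter data (expert on x, crowd on y), and the
# correlation-vs-minimum-valid-results sweep.

suppressPackageStartupMessages({
  library(airwaycrowd)
  library(dplyr)
})

seed <- 2026L
meas <- utils::read.csv("results/measurements.csv")
em <- utils::read.csv("results/expert_measurements.csv")

ct <- correlation_table(meas, em, seed = seed)
ct$rho <- round(ct$rho, 3)
utils::write.csv(ct, "results/correlation_table.csv", row.names = FALSE)
cat("Pearson correlations, crowd vs expert (and expert vs expert):\n")
print(as.data.frame(ct), digits = 3)

# combined estimates per strategy (vs expert 1 for "best")
e1 <- em[em$expert_id == 1, ]
for (strat in c("median", "random", "best")) {
  est <- combine_tasks(meas, strat, expert = e1, seed = seed)
  utils::write.csv(est, sprintf("results/combined_%s.csv", strat),
                   row.names = FALSE)
}

# scatter data: expert 1 on x, median-combined crowd on y
med <- combine_median(meas)
scatter <- inner_join(med, e1, by = "task_id",
                      suffix = c("_crowd", "_expert"))
utils::write.csv(
  scatter[, c("task_id", "n_valid",
              "inner_area_expert", "inner_area_crowd",
              "outer_area_expert", "outer_area_crowd",
              "wap_expert", "wap_crowd", "wtr_expert", "wtr_crowd")],
  "results/scatter_median_vs_expert1.csv", row.names = FALSE)

# correlation as a function of the minimum valid results per task
sweep <- threshold_sweep(meas, e1, v_range = 1:20)
sweep$rho <- round(sweep$rho, 3)
utils::write.csv(sweep, "results/threshold_sweep.csv", row.names = FALSE)
cat("\nmedian-combined correlation vs minimum valid results (inner area):\n")
print(as.data.frame(sweep[sweep$measure == "inner", ]))
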