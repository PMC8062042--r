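#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study — a 24-subject cohort with ~1026
# airway tasks, a 577-worker heterogeneous crowd contributing 20 results per
# task, and two independent expert references. Writes the interchange CSVs
# every later stage reads.

suppressPackageStartupMessages(library(airwaycrowd))

seed <- 2026L
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cohort <- generate_cohort(n_subjects = 24, tasks_per_subject = c(43, 64),
                          seed = seed)
cohort <- trim_cohort(cohort, 1026)
truth <- cohort$truth
cat(sprintf("cohort: %d subjects, %d tasks (trimmed to the study's 1026)\n",
            nrow(cohort$subjects), nrow(truth)))

workers <- worker_population(n_workers = 577, seed = seed + 1L)
sim <- simulate_crowd(truth, workers, results_per_task = 20,
                      seed = seed + 2L)
cat(sprintf("crowd: %d workers produced %d results (%d ellipses)\n",
            length(unique(sim$expected$worker_id)), nrow(sim$expected),
            nrow(sim$results)))

experts <- simulate_experts(truth, n_experts = 2, seed = seed + 3L)

write_results(sim$results, file.path(out_dir, "results.csv"))
write_tasks(truth, file.path(out_dir, "tasks.csv"))
write_subjects(cohort$subjects, file.path(out_dir, "subjects.csv"))
write_experts(experts, file.path(out_dir, "experts.csv"))
utils::write.csv(true_measures(truth), file.path(out_dir, "truth.csv"),
                 row.names = FALSE)
cat("wrote results/tasks/subjects/experts/truth CSVs to", out_dir, "\n")
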