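#!/usr/bin/env Rscript
# Stage 5: subject-level quality prediction. Per-subject crowd-expert
# correlations (median combining), then five Spearman tests of subject
# characteristics (CF status, FEV1, FVC, airway count, mean generation)
# against the inner-area correlation used as the quality proxy, with a
# Bonferroni-adjusted significance threshold of 0.05 / 5 = 0.01.

suppressPackageStartupMessages(library(airwaycrowd))

meas <- utils::read.csv("results/measurements.csv")
em <- utils::read.csv("results/expert_measurements.csv")
tasks <- read_tasks("results/data/tasks.csv")
subjects <- read_subjects("results/data/subjects.csv")

per <- per_subject_correlations(meas, em[em$expert_id == 1, ], tasks)
utils::write.csv(per, "results/per_subject_correlations.csv",
                 row.names = FALSE)
cat("per-subject crowd-expert correlations (median combining):\n")
print(as.data.frame(per), digits = 2)

qp <- quality_prediction(
  subjects,
  tibble::tibble(subject_id = per$subject_id, rho = per$inner)
)
qp$rho <- round(qp$rho, 3)
qp$p_value <- round(qp$p_value, 3)
utils::write.csv(qp, "results/quality_prediction.csv", row.names = FALSE)
cat(sprintf("\nSpearman tests of %d subject characteristics (n = %d subjects)\n",
            nrow(qp), attr(qp, "n_subjects")))
cat(sprintf("raw alpha %.2f, Bonferroni-adjusted alpha %.2f\n",
            attr(qp, "alpha"), attr(qp, "alpha_adjusted")))
print(as.data.frame(qp))
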