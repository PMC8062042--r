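# airwaycrowd

Quality analysis of crowdsourced airway annotations in chest CT.

Measuring airways in chest CT matters for diseases such as cystic fibrosis,
but manual measurement is slow and expert time is scarce. One alternative is
to crowdsource the task: show anonymous workers a 2D slice cut
perpendicular to an airway and ask them to draw two ellipses — one around
the airway lumen, one around the outer wall boundary — or to drop a small
circle in the top-right corner if they see no airway. Crowd submissions are
noisy and often malformed, so the analysis pipeline has to (1) filter out
invalid results, (2) turn the valid ones into airway measures, (3) combine
the redundant results collected per task into one estimate, and (4) ask how
well the combined crowd tracks a trained expert, and whether that quality is
predictable from subject characteristics.

`airwaycrowd` implements that pipeline for R, together with a synthetic
cohort/crowd generator so every stage can be exercised and validated without
any external data.

## The measures

For one airway with inner (lumen) area *a*ᵢ and outer area *a*ₒ (mm²),
with equivalent-circle diameters *d* = 2√(*a*/π):

- wall thickness **WT** = (*d*ₒ − *d*ᵢ) / 2
- wall thickness ratio **WTR** = WT / *d*ₒ  (dimensionless, < 0.5)
- wall area percentage **WAP** = (*a*ₒ − *a*ᵢ) / *a*ₒ × 100

Equivalent-circle diameters are used throughout because the expert
references record areas only, so crowd and expert measures must both assume
circular airways to be comparable.

A result is **valid** only if it consists of exactly two resized,
overlapping ellipses. Everything else is invalid (wrong ellipse count —
including the instructed "no airway" corner marker — unresized default
circles, or a non-overlapping pair), except results with four or more
ellipses, which form a separate multi-pair exclusion category.

Redundant valid results per task are combined by **median** (element-wise
median of inner/outer areas, ratios recomputed from the medians),
**random** (one seeded uniform draw per task; a pessimistic one-worker
bound) or **best** (the result closest to the expert in the
(*a*ᵢ, *a*ₒ) plane; an optimistic bound). Crowd-vs-expert agreement is
reported as Pearson correlations banded as weak (ρ < 0.3), moderate
(0.3 ≤ ρ < 0.5) or strong (ρ ≥ 0.5), and subject-level quality prediction
uses five two-sided Spearman tests at a Bonferroni-adjusted threshold of
0.05 / 5 = 0.01.

## Worked example

```r
library(airwaycrowd)

cohort  <- trim_cohort(generate_cohort(n_subjects = 24,
                                       tasks_per_subject = c(43, 64),
                                       seed = 2026), 1026)
workers <- worker_population(n_workers = 577, seed = 2027)
sim     <- simulate_crowd(cohort$truth, workers, results_per_task = 20,
                          seed = 2028)

labels <- classify_results(sim$results)
tabulate_validity(labels)$by_status
#>   status         n   pct
#> 1 invalid    11643  56.7
#> 2 multi_pair   503   2.5
#> 3 valid       8374  40.8
```

20520 results were collected (1026 tasks × 20); 56.7% are invalid and 2.5%
are multi-pair submissions — the filter keeps the 40.8% that are two
resized, overlapping ellipses. Measuring and combining those, then
correlating with a simulated expert:

```r
meas <- measure_results(sim$results, labels)
em   <- measure_experts(simulate_experts(cohort$truth, seed = 2029))
correlation_table(meas, em, strategies = c("median"))
#>   strategy expert_id measure   rho n_tasks strength
#> 1 median           1 inner   0.971    1025 strong
#> 2 median           1 outer   0.967    1025 strong
#> 3 median           1 wap     0.454    1025 moderate
#> 4 median           1 wtr     0.471    1025 moderate
#> ...
```

Area measures correlate far better than the ratio measures (WAP/WTR
amplify relative annotation noise), and the same gap shows up between the
two simulated experts — the qualitative signature of this kind of data.

## The analysis workflow

The `analysis/` directory holds the pipeline as numbered drivers over the
package functions; each stage reads/writes plain CSVs under `results/`:

```sh
Rscript analysis/01_simulate.R            # cohort, crowd, experts -> CSVs
Rscript analysis/02_filter.R              # validity labels + worker stats
Rscript analysis/03_measure.R             # airway measures (crowd + expert)
Rscript analysis/04_combine_evaluate.R    # combining, correlation table, sweep
Rscript analysis/05_quality_prediction.R  # per-subject rho + Spearman tests
```

The same readers accept externally collected annotation tables (one CSV row
per ellipse; see `?read_results`), so a real collection can be analysed by
replacing stage 1's outputs — including the deposited data from the
original collection, which is not bundled here.

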