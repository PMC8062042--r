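---
title: "Methods: filtering, measuring and evaluating crowdsourced airway annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: filtering, measuring and evaluating crowdsourced airway annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, conventions and numerical choices
behind `airwaycrowd`: what each pipeline stage assumes, which parameters
matter and why their defaults are what they are, what the synthetic
generator does and does not emulate, and the known limitations.

```{r setup}
library(airwaycrowd)
```

## The annotation model

A *task* is a 2D CT slice (rescaled to a 500 × 500-pixel canvas) cut
approximately perpendicular to an airway. A *result* is one worker's
submission for one task: one or more ellipses in pixel coordinates, each
stored as center, semi-axes and a rotation normalized to [0, π). The frame
uses the raster convention (origin top-left, y downward), so the
"top-right corner" where workers are told to put a no-airway marker means
large x, small y. One pixel corresponds to 0.05508 mm: the scans' 0.5508 mm
in-plane voxels displayed at 10× magnification.

## Validity filtering

A result is valid only if it is exactly two resized, overlapping ellipses.
The classifier applies rules in a fixed order, so every result receives
exactly one label:

1. **≥ 4 ellipses → multi-pair.** Reported as its own excluded category,
   not folded into the wrong-count bucket, because multi-pair submissions
   are bookkept separately from invalid ones in this kind of collection.
   Three ellipses are a wrong count, not a multi-pair: there is no second
   pair. The count-based rule is a deliberate simplification — nothing in
   the submissions marks which ellipses were meant as a pair.
2. **count ≠ 2 → wrong ellipse count.** A single annotation that is a small
   circle in the top-right corner region additionally carries a
   `no_airway` flag: it is the instructed way of declining the task, and
   worth counting separately even though it is still an invalid result.
3. **unresized default → not resized.** The annotation tool starts each
   ellipse as a circle of fixed size; a submission left at (or
   imperceptibly close to) that default carries no information. An ellipse
   counts as the default when both semi-axes are within a relative
   tolerance (2%) of the default semi-axis (50 px) *and* the two semi-axes
   differ by no more than the same tolerance (circle-shaped). One default
   ellipse in a pair suffices to invalidate it: the pair's measurement
   would be half-meaningless.
4. **no overlap → not overlapping.** Lumen and wall boundaries of one
   airway must enclose overlapping regions.

The corner region (top-right 20% × 20% of the frame), marker size cap (10%
of frame width), tool default size and tolerance are all configuration:
the interface never published numeric values for them, so they are stated
assumptions with conservative defaults, not facts.

### Overlap testing

Ellipse–ellipse intersection is decided by discretizing each boundary to
256 points and testing mutual center/boundary containment, after a
bounding-circle quick reject. This is robust and fast, at the cost of
missing sliver intersections thinner than the boundary spacing; the test
suite bounds the error against a rejection-sampling oracle (disagreements
only on intersections under 10 px², far below anything a hand-drawn
annotation produces). Exact conic–conic algebra was deliberately avoided:
annotations are nowhere near tangency, and the discretized test has no
degenerate branches.

## Airway measures

For a valid result, the smaller-area ellipse is the lumen — the interface
does not label the two ellipses, and area ordering is the only safe
criterion. Exact area ties are rejected as degenerate rather than guessed.
Pixel areas convert to mm² via `mm_per_pixel²`; diameters are
equivalent-circle diameters 2√(a/π); then WT = (d_o − d_i)/2,
WTR = WT/d_o, WAP = (a_o − a_i)/a_o × 100. Equivalent-circle diameters are
used for workers even though their ellipse axes are available, because
expert references record areas only and both sides must be measured on the
same footing. A consequence worth knowing: WAP and WTR are then two
deterministic transforms of the same area ratio
(WAP = 100·(1 − (1 − 2·WTR)²)), which the tests exploit as an internal
consistency check. Both ratios are invariant under any common rescaling of
the two areas, so the mm-vs-pixel choice cannot leak into any correlation.

## Combining

Per task, valid results are combined by:

- **median** — element-wise median of inner and outer areas; diameters,
  WT, WTR and WAP are recomputed from the median areas, never averaged
  from per-result ratios (even-length medians are the mean of the central
  pair);
- **random** — one uniform draw per task from a single seeded stream that
  visits tasks in sorted `task_id` order, making the output independent of
  input row order; a pessimistic bound on a one-worker-per-task design;
- **best** — the valid result minimizing Euclidean distance to the expert
  in the (inner area, outer area) plane, ties broken to the smallest
  result id; an optimistic bound, since it peeks at the reference. The
  distance metric is a design choice; "closest on the inner and outer
  measurements" does not pin down a norm, and the Euclidean choice treats
  a mm² of error on either boundary symmetrically.

Tasks with no valid results yield no estimate and drop out of every
correlation; `filter_min_valid()` additionally restricts to tasks with at
least *v* valid results for the threshold sweep.

## Evaluation

Crowd-vs-expert agreement uses Pearson correlations per measure, strategy
and expert; the "none" row pairs each individual valid result with its
task's expert value. Constant inputs have no defined correlation and are
reported as missing, never coerced to zero. Strength bands are half-open:
weak [0, 0.3), moderate [0.3, 0.5), strong [0.5, 1].

Subject-level quality prediction uses each subject's inner-area
crowd-expert correlation (median combining) as the quality proxy and runs
five two-sided Spearman tests against: CF status, FEV1, FVC, airway count
and mean airway generation. Ranks use midranks for ties (which is how the
binary CF covariate enters). P-values use the t-approximation
t = ρₛ√((n−2)/(1−ρₛ²)) on n−2 degrees of freedom: at the cohort size of
24 subjects this approximation is accurate (its type-I error is verified
to sit in [0.03, 0.07] at nominal 0.05), and it is the convention under
which published coefficient/p-value pairs of this analysis reproduce each
other. Bonferroni is used for the five comparisons — dividing 0.05 by 5
gives the adjusted threshold 0.01.

Per-worker statistics tally each worker's valid/invalid/multi-pair counts,
the cumulative-contribution curve (workers sorted by output), and an
ordinary least-squares fit of valid count on invalid count across workers;
a positive slope says workers who produce more also produce
proportionally more valid results.

## The synthetic generator

The generator exists so the full pipeline can be validated against known
ground truth. Its defaults are fixed once to mirror the regime of a real
collection of this design, and the key ones are:

- **Cohort**: 24 subjects; per-subject task counts uniform on [18, 68]
  (mean ≈ 43, cohort ≈ 1026 tasks; `trim_cohort()` reaches the exact
  total when needed). True inner radii are lognormal (median 1.4 mm,
  sdlog 0.35 — generation 5–8 pediatric airways); wall thickness is a
  lognormal fraction of the inner radius (median 0.4, sdlog 0.25), which
  keeps the implied WTR inside (0, 0.5) for every draw and puts WAP near
  50%. Axis ratios are uniform on [0.8, 0.97]: perpendicular cuts are
  nearly but never exactly circular, and a strictly sub-unit ratio keeps a
  true airway that happens to match the tool's default circle size
  geometrically distinguishable from an unresized default. Subject
  covariates (CF ~ Bernoulli(0.5), FEV1/FVC Gaussian in plausible
  percent-predicted ranges) carry no signal about task difficulty unless
  `difficulty_effect` is raised above its null default of 0.
- **Workers**: 577 workers with lognormal productivity (sdlog 1.3,
  floored at 1), giving the heavy-tailed output profile of anonymous
  platforms — a few workers dominate the collection. Each worker has a
  dominant behavior: careful (35%), no-airway-prone (20%), sloppy-single
  (20%), non-resizer (15%), spammer (10%), plus a lapse rate of 0.15 —
  the probability of acting against type on any given result. The lapse is
  what makes prolific workers accumulate both valid and invalid results,
  as real worker scatters show; with it, the mixture lands near 43% valid,
  54% invalid and 2.5% multi-pair results.
- **Annotation noise** is multiplicative on radii (lognormal, default
  sd 0.10) rather than additive on areas: relative error is the natural
  model for outlining, and it makes the characteristic noise amplification
  of the ratio measures (WAP/WTR correlating much worse than areas)
  *emerge* from the geometry instead of being injected.
- **Difficulty** modulates only the probability of a no-airway marker by
  default (`marker_base + marker_slope·difficulty`, 0.55 + 0.40·d). The
  optional `difficulty_noise` link additionally scales outlining noise
  with difficulty; it is off by default and used when one wants the
  mechanism behind threshold sweeps — tasks retaining many valid results
  being both easier and better measured — to be present explicitly.
- **Experts** record true areas with independent multiplicative lognormal
  noise (default sd 0.12), chosen so that two experts correlate ≈ 0.96 on
  areas while their WAP/WTR correlations sit far lower — the observed
  inter-expert signature.

All stochastic operations take explicit seeds, and callers derive
independent sub-seeds per stream, so every dataset is byte-reproducible.

What the generator does **not** emulate: pixel intensities or image
content (the crowd's perception enters only through the behavior and
difficulty model), worker learning or fatigue over time, correlated errors
between workers who misread the same image feature, and the real joint
distribution of worker behaviors, which is unknown and exposed entirely
through configuration. Passing tests on synthetic data therefore validate
the pipeline's logic and statistical behavior, not claims about any
specific real crowd.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full-scale design — 1026
tasks × 20 results from 577 workers (20 520 results, ≈ 35 000 ellipses) —
for the end-to-end recovery checks, and small cohorts (tens to hundreds of
tasks) elsewhere; Monte-Carlo checks use 10⁴–2×10⁵ draws. Overlap
discretization uses 256 boundary vertices. Reported percentages are
rounded to one decimal and correlations to three, matching the convention
of the tables this analysis style produces. Medians over even-length sets
are the mean of the central pair. Results whose two ellipses have exactly
equal areas (a measure-zero event for real annotations) are dropped with a
warning rather than assigned an arbitrary inner/outer order.

## Limitations

- The three geometric exclusion rules are necessary-but-crude: a worker
  can submit two resized overlapping ellipses unrelated to the airway and
  pass the filter. No semantic spam detection is attempted.
- The multi-pair rule (≥ 4 ellipses) is an assumption; collections that
  mark pairs explicitly should pre-group them before classification.
- The circular-airway assumption biases diameters of genuinely elliptical
  airways; it is forced by area-only expert references.
- Correlations on the synthetic cohort depend on the truth distribution's
  spread; they validate orderings and recovery, and are not predictions
  of any particular real collection's coefficients. Reproducing a real
  collection's tables requires its deposited annotation data, which this
  package reads but does not bundle.
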