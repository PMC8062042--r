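Package: airwaycrowd
Title: Quality Analysis of Crowdsourced Airway Annotations in Chest CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for crowdsourced two-ellipse airway annotations
    in chest computed tomography slices. Provides ellipse geometry primitives,
    validity filtering of crowd results (wrong ellipse count, unresized default
    circles, non-overlapping pairs, multi-pair submissions), airway lumen and
    wall measures (inner/outer area, wall thickness, wall thickness ratio, wall
    area percentage), per-task aggregation of redundant crowd results (median,
    random, best), crowd-versus-expert correlation reports with strength bands,
    per-worker statistics, subject-level quality prediction via Spearman tests
    with Bonferroni adjustment, and a synthetic cohort and crowd generator so
    the full pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
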