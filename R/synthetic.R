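#' Generate a synthetic subject cohort with ground-truth airways
#'
#' Emulates the structure of the study data: two dozen pediatric subjects,
#' each contributing a few dozen airway tasks, with per-subject covariates
#' (CF status, spirometry, airway count, mean generation). Ground truth per
#' task is an almost-circular airway: a lognormal inner (lumen) radius and a
#' wall thickness that is a lognormal fraction of the inner radius, which
#' keeps the implied wall thickness ratio strictly inside (0, 0.5) for any
#' positive fraction.
#'
#' @param n_subjects Number of subjects.
#' @param tasks_per_subject Integer range `c(min, max)`; each subject's task
#'   count is drawn uniformly from it (default mean ~43 tasks, giving a
#'   cohort of roughly a thousand tasks at 24 subjects).
#' @param inner_radius_meanlog,inner_radius_sdlog Lognormal parameters of
#'   the true inner radius, in log-mm (default median 1.4 mm, typical of
#'   generation 5-8 pediatric airways).
#' @param wall_fraction_meanlog,wall_fraction_sdlog Lognormal parameters of
#'   wall thickness as a fraction of inner radius (default median 0.4,
#'   giving wall area percentages around 50).
#' @param difficulty_effect Effect size linking CF status to task difficulty
#'   (0 = covariates carry no signal about crowd quality, the null default).
#' @param seed Integer seed; the output is fully reproducible.
#' @return A list of two tibbles: `subjects` (`subject_id`, `has_cf`,
#'   `fev1`, `fvc`, `n_airways`, `mean_generation`) and `truth` (`task_id`,
#'   `subject_id`, `true_inner_radius` (mm), `true_wall_thickness` (mm),
#'   `eccentricity` (minor/major axis ratio), `difficulty` in `[0, 1]`).
#' @examples
#' cohort <- generate_cohort(n_subjects = 4, seed = 1)
#' nrow(cohort$subjects)
#' @export
generate_cohort <- function(n_subjects = 24,
                            tasks_per_subject = c(18, 68),
                            inner_radius_meanlog = log(1.4),
                            inner_radius_sdlog = 0.35,
                            wall_fraction_meanlog = log(0.4),
                            wall_fraction_sdlog = 0.25,
                            difficulty_effect = 0,
                            seed = 1L) {
  if (n_subjects < 1 || any(tasks_per_subject < 1) ||
      tasks_per_subject[1] > tasks_per_subject[2]) {
    stop("invalid cohort configuration", call. = FALSE)
  }
  with_local_seed(seed, {
    subject_id <- sprintf("s%02d", seq_len(n_subjects))
    has_cf <- stats::rbinom(n_subjects, 1, 0.5)
    fev1 <- pmax(30, stats::rnorm(n_subjects, 90, 18))
    fvc <- pmax(30, stats::rnorm(n_subjects, 97, 15))
    mean_generation <- stats::rnorm(n_subjects, 6.5, 0.8)
    n_tasks <- sample(seq(tasks_per_subject[1], tasks_per_subject[2]),
                      n_subjects, replace = TRUE)

    subjects <- tibble::tibble(
      subject_id = subject_id, has_cf = has_cf, fev1 = fev1, fvc = fvc,
      n_airways = n_tasks, mean_generation = mean_generation
    )

    total <- sum(n_tasks)
    subj_of_task <- rep(subject_id, n_tasks)
    inner <- stats::rlnorm(total, inner_radius_meanlog, inner_radius_sdlog)
    frac <- stats::rlnorm(total, wall_fraction_meanlog, wall_fraction_sdlog)
    diff_shift <- difficulty_effect * (rep(has_cf, n_tasks) - 0.5)
    difficulty <- pmin(0.99, pmax(0.01,
                                  stats::rbeta(total, 2, 2) + diff_shift))
    truth <- tibble::tibble(
      task_id = sprintf("t%04d", seq_len(total)),
      subject_id = subj_of_task,
      true_inner_radius = inner,
      true_wall_thickness = frac * inner,
      # near-circular but never perfectly circular: perpendicular cuts of a
      # tube are slightly elliptical, and a strictly sub-unit axis ratio
      # keeps true airways distinguishable from the tool's default circle
      eccentricity = stats::runif(total, 0.8, 0.97),
      difficulty = difficulty
    )
    list(subjects = subjects, truth = truth)
  })
}

#' Generate a heterogeneous worker population
#'
#' Workers have a behavior type, a noise scale and a productivity weight.
#' Productivity is heavy-tailed (lognormal), so a few workers produce most
#' of the results while most produce only a handful — the hallmark of
#' anonymous crowd platforms. Behavior types map onto the observed result
#' taxonomy: `careful` workers outline both ellipses; `no_airway_prone`
#' workers place the instructed corner marker on hard images and annotate
#' properly otherwise; `sloppy_single` workers mark the airway with a single
#' ellipse; `non_resizer` workers submit the tool's default circles
#' unchanged; `spammer` workers submit junk (disjoint pairs, wrong counts,
#' or multiple pairs).
#'
#' @param n_workers Number of workers.
#' @param behavior_probs Named probabilities over the five behavior types.
#'   The default mixture reproduces the study regime of roughly 40% valid,
#'   57% invalid and 3% multi-pair results.
#' @param noise_scale Relative (lognormal sd on log radii) annotation noise
#'   of careful outlines.
#' @param lapse_rate Probability that a worker deviates from their dominant
#'   behavior on any given result (a careful worker occasionally submits an
#'   invalid result and vice versa). A nonzero default reflects that almost
#'   every prolific crowd worker produces both valid and invalid results;
#'   set to 0 for behaviorally pure populations.
#' @param center_jitter Center placement jitter in pixels.
#' @param productivity_meanlog,productivity_sdlog Lognormal parameters of
#'   worker productivity weights (floored at 1).
#' @param seed Integer seed.
#' @return A tibble: `worker_id`, `behavior`, `noise_scale`,
#'   `center_jitter`, `productivity`.
#' @export
worker_population <- function(n_workers = 577,
                              behavior_probs = c(careful = 0.35,
                                                 no_airway_prone = 0.20,
                                                 sloppy_single = 0.20,
                                                 non_resizer = 0.15,
                                                 spammer = 0.10),
                              noise_scale = 0.10,
                              lapse_rate = 0.15,
                              center_jitter = 3,
                              productivity_meanlog = 1.2,
                              productivity_sdlog = 1.3,
                              seed = 1L) {
  if (n_workers < 1) stop("need at least one worker", call. = FALSE)
  kinds <- c("careful", "no_airway_prone", "sloppy_single", "non_resizer",
             "spammer")
  if (!setequal(names(behavior_probs), kinds)) {
    stop("behavior_probs must name exactly the five behavior types",
         call. = FALSE)
  }
  with_local_seed(seed, {
    tibble::tibble(
      worker_id = sprintf("w%04d", seq_len(n_workers)),
      behavior = sample(names(behavior_probs), n_workers, replace = TRUE,
                        prob = behavior_probs),
      noise_scale = noise_scale,
      lapse_rate = lapse_rate,
      center_jitter = center_jitter,
      productivity = pmax(1, stats::rlnorm(n_workers, productivity_meanlog,
                                           productivity_sdlog))
    )
  })
}

#' Simulate a crowd of annotators over ground-truth airways
#'
#' For each task, `results_per_task` distinct workers are drawn with
#' probability proportional to productivity, and each emits a result
#' according to their behavior type. Careful outlines are two concentric
#' noisy ellipses around the true lumen and wall boundaries (multiplicative
#' noise on radii, so annotation error is relative — the natural model for
#' outlining, and the reason ratio measures like WAP/WTR come out noisier
#' than areas without any extra injected noise). `no_airway_prone` workers
#' place a corner marker with probability increasing in task difficulty.
#'
#' Each emitted result carries its generating mode, so classifier recovery
#' can be checked against known labels.
#'
#' @param truth Ground-truth table from [generate_cohort()].
#' @param workers Worker table from [worker_population()].
#' @param results_per_task Results collected per task (study design: 20).
#' @param frame An [image_frame()]; truth radii (mm) are converted to pixels
#'   through `frame$mm_per_pixel`.
#' @param default_size Default semi-axis of the annotation tool, in pixels.
#' @param marker_base,marker_slope Corner-marker probability for
#'   `no_airway_prone` workers: `marker_base + marker_slope * difficulty`,
#'   capped at 1.
#' @param difficulty_noise Optional link between task difficulty and
#'   outlining noise: the effective noise scale is
#'   `noise_scale * (1 + difficulty_noise * difficulty)`. At the default 0,
#'   difficulty modulates only the probability of invalid results; a
#'   positive value additionally makes hard images harder to outline
#'   accurately.
#' @param seed Integer seed.
#' @return A list of two tibbles: `results` (one row per ellipse:
#'   `result_id`, `task_id`, `worker_id`, `cx`, `cy`, `a`, `b`, `rotation`)
#'   and `expected` (one row per result: ids, `behavior`, `mode`,
#'   `expected_status`, `expected_reason`, `expected_no_airway`).
#' @export
simulate_crowd <- function(truth, workers, results_per_task = 20,
                           frame = image_frame(), default_size = 50,
                           marker_base = 0.55, marker_slope = 0.40,
                           difficulty_noise = 0, seed = 1L) {
  if (results_per_task < 1) stop("results_per_task must be >= 1",
                                 call. = FALSE)
  if (nrow(workers) == 0L) stop("empty worker population", call. = FALSE)
  if (results_per_task > nrow(workers)) {
    stop("results_per_task exceeds the number of workers", call. = FALSE)
  }
  with_local_seed(seed, {
    n_tasks <- nrow(truth)
    # weighted assignment of distinct workers to each task
    assigned <- lapply(seq_len(n_tasks), function(i) {
      sample.int(nrow(workers), results_per_task, prob = workers$productivity)
    })
    res <- tibble::tibble(
      result_id = seq_len(n_tasks * results_per_task),
      task_row = rep(seq_len(n_tasks), each = results_per_task),
      worker_row = unlist(assigned)
    )
    res$task_id <- truth$task_id[res$task_row]
    res$worker_id <- workers$worker_id[res$worker_row]
    res$behavior <- workers$behavior[res$worker_row]
    res$noise <- workers$noise_scale[res$worker_row] *
      (1 + difficulty_noise * truth$difficulty[res$task_row])
    res$jitter <- workers$center_jitter[res$worker_row]
    res$difficulty <- truth$difficulty[res$task_row]
    res$r_inner_px <- truth$true_inner_radius[res$task_row] / frame$mm_per_pixel
    res$r_outer_px <- (truth$true_inner_radius[res$task_row] +
                         truth$true_wall_thickness[res$task_row]) /
      frame$mm_per_pixel
    res$ecc <- truth$eccentricity[res$task_row]

    # per-result emission mode
    mode <- res$behavior
    na_rows <- mode == "no_airway_prone"
    p_marker <- pmin(1, marker_base + marker_slope * res$difficulty)
    mode[na_rows] <- ifelse(stats::runif(sum(na_rows)) < p_marker[na_rows],
                            "marker", "pair")
    mode[mode == "careful"] <- "pair"
    mode[mode == "sloppy_single"] <- "single"
    mode[mode == "non_resizer"] <- "default_pair"
    sp <- mode == "spammer"
    mode[sp] <- sample(c("disjoint", "multi", "triple"), sum(sp),
                       replace = TRUE, prob = c(0.5, 0.3, 0.2))

    # behavioral lapses: workers occasionally act against type, so almost
    # every prolific worker accumulates both valid and invalid results
    lapse <- if ("lapse_rate" %in% names(workers)) {
      workers$lapse_rate[res$worker_row]
    } else 0
    flip <- stats::runif(length(mode)) < lapse
    was_pair <- mode == "pair"
    n_flip_pair <- sum(flip & was_pair)
    if (n_flip_pair > 0L) {
      mode[flip & was_pair] <- sample(
        c("marker", "single", "default_pair", "disjoint"), n_flip_pair,
        replace = TRUE)
    }
    mode[flip & !was_pair] <- "pair"
    res$mode <- mode

    cx0 <- frame$width / 2
    cy0 <- frame$height / 2
    rows <- list()

    noisy_ellipse <- function(sub, radius, extra_sd = 0) {
      n <- nrow(sub)
      r <- radius * exp(stats::rnorm(n, 0, sub$noise + extra_sd))
      tibble::tibble(
        result_id = sub$result_id,
        task_id = sub$task_id,
        worker_id = sub$worker_id,
        cx = cx0 + stats::rnorm(n, 0, sub$jitter),
        cy = cy0 + stats::rnorm(n, 0, sub$jitter),
        a = r / sqrt(sub$ecc),
        b = r * sqrt(sub$ecc),
        rotation = stats::runif(n, 0, pi)
      )
    }

    pair_rows <- res[res$mode == "pair", ]
    if (nrow(pair_rows) > 0L) {
      rows$inner <- noisy_ellipse(pair_rows, pair_rows$r_inner_px)
      rows$outer <- noisy_ellipse(pair_rows, pair_rows$r_outer_px)
    }

    single_rows <- res[res$mode == "single", ]
    if (nrow(single_rows) > 0L) {
      rows$single <- noisy_ellipse(single_rows, single_rows$r_outer_px,
                                   extra_sd = 0.05)
    }

    marker_rows <- res[res$mode == "marker", ]
    if (nrow(marker_rows) > 0L) {
      n <- nrow(marker_rows)
      r <- stats::runif(n, 5, 12)
      rows$marker <- tibble::tibble(
        result_id = marker_rows$result_id, task_id = marker_rows$task_id,
        worker_id = marker_rows$worker_id,
        cx = stats::runif(n, 0.85, 0.96) * frame$width,
        cy = stats::runif(n, 0.04, 0.15) * frame$height,
        a = r, b = r, rotation = 0
      )
    }

    dp_rows <- res[res$mode == "default_pair", ]
    if (nrow(dp_rows) > 0L) {
      n <- nrow(dp_rows)
      one <- function(dx) tibble::tibble(
        result_id = dp_rows$result_id, task_id = dp_rows$task_id,
        worker_id = dp_rows$worker_id,
        cx = cx0 + stats::rnorm(n, dx, 25),
        cy = cy0 + stats::rnorm(n, 0, 25),
        a = default_size, b = default_size, rotation = 0
      )
      rows$dp1 <- one(-15)
      rows$dp2 <- one(15)
    }

    dj_rows <- res[res$mode == "disjoint", ]
    if (nrow(dj_rows) > 0L) {
      n <- nrow(dj_rows)
      junk <- function(lo, hi) {
        a <- stats::runif(n, 12, 40)
        tibble::tibble(
          result_id = dj_rows$result_id, task_id = dj_rows$task_id,
          worker_id = dj_rows$worker_id,
          cx = stats::runif(n, lo, hi), cy = stats::runif(n, lo, hi),
          a = a, b = a * stats::runif(n, 0.7, 0.92),
          rotation = stats::runif(n, 0, pi)
        )
      }
      rows$dj1 <- junk(60, 180)
      rows$dj2 <- junk(320, 440)
    }

    multi_rows <- res[res$mode == "multi", ]
    if (nrow(multi_rows) > 0L) {
      k <- sample(4:6, nrow(multi_rows), replace = TRUE)
      idx <- rep(seq_len(nrow(multi_rows)), k)
      n <- length(idx)
      a <- stats::runif(n, 10, 45)
      rows$multi <- tibble::tibble(
        result_id = multi_rows$result_id[idx],
        task_id = multi_rows$task_id[idx],
        worker_id = multi_rows$worker_id[idx],
        cx = stats::runif(n, 50, 450), cy = stats::runif(n, 50, 450),
        a = a, b = a * stats::runif(n, 0.7, 0.95),
        rotation = stats::runif(n, 0, pi)
      )
    }

    triple_rows <- res[res$mode == "triple", ]
    if (nrow(triple_rows) > 0L) {
      rows$tr1 <- noisy_ellipse(triple_rows, triple_rows$r_inner_px, 0.05)
      rows$tr2 <- noisy_ellipse(triple_rows, triple_rows$r_outer_px, 0.05)
      rows$tr3 <- noisy_ellipse(triple_rows, triple_rows$r_outer_px * 1.2,
                                0.05)
    }

    results <- dplyr::bind_rows(rows)
    results <- results[order(results$result_id), ]
    results$rotation <- normalize_rotation(results$rotation)

    expected <- tibble::tibble(
      result_id = res$result_id, task_id = res$task_id,
      worker_id = res$worker_id, behavior = res$behavior, mode = res$mode,
      expected_status = c(pair = "valid", marker = "invalid",
                          single = "invalid", default_pair = "invalid",
                          disjoint = "invalid", multi = "multi_pair",
                          triple = "invalid")[res$mode],
      expected_reason = c(pair = "ok", marker = "wrong_ellipse_count",
                          single = "wrong_ellipse_count",
                          default_pair = "not_resized",
                          disjoint = "not_overlapping",
                          multi = "multiple_pairs",
                          triple = "wrong_ellipse_count")[res$mode],
      expected_no_airway = res$mode == "marker"
    )
    list(results = results, expected = expected)
  })
}

#' Trim a cohort to an exact task total
#'
#' Removes excess tasks one at a time from the subjects that currently have
#' the most, so the cohort reaches an exact total (e.g. the study design's
#' 1026 tasks) while every subject stays represented and the per-subject
#' counts flatten as little as possible. Subject `n_airways` covariates are
#' updated to the retained counts.
#'
#' @param cohort A list from [generate_cohort()].
#' @param n_tasks Target total number of tasks; must not exceed the
#'   cohort's current total.
#' @return A cohort list of the same shape with exactly `n_tasks` tasks.
#' @export
trim_cohort <- function(cohort, n_tasks) {
  truth <- cohort$truth
  excess <- nrow(truth) - n_tasks
  if (excess < 0) {
    stop("cohort has fewer tasks than requested", call. = FALSE)
  }
  counts <- table(truth$subject_id)
  drop <- integer(0)
  remaining <- lapply(split(seq_len(nrow(truth)), truth$subject_id),
                      identity)
  for (i in seq_len(excess)) {
    big <- names(which.max(counts))
    rows <- remaining[[big]]
    drop <- c(drop, rows[length(rows)])
    remaining[[big]] <- rows[-length(rows)]
    counts[big] <- counts[big] - 1L
  }
  if (length(drop) > 0L) truth <- truth[-drop, ]
  subjects <- cohort$subjects
  kept <- table(truth$subject_id)
  subjects$n_airways <- as.integer(kept[subjects$subject_id])
  subjects$n_airways[is.na(subjects$n_airways)] <- 0L
  list(subjects = subjects, truth = truth)
}

#' Simulate expert area references
#'
#' Experts record the true inner and outer areas with independent
#' multiplicative lognormal noise. Two experts with the default noise scale
#' reproduce the observed regime in which expert-versus-expert area
#' correlations are very high while WAP/WTR correlations are markedly lower
#' (ratio measures amplify relative noise).
#'
#' @param truth Ground-truth table from [generate_cohort()].
#' @param expert_noise_scale Lognormal sd on log areas (0 = exact truth).
#' @param n_experts Number of independent experts.
#' @param seed Integer seed.
#' @return A tibble: `task_id`, `expert_id`, `inner_area`, `outer_area`
#'   (mm^2), with `inner_area < outer_area` guaranteed.
#' @export
simulate_experts <- function(truth, expert_noise_scale = 0.12,
                             n_experts = 2, seed = 1L) {
  if (expert_noise_scale < 0) stop("noise scale must be non-negative",
                                   call. = FALSE)
  if (n_experts < 1) stop("need at least one expert", call. = FALSE)
  true_inner <- pi * truth$true_inner_radius^2
  true_outer <- pi * (truth$true_inner_radius + truth$true_wall_thickness)^2
  with_local_seed(seed, {
    out <- lapply(seq_len(n_experts), function(e) {
      n <- nrow(truth)
      inner <- true_inner * exp(stats::rnorm(n, 0, expert_noise_scale))
      outer <- true_outer * exp(stats::rnorm(n, 0, expert_noise_scale))
      # an expert would never record an inverted wall; keep ordering
      swap <- inner >= outer
      if (any(swap)) {
        tmp <- inner[swap]
        inner[swap] <- pmin(tmp, outer[swap]) * 0.999
        outer[swap] <- pmax(tmp, outer[swap])
      }
      tibble::tibble(task_id = truth$task_id, expert_id = e,
                     inner_area = inner, outer_area = outer)
    })
    dplyr::bind_rows(out)
  })
}

#' True airway measures of a synthetic cohort
#'
#' Convenience accessor: the noise-free [airway_measures()] implied by the
#' ground truth, one row per task.
#'
#' @param truth Ground-truth table from [generate_cohort()].
#' @return A tibble with `task_id` and the [airway_measures()] columns.
#' @export
true_measures <- function(truth) {
  inner <- pi * truth$true_inner_radius^2
  outer <- pi * (truth$true_inner_radius + truth$true_wall_thickness)^2
  dplyr::bind_cols(tibble::tibble(task_id = truth$task_id),
                   airway_measures(inner, outer))
}

# Deterministically derive a sub-seed for an independent stream.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483647)
}
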