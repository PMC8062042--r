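#' Pearson correlation with explicit missing-data policy
#'
#' Pairs with a missing value on either side are dropped before computing
#' the product-moment coefficient. A constant input (zero variance) has no
#' defined correlation and is reported as `NA`, never coerced to 0.
#'
#' @param x,y Paired numeric vectors.
#' @return The coefficient, or `NA_real_` if fewer than 2 complete pairs
#'   remain or either side is constant.
#' @export
pearson_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Interpret a correlation coefficient's strength
#'
#' Band membership with half-open intervals: weak for `0 <= rho < 0.3`,
#' moderate for `0.3 <= rho < 0.5`, strong for `0.5 <= rho <= 1`. Negative
#' coefficients are banded by absolute value.
#'
#' @param rho Correlation coefficient(s) in `[-1, 1]`.
#' @return Character vector: `"weak"`, `"moderate"` or `"strong"` (`NA` for
#'   missing input).
#' @export
interpret_strength <- function(rho) {
  r <- abs(rho)
  out <- rep(NA_character_, length(r))
  out[!is.na(r) & r < 0.3] <- "weak"
  out[!is.na(r) & r >= 0.3 & r < 0.5] <- "moderate"
  out[!is.na(r) & r >= 0.5] <- "strong"
  out
}

#' Crowd-versus-expert correlation table
#'
#' Builds the full correlation report: for each combining strategy and each
#' expert, the Pearson correlation between crowd estimates and expert values
#' for the four measures (inner area, outer area, WAP, WTR), plus
#' expert-versus-expert rows when two or more experts are present. The
#' `"none"` strategy pairs every individual valid result with its task's
#' expert value. Tasks without valid results are excluded (they have no
#' estimate); `n_tasks` records the pairs actually used for each entry.
#'
#' @param measurements Per-result measurement table ([measure_results()]).
#' @param experts Expert measurement table ([measure_experts()]), possibly
#'   with several `expert_id` values.
#' @param strategies Character vector of combining strategies to report.
#' @param seed Seed for the `"random"` strategy.
#' @return A tibble: `strategy`, `expert_id`, `measure`, `rho`, `n_tasks`,
#'   `strength`. Entries with fewer than 2 comparable tasks are skipped with
#'   a warning.
#' @export
correlation_table <- function(measurements, experts,
                              strategies = c("none", "random", "median",
                                             "best"),
                              seed = 1L) {
  measures <- c(inner = "inner_area", outer = "outer_area",
                wap = "wap", wtr = "wtr")
  expert_ids <- sort(unique(experts$expert_id))
  out <- list()

  for (strat in strategies) {
    for (eid in expert_ids) {
      exp_e <- experts[experts$expert_id == eid, ]
      est <- combine_tasks(measurements, strat,
                           expert = exp_e, seed = seed)
      joined <- dplyr::inner_join(
        est, exp_e, by = "task_id", suffix = c("_crowd", "_expert"))
      if (nrow(joined) < 2L) {
        warning("fewer than 2 comparable tasks for strategy ", strat,
                " vs expert ", eid, "; entry skipped")
        next
      }
      for (mname in names(measures)) {
        col <- measures[[mname]]
        rho <- pearson_cor(joined[[paste0(col, "_crowd")]],
                           joined[[paste0(col, "_expert")]])
        out[[length(out) + 1L]] <- tibble::tibble(
          strategy = strat, expert_id = eid, measure = mname,
          rho = rho, n_tasks = nrow(joined),
          strength = interpret_strength(rho))
      }
    }
  }

  # expert-vs-expert rows
  if (length(expert_ids) >= 2L) {
    pairs <- utils::combn(expert_ids, 2, simplify = FALSE)
    for (p in pairs) {
      e1 <- experts[experts$expert_id == p[1], ]
      e2 <- experts[experts$expert_id == p[2], ]
      joined <- dplyr::inner_join(e1, e2, by = "task_id",
                                  suffix = c("_crowd", "_expert"))
      for (mname in names(measures)) {
        col <- measures[[mname]]
        rho <- pearson_cor(joined[[paste0(col, "_crowd")]],
                           joined[[paste0(col, "_expert")]])
        out[[length(out) + 1L]] <- tibble::tibble(
          strategy = paste0("expert_", p[1]), expert_id = p[2],
          measure = mname, rho = rho, n_tasks = nrow(joined),
          strength = interpret_strength(rho))
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Correlation as a function of the minimum-valid-results threshold
#'
#' For each `v`, restricts to tasks with at least `v` valid results,
#' median-combines and correlates against the expert. More valid results per
#' task generally indicates an easier image, so ratio measures are expected
#' to improve with `v`.
#'
#' @param measurements Per-result measurement table.
#' @param experts Expert measurement table for one expert.
#' @param v_range Integer vector of thresholds.
#' @return A tibble: `v`, `measure`, `rho`, `n_tasks`. A `v` that retains
#'   fewer than 2 tasks is reported with `rho = NA`.
#' @export
threshold_sweep <- function(measurements, experts, v_range = 1:20) {
  measures <- c(inner = "inner_area", outer = "outer_area",
                wap = "wap", wtr = "wtr")
  out <- list()
  for (v in v_range) {
    sub <- filter_min_valid(measurements, v)
    if (nrow(sub) == 0L) {
      out[[length(out) + 1L]] <- tibble::tibble(
        v = v, measure = names(measures), rho = NA_real_, n_tasks = 0L)
      next
    }
    est <- combine_median(sub)
    joined <- dplyr::inner_join(est, experts, by = "task_id",
                                suffix = c("_crowd", "_expert"))
    for (mname in names(measures)) {
      col <- measures[[mname]]
      rho <- if (nrow(joined) < 2L) NA_real_ else
        pearson_cor(joined[[paste0(col, "_crowd")]],
                    joined[[paste0(col, "_expert")]])
      out[[length(out) + 1L]] <- tibble::tibble(
        v = v, measure = mname, rho = rho, n_tasks = nrow(joined))
    }
  }
  dplyr::bind_rows(out)
}

#' Spearman rank correlation with a two-sided t-approximation p-value
#'
#' Rank correlation with average ranks for ties (so binary covariates such
#' as disease status are handled through midranks), with the two-sided
#' p-value from the t-approximation
#' `t = rho_s * sqrt((n - 2) / (1 - rho_s^2))` on `n - 2` degrees of
#' freedom.
#'
#' @param x,y Paired numeric vectors, `n >= 3` complete pairs.
#' @return A list with `rho` and `p_value`. All-tied input on either side
#'   yields `rho = NA`, `p_value = NA`.
#' @export
spearman_with_p <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  rho <- stats::cor(rx, ry)
  list(rho = rho, p_value = spearman_p_value(rho, n))
}

#' Two-sided p-value for a Spearman coefficient via the t-approximation
#'
#' @param rho Spearman coefficient.
#' @param n Number of pairs.
#' @return Two-sided p-value; exactly 0 when `|rho| = 1`.
#' @export
spearman_p_value <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(t_stat), df = n - 2)
}

#' Subject-level prediction of crowd quality
#'
#' Tests whether subject characteristics predict how well the crowd tracks
#' the expert, using each subject's crowd-expert inner-area correlation
#' (median combining) as the quality proxy. Five Spearman tests are run —
#' disease status (CF), FEV1, FVC, airway count, mean airway generation —
#' each two-sided, flagged at the raw threshold `alpha` and at the
#' Bonferroni-adjusted threshold `alpha / 5`.
#'
#' @param subjects Subject table: `subject_id`, `has_cf`, `fev1`, `fvc`,
#'   `n_airways`, `mean_generation`.
#' @param per_subject_rho Tibble with `subject_id` and `rho` (the quality
#'   proxy per subject). Subjects with missing covariates or missing rho are
#'   dropped with a warning.
#' @param alpha Raw significance threshold.
#' @return A tibble: `characteristic`, `rho`, `p_value`, `significant_raw`,
#'   `significant_adjusted`, with attributes `alpha` and `alpha_adjusted`.
#' @export
quality_prediction <- function(subjects, per_subject_rho, alpha = 0.05) {
  chars <- c("has_cf", "fev1", "fvc", "n_airways", "mean_generation")
  dat <- dplyr::inner_join(subjects, per_subject_rho, by = "subject_id")
  complete <- stats::complete.cases(dat[, c(chars, "rho")])
  if (!all(complete)) {
    warning(sum(!complete), " subject(s) dropped for missing values")
    dat <- dat[complete, ]
  }
  alpha_adj <- alpha / length(chars)
  rows <- lapply(chars, function(ch) {
    s <- spearman_with_p(dat[[ch]], dat$rho)
    tibble::tibble(characteristic = ch, rho = s$rho, p_value = s$p_value,
                   significant_raw = !is.na(s$p_value) & s$p_value < alpha,
                   significant_adjusted = !is.na(s$p_value) &
                     s$p_value < alpha_adj)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "alpha") <- alpha
  attr(out, "alpha_adjusted") <- alpha_adj
  attr(out, "n_subjects") <- nrow(dat)
  out
}

#' Per-subject crowd-expert correlations
#'
#' Median-combines each subject's tasks and correlates against one expert,
#' separately per subject, for all four measures.
#'
#' @param measurements Per-result measurement table.
#' @param experts Expert measurement table for one expert.
#' @param tasks Task table mapping `task_id` to `subject_id`.
#' @return A tibble: `subject_id`, `n_tasks`, `inner`, `outer`, `wap`,
#'   `wtr` (Pearson coefficients; `NA` where fewer than 2 tasks).
#' @export
per_subject_correlations <- function(measurements, experts, tasks) {
  est <- combine_median(measurements)
  joined <- dplyr::inner_join(est, experts, by = "task_id",
                              suffix = c("_crowd", "_expert"))
  joined <- dplyr::inner_join(joined,
                              tasks[, c("task_id", "subject_id")],
                              by = "task_id")
  dplyr::summarise(
    dplyr::group_by(joined, .data$subject_id),
    n_tasks = dplyr::n(),
    inner = pearson_cor(.data$inner_area_crowd, .data$inner_area_expert),
    outer = pearson_cor(.data$outer_area_crowd, .data$outer_area_expert),
    wap = pearson_cor(.data$wap_crowd, .data$wap_expert),
    wtr = pearson_cor(.data$wtr_crowd, .data$wtr_expert),
    .groups = "drop"
  )
}

#' Per-worker validity statistics
#'
#' Tallies each worker's results by validity status, computes the cumulative
#' contribution curve (workers sorted by decreasing output), and fits an
#' ordinary least-squares line of valid count on invalid count across
#' workers.
#'
#' @param labels Label table from [classify_results()].
#' @return A list: `workers` (tibble `worker_id`, `n_results`, `n_valid`,
#'   `n_invalid`, `n_multi_pair`), `cumulative` (tibble `worker_rank`,
#'   `n_results`, `cum_fraction`), and `fit` (list `slope`, `intercept` of
#'   `n_valid ~ n_invalid`).
#' @export
worker_statistics <- function(labels) {
  workers <- dplyr::summarise(
    dplyr::group_by(labels, .data$worker_id),
    n_results = dplyr::n(),
    n_valid = sum(.data$status == "valid"),
    n_invalid = sum(.data$status == "invalid"),
    n_multi_pair = sum(.data$status == "multi_pair"),
    .groups = "drop"
  )
  ord <- order(workers$n_results, decreasing = TRUE)
  cumulative <- tibble::tibble(
    worker_rank = seq_along(ord),
    n_results = workers$n_results[ord],
    cum_fraction = cumsum(workers$n_results[ord]) / sum(workers$n_results)
  )
  fit <- stats::lm(n_valid ~ n_invalid, data = workers)
  list(
    workers = workers,
    cumulative = cumulative,
    fit = list(slope = unname(stats::coef(fit)["n_invalid"]),
               intercept = unname(stats::coef(fit)["(Intercept)"]))
  )
}
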