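#' Combine valid results per task
#'
#' Aggregates the valid results of each task into one crowd estimate.
#' Three strategies are available, plus `"none"` which keeps every valid
#' result as its own (task-replicated) estimate:
#'
#' * `median` — element-wise median of the inner and outer areas across the
#'   task's valid results; WAP/WTR and diameters are recomputed from the
#'   median areas, never averaged from per-result ratios. Even-length medians
#'   are the mean of the two central values.
#' * `random` — one uniformly drawn valid result per task. Draws use one
#'   seeded stream per call, visiting tasks in sorted `task_id` order, so
#'   the output is reproducible regardless of input row order.
#' * `best` — the valid result closest to the expert reference in Euclidean
#'   distance on the (inner_area, outer_area) plane; an optimistic bound on
#'   crowd quality. Ties break to the smallest `result_id`.
#'
#' Tasks with no valid results produce no estimate and are thereby excluded
#' from downstream correlation analyses.
#'
#' @param measurements Per-result measurement table from [measure_results()].
#' @param strategy One of `"median"`, `"random"`, `"best"`, `"none"`.
#' @param expert Expert measurement table ([measure_experts()]) restricted to
#'   one expert; required for `strategy = "best"`.
#' @param seed Integer seed; required for `strategy = "random"`.
#' @return A tibble with `task_id`, `strategy`, `n_valid` and the
#'   [airway_measures()] columns (for `"none"`, also `result_id`).
#' @examples
#' m <- airway_measures(c(9, 10, 12), c(20, 21, 25))
#' m$task_id <- "t1"; m$result_id <- 1:3; m$worker_id <- "w"
#' combine_tasks(m, "median")
#' @export
combine_tasks <- function(measurements, strategy = c("median", "random",
                                                     "best", "none"),
                          expert = NULL, seed = NULL) {
  strategy <- match.arg(strategy)
  switch(strategy,
         median = combine_median(measurements),
         random = combine_random(measurements, seed),
         best = combine_best(measurements, expert),
         none = combine_none(measurements))
}

n_valid_per_task <- function(measurements) {
  dplyr::summarise(dplyr::group_by(measurements, .data$task_id),
                   n_valid = dplyr::n(), .groups = "drop")
}

#' @rdname combine_tasks
#' @export
combine_median <- function(measurements) {
  agg <- dplyr::summarise(
    dplyr::group_by(measurements, .data$task_id),
    n_valid = dplyr::n(),
    inner_area = stats::median(.data$inner_area),
    outer_area = stats::median(.data$outer_area),
    .groups = "drop"
  )
  finish_combined(agg, "median")
}

#' @rdname combine_tasks
#' @export
combine_random <- function(measurements, seed) {
  if (is.null(seed)) stop("random combining requires a seed", call. = FALSE)
  tasks <- sort(unique(measurements$task_id))
  picked <- with_local_seed(seed, {
    vapply(tasks, function(tid) {
      rows <- which(measurements$task_id == tid)
      # candidates visited in result_id order so the draw is invariant to
      # the row order of the input table
      rows <- rows[order(measurements$result_id[rows])]
      rows[sample.int(length(rows), 1L)]
    }, integer(1))
  })
  sel <- measurements[picked, ]
  nv <- n_valid_per_task(measurements)
  agg <- tibble::tibble(
    task_id = tasks,
    n_valid = nv$n_valid[match(tasks, nv$task_id)],
    inner_area = sel$inner_area,
    outer_area = sel$outer_area
  )
  finish_combined(agg, "random")
}

#' @rdname combine_tasks
#' @export
combine_best <- function(measurements, expert) {
  if (is.null(expert)) stop("best combining requires an expert reference",
                            call. = FALSE)
  joined <- dplyr::inner_join(
    measurements,
    tibble::tibble(task_id = expert$task_id,
                   exp_inner = expert$inner_area,
                   exp_outer = expert$outer_area),
    by = "task_id"
  )
  if (nrow(joined) == 0L) {
    return(finish_combined(tibble::tibble(task_id = joined$task_id,
                                          n_valid = integer(0),
                                          inner_area = numeric(0),
                                          outer_area = numeric(0)), "best"))
  }
  joined$dist <- sqrt((joined$inner_area - joined$exp_inner)^2 +
                        (joined$outer_area - joined$exp_outer)^2)
  joined <- joined[order(joined$task_id, joined$dist, joined$result_id), ]
  best <- joined[!duplicated(joined$task_id), ]
  nv <- n_valid_per_task(measurements)
  agg <- tibble::tibble(
    task_id = best$task_id,
    n_valid = nv$n_valid[match(best$task_id, nv$task_id)],
    inner_area = best$inner_area,
    outer_area = best$outer_area
  )
  finish_combined(agg, "best")
}

combine_none <- function(measurements) {
  nv <- n_valid_per_task(measurements)
  out <- dplyr::bind_cols(
    tibble::tibble(task_id = measurements$task_id,
                   result_id = measurements$result_id,
                   strategy = "none",
                   n_valid = nv$n_valid[match(measurements$task_id,
                                              nv$task_id)]),
    airway_measures(measurements$inner_area, measurements$outer_area)
  )
  out
}

finish_combined <- function(agg, strategy) {
  if (nrow(agg) == 0L) {
    return(tibble::tibble(task_id = agg$task_id, strategy = character(0),
                          n_valid = integer(0),
                          airway_measures(1, 1)[0, ]))
  }
  dplyr::bind_cols(
    tibble::tibble(task_id = agg$task_id, strategy = strategy,
                   n_valid = agg$n_valid),
    airway_measures(agg$inner_area, agg$outer_area)
  )
}

#' Keep only tasks with at least v valid results
#'
#' @param measurements Per-result measurement table ([measure_results()]).
#' @param v Minimum number of valid results a task must have.
#' @return The subset of `measurements` whose tasks have `>= v` valid
#'   results.
#' @export
filter_min_valid <- function(measurements, v) {
  if (v < 1) stop("v must be at least 1", call. = FALSE)
  nv <- n_valid_per_task(measurements)
  keep <- nv$task_id[nv$n_valid >= v]
  measurements[measurements$task_id %in% keep, ]
}

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}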