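#' Classify crowd results as valid, invalid, or multi-pair
#'
#' Applies the validity filter to every result in an annotation table. A
#' result is the set of ellipses one worker submitted for one task; it is
#' valid only if it consists of exactly two resized, overlapping ellipses.
#' The decision order is:
#'
#' 1. four or more ellipses: `multi_pair` (excluded separately, not folded
#'    into the wrong-count category);
#' 2. ellipse count not equal to 2: `invalid` / `wrong_ellipse_count`; a
#'    single small circle in the top-right corner additionally gets
#'    `no_airway = TRUE` (the instructed way to indicate no visible airway);
#' 3. an unresized default ellipse (circle-shaped with both semi-axes within
#'    `size_tolerance` of the tool's `default_size`): `invalid` /
#'    `not_resized`. One unresized ellipse suffices: its measurement would be
#'    meaningless, so the pair cannot be used;
#' 4. the two ellipses do not overlap: `invalid` / `not_overlapping`;
#' 5. otherwise `valid` / `ok`.
#'
#' @param results Data frame with one row per ellipse: columns `result_id`,
#'   `task_id`, `worker_id`, `cx`, `cy`, `a`, `b`, `rotation`. Results with
#'   zero ellipses cannot be represented as rows and are assumed absent.
#' @param frame An [image_frame()].
#' @param default_size Default semi-axis of the annotation tool's starting
#'   circle, in pixels.
#' @param size_tolerance Relative tolerance used both for "same size as the
#'   default" and for "circle-shaped".
#' @param corner_fraction,size_fraction Corner-marker thresholds, see
#'   [is_corner_marker()].
#' @return A tibble with one row per result: `result_id`, `task_id`,
#'   `worker_id`, `n_annotations`, `status` (`valid`/`invalid`/`multi_pair`),
#'   `reason` (`ok`/`wrong_ellipse_count`/`not_resized`/`not_overlapping`/
#'   `multiple_pairs`), `no_airway` (logical).
#' @examples
#' res <- simulate_crowd(generate_cohort(n_subjects = 2, seed = 1)$truth,
#'                       worker_population(n_workers = 30, seed = 2),
#'                       results_per_task = 5, seed = 3)
#' labels <- classify_results(res$results)
#' tabulate_validity(labels)
#' @export
classify_results <- function(results, frame = image_frame(),
                             default_size = 50, size_tolerance = 0.02,
                             corner_fraction = 0.2, size_fraction = 0.1) {
  check_results_columns(results)
  if (nrow(results) == 0L) {
    return(tibble::tibble(
      result_id = results$result_id, task_id = results$task_id,
      worker_id = results$worker_id, n_annotations = integer(0),
      status = character(0), reason = character(0), no_airway = logical(0)
    ))
  }
  if (any(results$a <= 0 | results$b <= 0)) {
    stop("invalid geometry: semi-axes must be strictly positive", call. = FALSE)
  }

  grp <- dplyr::summarise(
    dplyr::group_by(results, .data$result_id),
    task_id = .data$task_id[1],
    worker_id = .data$worker_id[1],
    n_annotations = dplyr::n(),
    .groups = "drop"
  )

  status <- rep("invalid", nrow(grp))
  reason <- rep("wrong_ellipse_count", nrow(grp))
  no_airway <- rep(FALSE, nrow(grp))

  status[grp$n_annotations >= 4L] <- "multi_pair"
  reason[grp$n_annotations >= 4L] <- "multiple_pairs"

  # single-annotation results: flag instructed "no airway" corner markers
  singles <- grp$result_id[grp$n_annotations == 1L]
  if (length(singles) > 0L) {
    rows <- results[match(singles, results$result_id), ]
    marker <- corner_marker_vec(rows$cx, rows$cy, rows$a, rows$b, frame,
                                corner_fraction, size_fraction)
    no_airway[match(singles, grp$result_id)] <- marker
  }

  # pairs: apply the resized and overlap rules
  pairs <- grp$result_id[grp$n_annotations == 2L]
  if (length(pairs) > 0L) {
    sub <- results[results$result_id %in% pairs, ]
    sub <- sub[order(match(sub$result_id, pairs)), ]
    first <- sub[seq(1L, nrow(sub), by = 2L), ]
    second <- sub[seq(2L, nrow(sub), by = 2L), ]

    unresized <- is_default_circle(first$a, first$b, default_size, size_tolerance) |
      is_default_circle(second$a, second$b, default_size, size_tolerance)
    overlap <- overlap_vec(first$cx, first$cy, first$a, first$b, first$rotation,
                           second$cx, second$cy, second$a, second$b,
                           second$rotation)

    pair_reason <- ifelse(unresized, "not_resized",
                          ifelse(!overlap, "not_overlapping", "ok"))
    at <- match(pairs, grp$result_id)
    reason[at] <- pair_reason
    status[at] <- ifelse(pair_reason == "ok", "valid", "invalid")
  }

  tibble::tibble(
    result_id = grp$result_id, task_id = grp$task_id,
    worker_id = grp$worker_id, n_annotations = grp$n_annotations,
    status = status, reason = reason, no_airway = no_airway
  )
}

# An ellipse is an unresized tool default if it is circle-shaped and both
# semi-axes sit within the relative tolerance of the default size.
is_default_circle <- function(a, b, default_size, size_tolerance) {
  abs(a - default_size) <= size_tolerance * default_size &
    abs(b - default_size) <= size_tolerance * default_size &
    abs(a - b) <= size_tolerance * default_size
}

#' Tabulate validity counts and percentages
#'
#' Summarises a label table into counts and percentages per status and per
#' invalidity reason, plus the count of instructed "no airway" indications.
#' Percentages are computed on the full result count and rounded to one
#' decimal for reporting.
#'
#' @param labels Label table from [classify_results()] (columns `status`,
#'   `reason`, `no_airway`), or any data frame with those columns.
#' @return A list with `n_total`, a `by_status` tibble (`status`, `n`,
#'   `pct`), a `by_reason` tibble, and `n_no_airway`. An empty input gives an
#'   empty summary.
#' @export
tabulate_validity <- function(labels) {
  n_total <- nrow(labels)
  pct <- function(n) if (n_total == 0L) numeric(length(n)) else round(100 * n / n_total, 1)

  by_status <- dplyr::summarise(dplyr::group_by(labels, .data$status),
                                n = dplyr::n(), .groups = "drop")
  by_status$pct <- pct(by_status$n)
  by_reason <- dplyr::summarise(dplyr::group_by(labels, .data$reason),
                                n = dplyr::n(), .groups = "drop")
  by_reason$pct <- pct(by_reason$n)

  list(
    n_total = n_total,
    by_status = by_status,
    by_reason = by_reason,
    n_no_airway = sum(labels$no_airway)
  )
}

check_results_columns <- function(results) {
  required <- c("result_id", "task_id", "worker_id", "cx", "cy", "a", "b",
                "rotation")
  missing <- setdiff(required, names(results))
  if (length(missing) > 0L) {
    stop("results table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(results)
}
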