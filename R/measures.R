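#' Airway measures from inner and outer areas
#'
#' Given lumen (inner) and total airway (outer) cross-sectional areas, derives
#' the full measurement set used throughout the analysis:
#'
#' * equivalent-circle diameters `d_inner`, `d_outer` (airways are assumed
#'   circular so that area-only expert references and worker ellipses are
#'   comparable);
#' * wall thickness `WT = (d_outer - d_inner) / 2`;
#' * wall thickness ratio `WTR = WT / d_outer` (dimensionless, in `[0, 0.5)`);
#' * wall area percentage `WAP = (outer - inner) / outer * 100` (percent).
#'
#' WAP and WTR are invariant under any common rescaling of the two areas, so
#' the unit of the inputs (mm^2 throughout this package) does not affect them.
#'
#' @param inner_area,outer_area Areas in mm^2 (vectorized). Must satisfy
#'   `0 < inner_area <= outer_area`; equality gives the degenerate
#'   zero-thickness wall (WT = WTR = WAP = 0).
#' @return A tibble with columns `inner_area`, `outer_area`, `d_inner`,
#'   `d_outer`, `wall_thickness`, `wtr`, `wap`.
#' @examples
#' # concentric circles, radii 5 and 10
#' airway_measures(25 * pi, 100 * pi)
#' @export
airway_measures <- function(inner_area, outer_area) {
  if (any(inner_area <= 0)) {
    stop("invalid measure: inner area must be positive", call. = FALSE)
  }
  if (any(inner_area > outer_area)) {
    stop("invalid measure: inner area exceeds outer area", call. = FALSE)
  }
  d_inner <- equivalent_diameter(inner_area)
  d_outer <- equivalent_diameter(outer_area)
  wt <- (d_outer - d_inner) / 2
  tibble::tibble(
    inner_area = inner_area,
    outer_area = outer_area,
    d_inner = d_inner,
    d_outer = d_outer,
    wall_thickness = wt,
    wtr = wt / d_outer,
    wap = (outer_area - inner_area) / outer_area * 100
  )
}

#' Measure one valid crowd result
#'
#' Computes the airway measures for a single valid result. The smaller-area
#' ellipse is taken as the lumen and the larger as the outer wall boundary
#' (the interface does not label which ellipse is which); exactly equal areas
#' are rejected as degenerate rather than assigned arbitrarily. Pixel areas
#' are converted to mm^2 through `frame$mm_per_pixel^2`.
#'
#' @param annotations Data frame of the result's two ellipses (columns `cx`,
#'   `cy`, `a`, `b`, `rotation`).
#' @param frame An [image_frame()].
#' @return One-row tibble as from [airway_measures()].
#' @export
measure_result <- function(annotations, frame = image_frame()) {
  if (nrow(annotations) != 2L) {
    stop("a valid result has exactly two ellipses", call. = FALSE)
  }
  areas_px <- ellipse_area(annotations$a, annotations$b)
  if (areas_px[1] == areas_px[2]) {
    stop("degenerate result: the two ellipses have identical areas",
         call. = FALSE)
  }
  areas_mm <- sort(areas_px) * frame$mm_per_pixel^2
  airway_measures(areas_mm[1], areas_mm[2])
}

#' Measure all valid results in an annotation table
#'
#' Applies [measure_result()] to every result labeled `valid`, vectorized.
#' Results whose two ellipses have exactly equal areas are dropped with a
#' warning (degenerate; inner/outer cannot be told apart).
#'
#' @param results Annotation table (one row per ellipse), see
#'   [classify_results()].
#' @param labels Label table from [classify_results()].
#' @param frame An [image_frame()].
#' @return A tibble with one row per valid result: `result_id`, `task_id`,
#'   `worker_id` and the [airway_measures()] columns.
#' @export
measure_results <- function(results, labels, frame = image_frame()) {
  check_results_columns(results)
  valid_ids <- labels$result_id[labels$status == "valid"]
  sub <- results[results$result_id %in% valid_ids, ]
  empty <- tibble::tibble(
    result_id = sub$result_id[0], task_id = sub$task_id[0],
    worker_id = sub$worker_id[0],
    airway_measures(numeric(0) + 1, numeric(0) + 1)[0, ]
  )
  if (nrow(sub) == 0L) return(empty)

  sub <- sub[order(match(sub$result_id, valid_ids)), ]
  first <- sub[seq(1L, nrow(sub), by = 2L), ]
  second <- sub[seq(2L, nrow(sub), by = 2L), ]
  area1 <- ellipse_area(first$a, first$b) * frame$mm_per_pixel^2
  area2 <- ellipse_area(second$a, second$b) * frame$mm_per_pixel^2

  tie <- area1 == area2
  if (any(tie)) {
    warning(sum(tie), " degenerate result(s) with equal ellipse areas dropped")
    first <- first[!tie, ]; second <- second[!tie, ]
    area1 <- area1[!tie]; area2 <- area2[!tie]
  }
  if (length(area1) == 0L) return(empty)

  m <- airway_measures(pmin(area1, area2), pmax(area1, area2))
  dplyr::bind_cols(
    tibble::tibble(result_id = first$result_id, task_id = first$task_id,
                   worker_id = first$worker_id),
    m
  )
}

#' Measure expert references
#'
#' Experts record only the inner and outer areas; the same formulas as for
#' the crowd are applied, with diameters taken as equivalent-circle diameters
#' of the recorded areas.
#'
#' @param experts Data frame with columns `task_id`, `expert_id`,
#'   `inner_area`, `outer_area` (areas in mm^2).
#' @return A tibble with `task_id`, `expert_id` and the [airway_measures()]
#'   columns.
#' @export
measure_experts <- function(experts) {
  required <- c("task_id", "expert_id", "inner_area", "outer_area")
  missing <- setdiff(required, names(experts))
  if (length(missing) > 0L) {
    stop("expert table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(experts$inner_area >= experts$outer_area)) {
    stop("invalid reference: expert inner area must be below outer area",
         call. = FALSE)
  }
  dplyr::bind_cols(
    tibble::tibble(task_id = experts$task_id, expert_id = experts$expert_id),
    airway_measures(experts$inner_area, experts$outer_area)
  )
}
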