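#' Read a crowd results table
#'
#' Reads the one-row-per-ellipse CSV dialect: columns `result_id`,
#' `task_id`, `worker_id`, `cx`, `cy`, `a`, `b`, `rotation`, and optionally
#' `angle_unit` (`"radians"` or `"degrees"`; degrees are converted on read).
#' Rotations are normalized to `[0, pi)`. Rows with non-positive semi-axes
#' are rejected with their line numbers.
#'
#' @param path CSV file path.
#' @param columns Optional named character vector mapping the canonical
#'   column names to the names used in the file, e.g.
#'   `c(cx = "center_x")`, for foreign dialects.
#' @return A tibble suitable for [classify_results()].
#' @export
read_results <- function(path, columns = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(columns)) {
    for (canon in names(columns)) {
      names(raw)[names(raw) == columns[[canon]]] <- canon
    }
  }
  check_results_columns(raw)
  bad <- which(!is.finite(raw$a) | !is.finite(raw$b) | raw$a <= 0 | raw$b <= 0)
  if (length(bad) > 0L) {
    stop("malformed ellipse row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  if ("angle_unit" %in% names(raw)) {
    deg <- !is.na(raw$angle_unit) & raw$angle_unit == "degrees"
    raw$rotation[deg] <- raw$rotation[deg] * pi / 180
    raw$angle_unit <- NULL
  }
  raw$rotation <- normalize_rotation(raw$rotation)
  tibble::as_tibble(raw)
}

#' Write a crowd results table
#'
#' @param results Annotation table (one row per ellipse).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  check_results_columns(results)
  out <- results[, c("result_id", "task_id", "worker_id", "cx", "cy",
                     "a", "b", "rotation")]
  out$angle_unit <- "radians"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read an expert reference table
#'
#' CSV with `task_id`, `expert_id`, `inner_area`, `outer_area` and an
#' optional `area_unit` column (`"mm2"` or `"pixel2"`); pixel areas are
#' converted to mm^2 through `mm_per_pixel^2`.
#'
#' @param path CSV file path.
#' @param mm_per_pixel Conversion scale used when `area_unit` is
#'   `"pixel2"`.
#' @return A tibble with areas in mm^2.
#' @export
read_experts <- function(path, mm_per_pixel = 0.05508) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("task_id", "expert_id", "inner_area", "outer_area")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("expert table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if ("area_unit" %in% names(raw)) {
    px <- !is.na(raw$area_unit) & raw$area_unit == "pixel2"
    raw$inner_area[px] <- raw$inner_area[px] * mm_per_pixel^2
    raw$outer_area[px] <- raw$outer_area[px] * mm_per_pixel^2
    raw$area_unit <- NULL
  }
  tibble::as_tibble(raw)
}

#' Write an expert reference table
#'
#' @param experts Expert table with areas in mm^2.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_experts <- function(experts, path) {
  out <- experts[, c("task_id", "expert_id", "inner_area", "outer_area")]
  out$area_unit <- "mm2"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read and write subject and task tables
#'
#' `subjects.csv` carries `subject_id`, `has_cf`, `fev1`, `fvc`,
#' `n_airways`, `mean_generation`; `tasks.csv` maps `task_id` to
#' `subject_id`.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_subjects <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "has_cf", "fev1", "fvc", "n_airways",
                "mean_generation")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("subject table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(raw)
}

#' @rdname read_subjects
#' @param subjects Subject table.
#' @export
write_subjects <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_subjects
#' @export
read_tasks <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("task_id", "subject_id"), names(raw))
  if (length(missing) > 0L) {
    stop("task table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(raw)
}

#' @rdname read_subjects
#' @param tasks Task table.
#' @export
write_tasks <- function(tasks, path) {
  utils::write.csv(tasks[, c("task_id", "subject_id")], path,
                   row.names = FALSE)
  invisible(path)
}
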