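# Small fixture builders used across the test files.

# One annotation row.
ellipse_row <- function(result_id, cx, cy, a, b, rotation = 0,
                        task_id = "t1", worker_id = "w1") {
  tibble::tibble(result_id = result_id, task_id = task_id,
                 worker_id = worker_id, cx = cx, cy = cy, a = a, b = b,
                 rotation = rotation)
}

# A result made of several ellipses, each given as c(cx, cy, a, b[, rot]).
make_result <- function(result_id, ellipses, task_id = "t1",
                        worker_id = "w1") {
  rows <- lapply(ellipses, function(e) {
    rot <- if (length(e) >= 5) e[5] else 0
    ellipse_row(result_id, e[1], e[2], e[3], e[4], rot,
                task_id = task_id, worker_id = worker_id)
  })
  dplyr::bind_rows(rows)
}

# A canonical valid result: two concentric resized circles.
valid_pair <- function(result_id, r_inner = 25, r_outer = 40,
                       cx = 250, cy = 250, task_id = "t1",
                       worker_id = "w1") {
  make_result(result_id,
              list(c(cx, cy, r_inner, r_inner), c(cx, cy, r_outer, r_outer)),
              task_id = task_id, worker_id = worker_id)
}

# Monte-Carlo rejection-sampling estimate of an ellipse's area from its
# bounding box; independent of the closed form under test.
mc_ellipse_area <- function(e, n = 1e5) {
  rad <- max(e$a, e$b)
  x <- stats::runif(n, e$cx - rad, e$cx + rad)
  y <- stats::runif(n, e$cy - rad, e$cy + rad)
  dx <- x - e$cx
  dy <- y - e$cy
  u <- cos(e$rotation) * dx + sin(e$rotation) * dy
  v <- -sin(e$rotation) * dx + cos(e$rotation) * dy
  mean((u / e$a)^2 + (v / e$b)^2 < 1) * (2 * rad)^2
}

# Monte-Carlo estimate of the intersection area of two ellipses over the
# union bounding box; doubles as an overlap oracle.
mc_intersection_area <- function(e1, e2, n = 1e4) {
  r1 <- max(e1$a, e1$b); r2 <- max(e2$a, e2$b)
  xmin <- min(e1$cx - r1, e2$cx - r2); xmax <- max(e1$cx + r1, e2$cx + r2)
  ymin <- min(e1$cy - r1, e2$cy - r2); ymax <- max(e1$cy + r1, e2$cy + r2)
  x <- stats::runif(n, xmin, xmax)
  y <- stats::runif(n, ymin, ymax)
  inside <- function(e) {
    dx <- x - e$cx; dy <- y - e$cy
    u <- cos(e$rotation) * dx + sin(e$rotation) * dy
    v <- -sin(e$rotation) * dx + cos(e$rotation) * dy
    (u / e$a)^2 + (v / e$b)^2 < 1
  }
  mean(inside(e1) & inside(e2)) * (xmax - xmin) * (ymax - ymin)
}

random_ellipse <- function(frame_size = 500) {
  ellipse(stats::runif(1, 50, frame_size - 50),
          stats::runif(1, 50, frame_size - 50),
          stats::runif(1, 5, 60), stats::runif(1, 5, 60),
          stats::runif(1, 0, pi))
}

# A small simulated dataset shared by several tests.
small_simulation <- function(n_subjects = 4, results_per_task = 10,
                             n_workers = 60, seed = 42) {
  cohort <- generate_cohort(n_subjects = n_subjects,
                            tasks_per_subject = c(10, 20), seed = seed)
  workers <- worker_population(n_workers = n_workers, seed = seed + 1)
  sim <- simulate_crowd(cohort$truth, workers,
                        results_per_task = results_per_task,
                        seed = seed + 2)
  experts <- simulate_experts(cohort$truth, seed = seed + 3)
  list(cohort = cohort, workers = workers, sim = sim, experts = experts)
}
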