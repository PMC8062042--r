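test_that("pearson correlation: closed-form cases and missing-data policy", {
  x <- 1:10
  expect_equal(pearson_cor(x, 2 * x + 3), 1)
  expect_equal(pearson_cor(x, -x), -1)
  # hand-computed from the product-moment formula
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  # constant input: undefined, reported as missing (never 0)
  expect_true(is.na(pearson_cor(rep(1, 5), 1:5)))
  # incomplete pairs dropped first
  expect_equal(pearson_cor(c(1, 2, NA, 4), c(2, 4, 5, 8)), 1)
  # affine rescaling of either side cannot change the coefficient
  set.seed(11)
  a <- rnorm(30); b <- a + rnorm(30, 0, 0.5)
  expect_equal(pearson_cor(a, b), pearson_cor(100 * a - 3, 0.01 * b + 7))
})

test_that("strength bands use half-open intervals", {
  expect_equal(interpret_strength(0), "weak")
  expect_equal(interpret_strength(0.29999), "weak")
  expect_equal(interpret_strength(0.3), "moderate")
  expect_equal(interpret_strength(0.49999), "moderate")
  expect_equal(interpret_strength(0.5), "strong")
  expect_equal(interpret_strength(1), "strong")
  # negative coefficients banded by absolute value
  expect_equal(interpret_strength(-0.4), "moderate")
  expect_true(is.na(interpret_strength(NA_real_)))
})

test_that("a crowd identical to the expert correlates perfectly", {
  s <- small_simulation()
  truth <- s$cohort$truth
  tm <- true_measures(truth)
  # expert recording exact truth
  experts <- tibble::tibble(task_id = truth$task_id, expert_id = 1,
                            inner_area = tm$inner_area,
                            outer_area = tm$outer_area)
  em <- measure_experts(experts)
  # "crowd" = one exact result per task
  meas <- tm
  meas$result_id <- seq_len(nrow(meas))
  meas$worker_id <- "w1"
  ct <- correlation_table(meas, em, strategies = c("none", "median"))
  expect_true(all(abs(ct$rho - 1) < 1e-12))
  expect_true(all(ct$strength == "strong"))
})

test_that("shuffled expert pairing destroys the correlation", {
  set.seed(21)
  n <- 1000
  inner <- rlnorm(n, log(5), 0.5)
  meas <- airway_measures(inner, inner + 2)
  meas$task_id <- sprintf("t%04d", 1:n)
  meas$result_id <- 1:n
  meas$worker_id <- "w"
  shuffled <- airway_measures(sample(inner), sample(inner) + 30)
  shuffled$task_id <- meas$task_id
  shuffled$expert_id <- 1
  est <- combine_median(meas)
  joined <- dplyr::inner_join(est, shuffled, by = "task_id",
                              suffix = c("_crowd", "_expert"))
  rho <- pearson_cor(joined$inner_area_crowd, joined$inner_area_expert)
  expect_lt(abs(rho), 0.1)
})

test_that("correlation rises monotonically as crowd noise vanishes", {
  cohort <- generate_cohort(n_subjects = 6, tasks_per_subject = c(20, 30),
                            seed = 31)
  em <- measure_experts(simulate_experts(cohort$truth,
                                         expert_noise_scale = 0,
                                         n_experts = 1, seed = 32))
  rhos <- vapply(c(0.30, 0.15, 0.05, 0.01), function(sigma) {
    w <- worker_population(n_workers = 60,
                           behavior_probs = c(careful = 1,
                                              no_airway_prone = 0,
                                              sloppy_single = 0,
                                              non_resizer = 0, spammer = 0),
                           noise_scale = sigma, lapse_rate = 0, seed = 33)
    sim <- simulate_crowd(cohort$truth, w, results_per_task = 10, seed = 34)
    lab <- classify_results(sim$results)
    meas <- measure_results(sim$results, lab)
    est <- combine_median(meas)
    joined <- dplyr::inner_join(est, em, by = "task_id",
                                suffix = c("_crowd", "_expert"))
    pearson_cor(joined$inner_area_crowd, joined$inner_area_expert)
  }, numeric(1))
  expect_true(all(diff(rhos) > 0))
  expect_gt(rhos[4], 0.999)
})

test_that("threshold sweep: v = 1 is the unthresholded analysis", {
  s <- small_simulation(n_subjects = 6, results_per_task = 15, seed = 41)
  lab <- classify_results(s$sim$results)
  meas <- measure_results(s$sim$results, lab)
  em <- measure_experts(s$experts)
  e1 <- em[em$expert_id == 1, ]
  sweep <- threshold_sweep(meas, e1, v_range = 1:10)
  base <- combine_median(meas)
  joined <- dplyr::inner_join(base, e1, by = "task_id",
                              suffix = c("_crowd", "_expert"))
  expect_equal(sweep$rho[sweep$v == 1 & sweep$measure == "inner"],
               pearson_cor(joined$inner_area_crowd,
                           joined$inner_area_expert))
  # retained-task counts are non-increasing in v
  n_by_v <- sweep$n_tasks[sweep$measure == "inner"]
  expect_true(all(diff(n_by_v) <= 0))
})

test_that("ratio-measure correlation trends upward with the threshold", {
  # harder tasks attract more "no airway" markers and are outlined less
  # accurately, so high-v tasks are both easier and better measured
  cohort <- generate_cohort(n_subjects = 8, tasks_per_subject = c(60, 80),
                            seed = 51)
  w <- worker_population(n_workers = 120,
                         behavior_probs = c(careful = 0.45,
                                            no_airway_prone = 0.40,
                                            sloppy_single = 0.05,
                                            non_resizer = 0.05,
                                            spammer = 0.05),
                         noise_scale = 0.10, productivity_sdlog = 0,
                         seed = 52)
  sim <- simulate_crowd(cohort$truth, w, results_per_task = 20,
                        marker_base = 0.05, marker_slope = 0.95,
                        difficulty_noise = 3, seed = 53)
  lab <- classify_results(sim$results)
  meas <- measure_results(sim$results, lab)
  em <- measure_experts(simulate_experts(cohort$truth,
                                         expert_noise_scale = 0,
                                         n_experts = 1, seed = 54))
  sweep <- threshold_sweep(meas, em, v_range = 1:14)
  wap <- sweep[sweep$measure == "wap" & !is.na(sweep$rho), ]
  expect_gt(cor(wap$v, wap$rho, method = "spearman"), 0)
})

test_that("spearman handles monotone transforms, ties and the null p", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  s <- spearman_with_p(x, exp(x))
  expect_equal(s$rho, 1)
  expect_equal(s$p_value, 0)
  # binary covariate through midranks: finite rho
  set.seed(61)
  s2 <- spearman_with_p(rep(c(0, 1), each = 12), rnorm(24))
  expect_true(is.finite(s2$rho))
  # all-tied input: undefined
  s3 <- spearman_with_p(rep(1, 10), rnorm(10))
  expect_true(is.na(s3$rho))
  # agrees with the reference rank correlation
  a <- rnorm(24); b <- rnorm(24)
  expect_equal(spearman_with_p(a, b)$rho,
               cor(a, b, method = "spearman"))
})

test_that("t-approximation reproduces the printed p at n = 24", {
  expect_equal(spearman_p_value(-0.265, 24), 0.211, tolerance = 0.02)
})

test_that("spearman type-I error is calibrated at n = 24", {
  set.seed(71)
  rejections <- vapply(1:2000, function(i) {
    spearman_with_p(rnorm(24), rnorm(24))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("quality prediction runs five tests with Bonferroni adjustment", {
  set.seed(81)
  subjects <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:24),
    has_cf = rbinom(24, 1, 0.5),
    fev1 = rnorm(24, 90, 15), fvc = rnorm(24, 95, 15),
    n_airways = sample(18:278, 24), mean_generation = rnorm(24, 6.5, 0.8)
  )
  rho <- tibble::tibble(subject_id = subjects$subject_id,
                        rho = runif(24, 0.6, 1))
  qp <- quality_prediction(subjects, rho)
  expect_equal(nrow(qp), 5L)
  expect_equal(attr(qp, "alpha_adjusted"), 0.01)
  # a characteristic identical to the quality vector is maximally
  # significant at both levels
  subjects2 <- subjects
  subjects2$fev1 <- rho$rho
  qp2 <- quality_prediction(subjects2, rho)
  row <- qp2[qp2$characteristic == "fev1", ]
  expect_equal(row$rho, 1)
  expect_true(row$significant_raw && row$significant_adjusted)
})

test_that("null subjects rarely show more than one significant test", {
  set.seed(91)
  clean <- vapply(1:500, function(i) {
    subjects <- tibble::tibble(
      subject_id = 1:24, has_cf = rbinom(24, 1, 0.5),
      fev1 = rnorm(24), fvc = rnorm(24),
      n_airways = sample(10:300, 24), mean_generation = rnorm(24)
    )
    rho <- tibble::tibble(subject_id = 1:24, rho = runif(24))
    sum(quality_prediction(subjects, rho)$significant_raw) <= 1
  }, logical(1))
  expect_gte(mean(clean), 0.8)
})

test_that("worker statistics tally, fit and accumulate correctly", {
  set.seed(95)
  # planted 60/40 valid/invalid mix across a worker population
  n_results <- pmax(1, round(rlnorm(300, 3, 1)))
  labels <- dplyr::bind_rows(lapply(seq_along(n_results), function(w) {
    n <- n_results[w]
    valid <- rbinom(1, n, 0.6)
    tibble::tibble(
      result_id = paste0(w, "_", seq_len(n)),
      task_id = "t", worker_id = sprintf("w%03d", w),
      n_annotations = 2L,
      status = c(rep("valid", valid), rep("invalid", n - valid)),
      reason = "x", no_airway = FALSE
    )
  }))
  ws <- worker_statistics(labels)
  expect_true(all(ws$workers$n_results ==
                    ws$workers$n_valid + ws$workers$n_invalid +
                    ws$workers$n_multi_pair))
  # slope of valid ~ invalid recovers the planted 0.6/0.4 ratio
  expect_equal(ws$fit$slope, 1.5, tolerance = 0.1)
  # cumulative contribution reaches exactly 100%
  expect_equal(ws$cumulative$cum_fraction[nrow(ws$cumulative)], 1)
  expect_true(all(diff(ws$cumulative$n_results) <= 0))
})

test_that("per-subject correlations are consistent with pooled analysis", {
  s <- small_simulation(n_subjects = 5, results_per_task = 12, seed = 97)
  lab <- classify_results(s$sim$results)
  meas <- measure_results(s$sim$results, lab)
  e1 <- measure_experts(s$experts[s$experts$expert_id == 1, ])
  tasks <- s$cohort$truth[, c("task_id", "subject_id")]
  per <- per_subject_correlations(meas, e1, tasks)
  expect_equal(sort(per$subject_id), sort(s$cohort$subjects$subject_id))
  expect_true(all(per$inner[per$n_tasks >= 2] <= 1, na.rm = TRUE))
  # a single subject's entry equals the pooled analysis restricted to it
  sid <- per$subject_id[which.max(per$n_tasks)]
  keep <- tasks$task_id[tasks$subject_id == sid]
  est <- combine_median(meas[meas$task_id %in% keep, ])
  joined <- dplyr::inner_join(est, e1, by = "task_id",
                              suffix = c("_crowd", "_expert"))
  expect_equal(per$inner[per$subject_id == sid],
               pearson_cor(joined$inner_area_crowd,
                           joined$inner_area_expert))
})
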