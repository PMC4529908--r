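test_that("partition_remaining chunks with a remainder group", {
  set.seed(1)
  g <- partition_remaining(11:17, 3)
  expect_length(g, 3L)
  expect_identical(lengths(g), c(3L, 3L, 1L))
  expect_setequal(unlist(g), 11:17)
  g2 <- partition_remaining(1:6, 2)
  expect_identical(lengths(g2), c(2L, 2L, 2L))
  expect_identical(partition_remaining(integer(0), 4), list())
  expect_error(partition_remaining(1:4, 0), "add_size")
})

test_that("partitioning is deterministic under a fixed seed", {
  a <- farms:::with_seed(99, partition_remaining(1:20, 6))
  b <- farms:::with_seed(99, partition_remaining(1:20, 6))
  expect_identical(a, b)
  expect_identical(farms:::with_seed(99, partition_remaining(1:20, 6,
                                                             shuffle = FALSE)),
                   farms:::with_seed(12, partition_remaining(1:20, 6,
                                                             shuffle = FALSE)))
})

test_that("starting at the global optimum is a one-iteration fixed point", {
  cohort <- generate_cohort(n = 300, p = 8, n_signal = 2, beta = c(2, -2),
                            noise_sd = 0.5, seed = 4)
  opt <- all_subsets_regression(cohort$data, criterion = "BIC")
  res <- run_farms(cohort$data,
                   farms_config(start_vars = opt$subset, add_size = 3,
                                seed = 1))
  # nothing can strictly improve the exhaustive BIC optimum
  expect_identical(res$final_fit$subset, opt$subset)
  expect_identical(res$n_iterations, 1L)
  expect_true(res$converged)
})

test_that("a single all-covering pool reproduces the exhaustive optimum", {
  for (r in 1:6) {
    cohort <- generate_cohort(n = 120, p = 10, n_signal = 3, seed = 40 + r)
    d <- cohort$data
    oracle <- naive_all_subsets_oracle(d, pool = 1:10, c1 = "BIC")
    for (start_seed in c(1, 7, 23)) {
      res <- run_farms(d, farms_config(start_size = 5, add_size = 10,
                                       seed = start_seed))
      expect_identical(res$final_fit$subset,
                       as.integer(oracle$best_overall$subset))
    }
  }
})

test_that("the trace strictly improves and forced variables never leave", {
  cohort <- strong_signal_cohort(seed = 3, n = 200, p = 30)
  forced <- cohort$truth$support[1]
  res <- run_farms(cohort$data,
                   farms_config(start_size = 4, add_size = 5,
                                forced = forced, seed = 6))
  expect_farms_invariants(res, forced = forced)
  expect_gte(res$n_iterations, 1L)
  expect_true(forced %in% res$final_fit$subset)
  # also under c2 = AIC
  res2 <- run_farms(cohort$data,
                    farms_config(start_size = 4, add_size = 5, c2 = "AIC",
                                 forced = forced, seed = 6))
  expect_farms_invariants(res2, forced = forced)
})

test_that("max_model_size caps the final model, forced counting toward it", {
  cohort <- strong_signal_cohort(seed = 8, n = 250, p = 30)
  res <- run_farms(cohort$data,
                   farms_config(start_size = 2, add_size = 4,
                                forced = 1, max_model_size = 4, seed = 2))
  expect_lte(length(res$final_fit$subset), 4L)
  expect_true(all(res$inclusion[, 1] == 1L))
})

test_that("identical seeds give identical runs", {
  cohort <- strong_signal_cohort(seed = 9, n = 200, p = 25)
  a <- run_farms(cohort$data, farms_config(start_size = 3, add_size = 4,
                                           seed = 77))
  b <- run_farms(cohort$data, farms_config(start_size = 3, add_size = 4,
                                           seed = 77))
  expect_identical(a$final_fit$subset, b$final_fit$subset)
  expect_identical(a$inclusion, b$inclusion)
  expect_equal(a$trace$bic, b$trace$bic)
})

test_that("a zero time budget returns the starting model unconverged", {
  cohort <- strong_signal_cohort(seed = 10, n = 200, p = 25)
  res <- run_farms(cohort$data,
                   farms_config(start_size = 3, add_size = 4,
                                max_time_s = 0, seed = 1))
  expect_false(res$converged)
  expect_identical(res$n_iterations, 1L)
})

test_that("invalid configurations are rejected", {
  d <- rand_design(30, 5, seed = 12)
  expect_error(run_farms(d, farms_config(start_size = 6, seed = 1)),
               "exceeds the number of available variables")
  expect_error(run_farms(d, farms_config(start_size = 2, forced = 1,
                                         start_vars = 1, seed = 1)),
               "overlap")
  expect_error(farms_config(start_size = 0), "start_size")
  expect_error(run_farms(d, farms_config(start_size = 2, forced = 1:2,
                                         max_model_size = 1, seed = 1)),
               "max_model_size")
})

test_that("robustness_grid reruns cells and summarizes them", {
  cohort <- generate_cohort(n = 150, p = 12, n_signal = 2,
                            beta = c(1.5, -1.5), noise_sd = 0.6, seed = 20)
  g <- robustness_grid(cohort$data, farms_config(seed = 5),
                       start_sizes = c(2, 4), add_sizes = c(2, 3, 4),
                       replicates = 2)
  expect_s3_class(g, "farms_grid")
  expect_identical(nrow(g), 12L)
  expect_true(all(is.na(g$error)))
  # a degenerate 1x1 grid is one run_farms with the derived seed
  g1 <- robustness_grid(cohort$data, farms_config(seed = 5),
                        start_sizes = 3, add_sizes = 3)
  ref <- run_farms(cohort$data, farms_config(start_size = 3, add_size = 3,
                                             seed = g1$seed[1]))
  expect_identical(g1$vars,
                   paste(cohort$data$names[ref$final_fit$subset],
                         collapse = ","))
  expect_identical(g1$n_iterations, ref$n_iterations)
})

test_that("grid cells that error are recorded, not fatal", {
  d <- rand_design(30, 4, seed = 13)
  g <- robustness_grid(d, farms_config(seed = 2),
                       start_sizes = c(2, 6), add_sizes = 2)
  expect_true(is.na(g$error[g$start_size == 2]))
  expect_match(g$error[g$start_size == 6], "exceeds")
})
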