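test_that("an empty pool returns the forced-only model", {
  d <- rand_design(30, 10, seed = 1)
  res <- search_best_subsets(d, pool = integer(0), forced = 10, c1 = "BIC")
  expect_identical(res$best_overall$subset, 10L)
  expect_identical(res$n_candidates, 1)
})

test_that("a 5-variable pool with one forced variable spans 32 candidates", {
  # toy shape: 3 starting + 2 added free variables, variable 10 forced
  d <- rand_design(40, 10, seed = 2)
  res <- search_best_subsets(d, pool = c(1, 2, 3, 4, 5), forced = 10,
                             c1 = "BIC")
  expect_identical(res$n_candidates, 2^5)
  for (fit in res$best_per_size) expect_true(10L %in% fit$subset)
})

test_that("search agrees with the naive oracle across criteria", {
  set.seed(33)
  for (r in 1:30) {
    n <- 50 + sample(0:30, 1); p <- sample(4:10, 1)
    d <- rand_design(n, p, seed = 2000 + r)
    forced <- if (r %% 3 == 0) sample(p, 1) else integer(0)
    pool <- setdiff(seq_len(p), forced)
    c1 <- sample(c("BIC", "AIC", "ADJR2", "CP", "RSS"), 1)
    full <- fit_ols(d, seq_len(p))
    s2 <- full$rss / (full$n - full$k)
    a <- search_best_subsets(d, pool, forced, c1 = c1, c2 = "BIC",
                             sigma2_full = s2)
    b <- naive_all_subsets_oracle(d, pool, forced, c1 = c1, c2 = "BIC",
                                  sigma2_full = s2)
    expect_identical(a$best_overall$subset, b$best_overall$subset)
    for (s in seq_along(a$best_per_size)) {
      expect_identical(a$best_per_size[[s]]$subset,
                       as.integer(b$best_per_size[[s]]$subset))
      expect_equal(a$best_per_size[[s]]$rss, b$best_per_size[[s]]$rss,
                   tolerance = 1e-8)
    }
  }
})

test_that("the overall winner is criterion-optimal among all candidates", {
  d <- rand_design(60, 8, seed = 5)
  res <- search_best_subsets(d, pool = 1:8, c1 = "BIC")
  best <- criterion_value(res$best_overall, "BIC")
  for (s in 0:8) for (sub in if (s == 0) list(integer(0)) else
                       asplit(combn(8, s), 2))
    expect_lte(best,
               criterion_value(fit_ols(d, as.integer(sub)), "BIC") + 1e-10)
})

test_that("per-size rss is non-increasing in subset size", {
  d <- rand_design(50, 9, seed = 6)
  res <- search_best_subsets(d, pool = 1:9, c1 = "BIC")
  rss <- vapply(res$best_per_size, `[[`, numeric(1), "rss")
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("the result does not depend on the order the pool is supplied", {
  d <- rand_design(45, 8, seed = 7)
  a <- search_best_subsets(d, pool = c(2, 5, 1, 8, 3, 7), forced = 4,
                           c1 = "AIC")
  b <- search_best_subsets(d, pool = c(8, 1, 7, 3, 2, 5), forced = 4,
                           c1 = "AIC")
  expect_identical(a$best_overall$subset, b$best_overall$subset)
  expect_equal(vapply(a$best_per_size, `[[`, numeric(1), "rss"),
               vapply(b$best_per_size, `[[`, numeric(1), "rss"))
})

test_that("max_free caps the number of free variables", {
  d <- rand_design(50, 8, seed = 8)
  res <- search_best_subsets(d, pool = 1:6, forced = 7, c1 = "BIC",
                             max_free = 2)
  expect_length(res$best_per_size, 3L)   # sizes 0, 1, 2
  for (fit in res$best_per_size)
    expect_lte(length(setdiff(fit$subset, 7L)), 2L)
  expect_identical(res$n_candidates, sum(choose(6, 0:2)))
})

test_that("oversized pools and overlapping sets are rejected", {
  d <- rand_design(40, 12, seed = 9)
  expect_error(search_best_subsets(d, pool = 1:12, c1 = "BIC",
                                   hard_cap = 10),
               "lower the adding-group size")
  expect_error(search_best_subsets(d, pool = 1:4, forced = 3, c1 = "BIC"),
               "overlap")
  expect_error(naive_all_subsets_oracle(d, pool = 1:4, forced = 4),
               "overlap")
})

test_that("a collinear pool falls back to direct enumeration and still wins", {
  d <- rand_design(40, 4, seed = 10)
  dd <- design_data(d$outcome, cbind(d$covariates, dup = d$covariates[, 2]))
  res <- search_best_subsets(dd, pool = 1:5, c1 = "BIC")
  # compare against exhaustive fit over all subsets excluding the duplicate
  ref <- naive_all_subsets_oracle(dd, pool = c(1, 2, 3, 4), c1 = "BIC")
  expect_equal(criterion_value(res$best_overall, "BIC"),
               ref$best_overall$value, tolerance = 1e-8)
})

test_that("size-monotone c1 needs a penalized c2 to pick a winner", {
  d <- rand_design(30, 5, seed = 11)
  expect_error(search_best_subsets(d, pool = 1:5, c1 = "RSS", c2 = "R2"),
               "penalized")
  res <- search_best_subsets(d, pool = 1:5, c1 = "RSS", c2 = "BIC")
  ref <- search_best_subsets(d, pool = 1:5, c1 = "BIC")
  expect_identical(res$best_overall$subset, ref$best_overall$subset)
})
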