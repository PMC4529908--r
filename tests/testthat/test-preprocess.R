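test_that("viral-load transform reproduces the printed log10 arithmetic", {
  expect_equal(round(transform_viral_load(37800), 3), 4.577)
  expect_equal(round(transform_viral_load(37240), 3), 4.571)
  expect_equal(round(transform_viral_load(131500), 3), 5.119)
  expect_equal(round(transform_viral_load(13310), 3), 4.124)
})

test_that("values under the detection limit are floored before the log", {
  expect_equal(transform_viral_load(30), log10(49))
  expect_equal(transform_viral_load(49.9), log10(49))
  expect_equal(transform_viral_load(50), log10(50))
  expect_error(transform_viral_load(c(100, -5, 0)), "position\\(s\\) 2, 3")
})

test_that("the transform is monotone non-decreasing", {
  v <- sort(c(runif(50, 1, 200), runif(50, 200, 1e6)))
  out <- transform_viral_load(v)
  expect_true(all(diff(out) >= 0))
})

test_that("Box-Cox lambda recovers its known limits", {
  set.seed(41)
  expect_lt(abs(boxcox_lambda(exp(rnorm(3000)))), 0.05)      # log-normal -> 0
  expect_lt(abs(boxcox_lambda(rnorm(3000, 50, 5)) - 1), 0.1) # normal -> 1
  expect_error(boxcox_lambda(5), "at least 2")
  expect_error(boxcox_lambda(rep(2, 10)), "constant")
  expect_error(boxcox_lambda(c(1, -1, 2)), "positive")
})

test_that("Box-Cox profile agrees with the MASS implementation", {
  library(MASS)
  set.seed(42)
  v <- rlnorm(400, 3, 0.8)
  ours <- boxcox_lambda(v)
  bc <- boxcox(v ~ 1, lambda = seq(-2, 2, 0.001), plotit = FALSE)
  expect_equal(as.numeric(ours), bc$x[which.max(bc$y)], tolerance = 0.002)
})

test_that("allele records binarize to carriage indicators", {
  rec <- data.frame(
    subject_id = c("s1", "s1", "s1", "s2", "s2"),
    locus = c("A", "A", "B", "A", "B"),
    allele = c("A*02", "A*02", "B*35", "A*01", "B*57"))
  m <- binarize_alleles(rec)
  expect_identical(colnames(m), c("A*01", "A*02", "B*35", "B*57"))
  expect_identical(m["s1", "A*02"], 1L)    # homozygote coded 1, not 2
  expect_identical(unname(m["s1", ]), c(0L, 1L, 1L, 0L))
  expect_identical(unname(m["s2", ]), c(1L, 0L, 0L, 1L))
  expect_true(all(m %in% 0:1))
})

test_that("more than two alleles per locus is rejected", {
  rec <- data.frame(subject_id = rep("s1", 3), locus = rep("A", 3),
                    allele = c("A*01", "A*02", "A*03"))
  expect_error(binarize_alleles(rec), "more than 2 alleles")
})

test_that("olp magnitudes binarize by positivity or threshold", {
  m <- matrix(c(0, 0.5, 2, 0, 1, 0), 2)
  expect_identical(binarize_olp(matrix(0, 3, 2)), matrix(0L, 3, 2))
  expect_identical(binarize_olp(m + 1, threshold = 0), matrix(1L, 2, 3))
  expect_identical(as.vector(binarize_olp(m)), c(0L, 1L, 1L, 0L, 1L, 0L))
  expect_identical(as.vector(binarize_olp(m, threshold = 1)),
                   c(0L, 0L, 1L, 0L, 1L, 0L))
  expect_error(binarize_olp(-m), "negative")
})

test_that("feature expansion counts columns and drops binary squares", {
  d <- rand_design(30, 5, seed = 43)
  di <- expand_features(d, interactions = TRUE)
  expect_length(di$names, 5 + choose(5, 2))
  dq <- expand_features(d, quadratic = TRUE)
  expect_length(dq$names, 10)
  db <- rand_design(30, 4, seed = 44, binary = TRUE, freq = 0.5)
  expect_warning(dbq <- expand_features(db, quadratic = TRUE),
                 "constant or duplicate")
  expect_identical(dbq$names, db$names)   # squares of 0/1 add nothing
  d2 <- rand_design(20, 2, seed = 45)
  expect_length(expand_features(d2, interactions = TRUE)$names, 3)
})

test_that("the univariate screen matches a hand-computed pooled t", {
  y <- c(1, 2, 3, 4, 5, 6)
  x <- c(0, 0, 0, 1, 1, 1)
  d <- design_data(y, matrix(x), "g")
  row <- univariate_screen(d)
  # pooled t for groups {1,2,3} vs {4,5,6}: sp = 1, t = 3 / sqrt(2/3)
  t_hand <- (mean(y[4:6]) - mean(y[1:3])) / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(row$t_stat, t_hand, tolerance = 1e-12)
  expect_equal(row$p_value, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  # and against the stock t.test as an external cross-check
  tt <- t.test(y[x == 1], y[x == 0], var.equal = TRUE)
  expect_equal(row$t_stat, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(row$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("identical group outcomes give t = 0, p = 1", {
  d <- design_data(c(1, 2, 3, 1, 2, 3), matrix(c(0, 0, 0, 1, 1, 1)), "g")
  row <- univariate_screen(d)
  expect_equal(row$t_stat, 0)
  expect_equal(row$p_value, 1)
})

test_that("screen validation and untestable columns", {
  d <- design_data(rnorm(20), cbind(a = rbinom(20, 1, 0.5),
                                    b = rep(0, 20)))
  out <- univariate_screen(d)
  expect_true(out$untestable[out$variable == "b"])
  expect_true(is.na(out$q_value[out$variable == "b"]))
  dbad <- design_data(rnorm(10), matrix(rnorm(10)), "cont")
  expect_error(univariate_screen(dbad), "'cont' is not binary")
})

test_that("q-values are monotone in p-values for both estimators", {
  cohort <- generate_cohort(n = 150, p = 40, n_signal = 3, seed = 46)
  for (method in c("BH", "storey")) {
    out <- univariate_screen(cohort$data, q_method = method)
    ok <- !out$untestable
    o <- order(out$p_value[ok])
    expect_true(all(diff(out$q_value[ok][o]) >= -1e-12))
    if (method == "BH")   # Storey's pi0 < 1 can pull q below p
      expect_true(all(out$q_value[ok] >= out$p_value[ok] - 1e-12))
    expect_true(all(out$q_value[ok] >= 0 & out$q_value[ok] <= 1))
  }
})

test_that("BH q-values agree with p.adjust", {
  cohort <- generate_cohort(n = 120, p = 25, n_signal = 2, seed = 47)
  out <- univariate_screen(cohort$data)
  ok <- !out$untestable
  expect_equal(out$q_value[ok], p.adjust(out$p_value[ok], "BH"))
})
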