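# Shared fixtures: all data is generated in code, seeded per call.

rand_design <- function(n, p, seed, binary = FALSE, freq = 0.2) {
  set.seed(seed)
  X <- if (binary) matrix(rbinom(n * p, 1, freq), n) else
    matrix(rnorm(n * p), n)
  design_data(rnorm(n), X, sprintf("v%02d", seq_len(p)))
}

# independent normal-equations least squares used as an oracle for fit_ols
ne_oracle_rss <- function(data, subset) {
  X <- cbind(1, data$covariates[, subset, drop = FALSE])
  beta <- solve(t(X) %*% X, t(X) %*% data$outcome)
  sum((data$outcome - X %*% beta)^2)
}

# direct log-likelihood route to the information criteria: evaluate the
# Gaussian likelihood at residuals carrying the given sum of squares and
# the MLE variance rss/n
ll_oracle_aic <- function(rss, n, k) {
  r <- rep(sqrt(rss / n), n)
  ll <- sum(dnorm(r, 0, sqrt(rss / n), log = TRUE))
  -2 * ll + 2 * (k + 1)
}
ll_oracle_bic <- function(rss, n, k) {
  r <- rep(sqrt(rss / n), n)
  ll <- sum(dnorm(r, 0, sqrt(rss / n), log = TRUE))
  -2 * ll + log(n) * (k + 1)
}

# post-run sanity assertions shared across FARMS tests: the trace must
# strictly improve under c2 and forced variables must never leave
expect_farms_invariants <- function(res, forced = integer(0)) {
  c2 <- res$config$c2
  if (res$n_iterations > 1L) {
    d <- diff(res$trace$c2_value)
    if (c2$direction == "minimize") expect_true(all(d < 0))
    else expect_true(all(d > 0))
  }
  if (length(forced))
    expect_true(all(res$inclusion[, forced, drop = FALSE] == 1L))
  last <- which(res$inclusion[res$n_iterations, ] == 1L)
  expect_identical(sort(res$final_fit$subset), as.integer(sort(last)))
  invisible(res)
}
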