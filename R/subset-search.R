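#' Exhaustive best-subset search over a bounded candidate pool
#'
#' Evaluates every subset of the `pool` variables with at most `max_free`
#' members, always together with the `forced` variables and an intercept,
#' and returns the best subset of each size plus the overall winner.  This
#' is the "all subsets regression" half of the FARMS iteration.
#'
#' The search runs on compiled code: variables are swept in and out of the
#' centred cross-product matrix along a removal tree, with subtrees pruned
#' once their residual sum of squares can no longer improve the incumbent
#' best at any reachable model size.  The returned subsets are identical to
#' a naive full enumeration; only provably suboptimal work is skipped.  If
#' the pooled design is collinear the compiled path is abandoned and every
#' subset is fitted directly (feasible for pools of up to 20 variables).
#'
#' Within a model size all penalized criteria rank subsets exactly as RSS
#' does, so per-size winners are RSS-optimal subsets.  Across sizes the
#' winner is chosen by `c1` when `c1` is penalized; the size-monotone
#' criteria (RSS, R2) always prefer the largest subset, so under those the
#' per-size winners are ranked by `c2` instead.  Ties prefer fewer free
#' variables, then the lexicographically smallest index set.
#'
#' @param data A [design_data()] object.
#' @param pool Indices or names of the free candidate variables.
#' @param forced Indices or names of variables forced into every model;
#'   must be disjoint from `pool`.
#' @param c1 Subset-selection criterion (see [criterion()]).
#' @param c2 Model-comparison criterion, used to rank per-size winners when
#'   `c1` is size-monotone; must be penalized in that case.
#' @param max_free Maximum number of free (non-forced) variables in any
#'   evaluated subset; defaults to the pool size.
#' @param hard_cap Refuse pools larger than this (default 25), since the
#'   enumeration grows as `2^|pool|`.
#' @param sigma2_full Full-model residual-variance estimate, required when
#'   either criterion is Mallows' Cp.
#' @return An object of class `"search_result"`: list with
#'   `best_overall` (a [fit_ols()] summary), `best_value` (its ranking
#'   criterion value), `best_per_size` (list of fit summaries indexed by
#'   free-subset size `0..max_free`), `c1_values`, `n_candidates` (number of
#'   candidate subsets in the search space), `n_nodes` (nodes actually
#'   visited), and the echoed `pool`, `forced`, `c1`, `c2`.
#' @seealso [naive_all_subsets_oracle()] for the reference implementation,
#'   [run_farms()] for the outer loop.
#' @examples
#' set.seed(1)
#' d <- design_data(rnorm(50), matrix(rnorm(50 * 6), 50),
#'                  paste0("x", 1:6))
#' s <- search_best_subsets(d, pool = 1:5, forced = 6, c1 = "BIC")
#' s$best_overall$subset  # always contains variable 6
#' @export
search_best_subsets <- function(data, pool, forced = integer(0),
                                c1 = "BIC", c2 = "BIC",
                                max_free = NULL, hard_cap = 25L,
                                sigma2_full = NULL) {
  stopifnot(inherits(data, "design_data"))
  c1 <- criterion(c1); c2 <- criterion(c2)
  rank_crit <- model_rank_criterion(c1, c2)
  pool <- resolve_vars(data, pool, "pool")
  forced <- resolve_vars(data, forced, "forced")
  if (length(intersect(pool, forced)))
    stop("pool and forced sets overlap: ",
         paste(data$names[intersect(pool, forced)], collapse = ", "),
         call. = FALSE)
  m <- length(pool)
  if (m > hard_cap)
    stop("candidate pool has ", m, " variables, above the hard cap of ",
         hard_cap, "; lower the adding-group size (or the starting-set ",
         "size) so that 2^|pool| enumeration stays tractable", call. = FALSE)
  if (is.null(max_free)) max_free <- m
  max_free <- as.integer(max_free)
  if (max_free < 0L) stop("max_free must be >= 0", call. = FALSE)
  max_free <- min(max_free, m)
  if ((c1$name == "CP" || rank_crit$name == "CP") && is.null(sigma2_full))
    stop("Mallows' Cp requires sigma2_full (residual variance of the fit ",
         "on all candidate variables)", call. = FALSE)

  per_size <- NULL
  n_nodes <- NA_real_
  if (m > 0L) {
    y <- data$outcome
    Z <- cbind(data$covariates[, forced, drop = FALSE],
               data$covariates[, pool, drop = FALSE], y)
    M <- crossprod(scale(Z, center = TRUE, scale = FALSE))
    # exclude the most informative variables first so that subtrees missing
    # them become prunable as early as possible
    imp <- abs(M[length(forced) + seq_len(m), ncol(M)]) /
      sqrt(pmax(diag(M)[length(forced) + seq_len(m)], .Machine$double.eps))
    imp[!is.finite(imp)] <- 0
    eng <- .subset_search_engine(M, length(forced), m, max_free,
                                 order(-imp) - 1L, 1e-10)
    if (isTRUE(eng$ok)) {
      per_size <- lapply(0:max_free, function(s) sort(pool[eng$sets[[s + 1L]]]))
      n_nodes <- eng$nodes
    }
  }
  if (is.null(per_size)) per_size <- enumerate_subsets_r(data, pool, forced, max_free)

  fits <- lapply(per_size, function(free) fit_ols(data, c(forced, free)))
  c1_values <- vapply(fits, criterion_value, numeric(1),
                      spec = c1, sigma2_full = sigma2_full)
  rank_values <- if (identical(rank_crit$name, c1$name)) c1_values else
    vapply(fits, criterion_value, numeric(1),
           spec = rank_crit, sigma2_full = sigma2_full)
  best <- 1L
  for (i in seq_along(fits)[-1L])
    if (is_better(rank_values[i], rank_values[best], rank_crit)) best <- i

  structure(list(best_overall = fits[[best]],
                 best_value = rank_values[best],
                 best_size = best - 1L,
                 best_per_size = fits,
                 c1_values = c1_values,
                 rank_values = rank_values,
                 n_candidates = sum(choose(m, 0:max_free)),
                 n_nodes = n_nodes,
                 pool = pool, forced = forced, c1 = c1, c2 = c2),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result: pool of ", length(x$pool), ", ", x$n_candidates,
      " candidate subsets; best has ", length(x$best_overall$subset),
      " variable(s), ", x$c1$name, "-ranked>\n", sep = "")
  invisible(x)
}

# Slow direct enumeration used when the pooled design is collinear: fits
# every subset with fit_ols and keeps the per-size best, preferring
# full-rank fits, then lexicographically smaller index sets, on equal rss.
enumerate_subsets_r <- function(data, pool, forced, max_free) {
  if (length(pool) > 20L)
    stop("pooled design is collinear and too large for the direct ",
         "enumeration fallback; remove aliased columns", call. = FALSE)
  lapply(0:max_free, function(s) {
    combos <- if (s == 0L) list(integer(0)) else
      asplit(combn(pool, s), 2L)
    best <- NULL; best_fit <- NULL
    for (free in combos) {
      free <- as.integer(free)
      fit <- fit_ols(data, c(forced, free))
      if (is.null(best_fit) ||
          fit$rss < best_fit$rss ||
          (fit$rss == best_fit$rss &&
           (best_fit$rank_deficient && !fit$rank_deficient))) {
        best <- free; best_fit <- fit
      }
    }
    best
  })
}

#' Reference all-subsets search by naive double-loop enumeration
#'
#' Independent oracle for [search_best_subsets()]: iterates model sizes and
#' `utils::combn()` subsets, fits each candidate by solving the normal
#' equations directly, and scores it with its own criterion arithmetic
#' (via the Gaussian log-likelihood for AIC/BIC).  No code is shared with
#' the compiled search path.  Intended for tests and small problems only.
#'
#' @inheritParams search_best_subsets
#' @return A list with `best_overall` and `best_per_size`; each entry is a
#'   list with `subset` (forced plus free, sorted), `free`, `rss` and
#'   `value` (the criterion used for ranking at that stage).
#' @export
naive_all_subsets_oracle <- function(data, pool, forced = integer(0),
                                     c1 = "BIC", c2 = "BIC",
                                     max_free = NULL, sigma2_full = NULL) {
  stopifnot(inherits(data, "design_data"))
  c1 <- criterion(c1); c2 <- criterion(c2)
  pool <- resolve_vars(data, pool, "pool")
  forced <- resolve_vars(data, forced, "forced")
  if (length(intersect(pool, forced)))
    stop("pool and forced sets overlap", call. = FALSE)
  if (length(pool) > 15L)
    stop("oracle enumeration is limited to pools of at most 15 variables",
         call. = FALSE)
  if (is.null(max_free)) max_free <- length(pool)
  max_free <- min(as.integer(max_free), length(pool))
  y <- data$outcome; n <- length(y)
  tss <- sum((y - mean(y))^2)

  score <- function(rss, k, crit) {
    switch(crit$name,
      RSS = rss,
      R2 = 1 - rss / tss,
      ADJR2 = 1 - (rss / tss) * (n - 1) / (n - k),
      CP = {
        if (is.null(sigma2_full)) stop("Cp needs sigma2_full", call. = FALSE)
        rss / sigma2_full - n + 2 * k
      },
      AIC = , BIC = {
        ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
        pen <- if (crit$name == "AIC") 2 else log(n)
        -2 * ll + pen * (k + 1)
      })
  }
  fit_one <- function(free) {
    # SVD least squares: independent of the sweep path and of fit_ols's QR,
    # and tolerant of aliased (e.g. all-zero) columns
    X <- cbind(1, data$covariates[, c(forced, free), drop = FALSE])
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
    r <- y - X %*% beta
    list(free = sort(free), subset = sort(c(forced, free)),
         rss = sum(r * r), k = sum(pos))
  }

  per_size <- vector("list", max_free + 1L)
  for (s in 0:max_free) {
    combos <- if (s == 0L) list(integer(0)) else asplit(combn(pool, s), 2L)
    best <- NULL
    for (free in combos) {
      cand <- fit_one(as.integer(free))
      cand$value <- score(cand$rss, cand$k, c1)
      take <- is.null(best) || is_better(cand$value, best$value, c1) ||
        (cand$value == best$value &&
         lex_lt(cand$subset, best$subset))
      if (take) best <- cand
    }
    per_size[[s + 1L]] <- best
  }
  rank_crit <- model_rank_criterion(c1, c2)
  best <- per_size[[1L]]
  best_val <- score(best$rss, best$k, rank_crit)
  for (s in seq_len(max_free)) {
    cand <- per_size[[s + 1L]]
    v <- score(cand$rss, cand$k, rank_crit)
    if (is_better(v, best_val, rank_crit)) { best <- cand; best_val <- v }
  }
  best$value <- best_val
  list(best_overall = best, best_per_size = per_size)
}

# lexicographic strict order of two sorted integer vectors, shorter-first
# on shared prefixes
lex_lt <- function(a, b) {
  la <- length(a); lb <- length(b)
  k <- min(la, lb)
  if (k > 0L) for (i in seq_len(k)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  la < lb
}
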