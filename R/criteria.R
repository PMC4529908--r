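#' Model-selection criteria
#'
#' Constructs a criterion specification used throughout the package to score
#' fitted variable subsets.  Six criteria are supported:
#'
#' \describe{
#'   \item{RSS}{residual sum of squares (minimize; improves with every added
#'     variable, hence \emph{size-monotone}).}
#'   \item{R2}{coefficient of determination \eqn{1 - RSS/TSS} (maximize;
#'     size-monotone).}
#'   \item{ADJR2}{adjusted R-squared
#'     \eqn{1 - (RSS/(n-k)) / (TSS/(n-1))} (maximize).}
#'   \item{CP}{Mallows' Cp, \eqn{RSS/\hat\sigma^2 - n + 2k}, where
#'     \eqn{\hat\sigma^2} is the residual-variance estimate from the fit on
#'     all candidate variables (minimize).}
#'   \item{AIC}{Gaussian-likelihood Akaike information criterion,
#'     \eqn{n \log(2\pi RSS/n) + n + 2(k+1)} (minimize).}
#'   \item{BIC}{Schwarz/Bayesian information criterion,
#'     \eqn{n \log(2\pi RSS/n) + n + (k+1)\log n} (minimize).}
#' }
#'
#' Here \eqn{k} counts the estimated mean-model coefficients including the
#' intercept.  AIC and BIC use the full Gaussian log-likelihood with the
#' residual variance counted as one additional parameter (the \eqn{k+1}),
#' the convention of `stats::AIC()`/`stats::BIC()` on `lm` fits, so values
#' are directly cross-checkable against mainstream output.  For fixed
#' \eqn{n} the additive constants do not affect which model is selected.
#'
#' @param name Criterion name, one of `"RSS"`, `"R2"`, `"ADJR2"`, `"CP"`,
#'   `"AIC"`, `"BIC"` (case-insensitive).
#' @return An object of class `"criterion_spec"`: a list with elements
#'   `name`, `direction` (`"minimize"` or `"maximize"`) and `size_monotone`
#'   (`TRUE` for RSS and R2, which always prefer larger subsets).
#' @seealso [criterion_value()], [is_better()]
#' @examples
#' criterion("BIC")
#' criterion("r2")$size_monotone
#' @export
criterion <- function(name) {
  if (inherits(name, "criterion_spec")) return(name)
  stopifnot(is.character(name), length(name) == 1L)
  nm <- toupper(name)
  info <- switch(nm,
    RSS   = list(direction = "minimize", size_monotone = TRUE),
    R2    = list(direction = "maximize", size_monotone = TRUE),
    ADJR2 = list(direction = "maximize", size_monotone = FALSE),
    CP    = list(direction = "minimize", size_monotone = FALSE),
    AIC   = list(direction = "minimize", size_monotone = FALSE),
    BIC   = list(direction = "minimize", size_monotone = FALSE),
    stop("unknown criterion '", name,
         "'; choose one of RSS, R2, ADJR2, CP, AIC, BIC", call. = FALSE)
  )
  structure(list(name = nm, direction = info$direction,
                 size_monotone = info$size_monotone),
            class = "criterion_spec")
}

#' @export
print.criterion_spec <- function(x, ...) {
  cat("<criterion ", x$name, ": ", x$direction,
      if (x$size_monotone) ", size-monotone" else "", ">\n", sep = "")
  invisible(x)
}

#' Evaluate a selection criterion on a fitted subset
#'
#' @param fit A [fit_ols()] result (class `"fit_summary"`).
#' @param spec A [criterion()] specification (or its name).
#' @param sigma2_full Residual-variance estimate from the fit on \emph{all}
#'   candidate variables; required (and must be positive) for Mallows' Cp,
#'   ignored otherwise.
#' @return The criterion value, a single number on the scale documented in
#'   [criterion()].
#' @details A zero residual sum of squares makes the Gaussian log-likelihood
#'   unbounded, so AIC/BIC raise an error for perfect fits; a constant
#'   outcome (`tss == 0`) is rejected for the R-squared family.
#' @examples
#' d <- design_data(rnorm(20), matrix(rnorm(40), 20), c("a", "b"))
#' f <- fit_ols(d, 1:2)
#' criterion_value(f, "BIC")
#' @export
criterion_value <- function(fit, spec, sigma2_full = NULL) {
  spec <- criterion(spec)
  stopifnot(inherits(fit, "fit_summary"))
  n <- fit$n; k <- fit$k; rss <- fit$rss; tss <- fit$tss
  switch(spec$name,
    RSS = rss,
    R2 = {
      if (tss <= 0) stop("constant outcome: tss = 0, R2 undefined", call. = FALSE)
      1 - rss / tss
    },
    ADJR2 = {
      if (tss <= 0) stop("constant outcome: tss = 0, adjusted R2 undefined", call. = FALSE)
      if (n <= k) stop("no residual degrees of freedom for adjusted R2", call. = FALSE)
      1 - (rss / (n - k)) / (tss / (n - 1))
    },
    CP = {
      if (is.null(sigma2_full) || !is.finite(sigma2_full) || sigma2_full <= 0)
        stop("Mallows' Cp needs a positive full-model residual variance ",
             "estimate (sigma2_full)", call. = FALSE)
      rss / sigma2_full - n + 2 * k
    },
    AIC = {
      if (rss <= 0) stop("rss = 0: Gaussian AIC is unbounded for a perfect fit",
                         call. = FALSE)
      n * log(2 * pi * rss / n) + n + 2 * (k + 1)
    },
    BIC = {
      if (rss <= 0) stop("rss = 0: Gaussian BIC is unbounded for a perfect fit",
                         call. = FALSE)
      n * log(2 * pi * rss / n) + n + (k + 1) * log(n)
    })
}

#' Strict "better-than" comparison between two criterion values
#'
#' Returns `TRUE` iff `a` strictly improves on `b` in the criterion's
#' direction.  Equality returns `FALSE`: the algorithms in this package stop
#' on non-improvement, and requiring strict improvement guarantees
#' termination.  Comparison is exact floating-point with no epsilon band,
#' for reproducibility.
#'
#' @param a,b Criterion values (finite numbers).
#' @param spec A [criterion()] specification (or its name).
#' @return A single logical.
#' @examples
#' is_better(2224.82, 2235.4, "BIC")  # TRUE: lower BIC wins
#' is_better(0.15, 0.12, "R2")        # TRUE: higher R2 wins
#' @export
is_better <- function(a, b, spec) {
  spec <- criterion(spec)
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L || length(b) != 1L ||
      is.na(a) || is.na(b))
    stop("is_better() requires two finite scalar criterion values", call. = FALSE)
  if (!is.finite(a) || !is.finite(b))
    stop("non-finite criterion value in comparison", call. = FALSE)
  if (spec$direction == "minimize") a < b else a > b
}

# Comparator used when ranking whole models: penalized criteria can be
# compared across model sizes directly; the size-monotone ones (RSS, R2)
# always prefer the larger subset, so cross-size/cross-group ranking falls
# back to the model-comparison criterion c2.
model_rank_criterion <- function(c1, c2) {
  c1 <- criterion(c1); c2 <- criterion(c2)
  if (!c1$size_monotone) return(c1)
  if (c2$size_monotone)
    stop("when c1 is size-monotone (", c1$name,
         "), c2 must be a penalized criterion (ADJR2, CP, AIC or BIC)",
         call. = FALSE)
  c2
}
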