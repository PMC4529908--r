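# Classical selection baselines used for head-to-head comparisons with the
# FARMS loop: forward selection, forward/backward stepwise, and exhaustive
# all-subsets regression.  All scan candidates in ascending column order
# with ties broken toward the smaller index, so paths are deterministic.

base_model_vars <- function(data, base, forced) {
  base <- match.arg(base, c("forced", "intercept_only"))
  if (base == "intercept_only" && length(forced))
    stop("an intercept-only baseline with forced-in variables is ",
         "contradictory; use base = \"forced\"", call. = FALSE)
  forced
}

cp_sigma2 <- function(data, criterion) {
  if (criterion$name != "CP") return(NULL)
  p <- length(data$names)
  if (length(data$outcome) <= p + 1L)
    stop("Mallows' Cp needs the full-model fit, impossible here: n <= p + 1",
         call. = FALSE)
  full <- fit_ols(data, seq_len(p))
  full$rss / (full$n - full$k)
}

#' Forward selection
#'
#' Starting from the base model (intercept-only, or intercept plus the
#' forced variables), repeatedly adds the single variable whose addition
#' improves the criterion most, and stops when no addition strictly
#' improves it.
#'
#' @param data A [design_data()] object.
#' @param criterion A penalized [criterion()] (AIC, BIC, CP or ADJR2).
#' @param base `"forced"` (default; reduces to intercept-only when `forced`
#'   is empty) or `"intercept_only"`, which rejects a non-empty `forced`
#'   set as contradictory.
#' @param forced Variables present in every model and never droppable.
#' @return The final [fit_ols()] summary, with the visited subsets attached
#'   as `attr(, "path")` (a list, base model first).
#' @seealso [stepwise()], [all_subsets_regression()]
#' @export
forward_selection <- function(data, criterion = "BIC", base = "forced",
                              forced = integer(0)) {
  criterion <- criterion(criterion)
  if (criterion$size_monotone)
    stop("forward selection under a size-monotone criterion (",
         criterion$name, ") never stops; use a penalized criterion",
         call. = FALSE)
  forced <- resolve_vars(data, forced, "forced")
  current <- base_model_vars(data, base, forced)
  sigma2_full <- cp_sigma2(data, criterion)
  p <- length(data$names)
  fit <- fit_ols(data, current)
  value <- criterion_value(fit, criterion, sigma2_full)
  path <- list(fit$subset)
  repeat {
    step <- best_single_change(data, current, forced, criterion, sigma2_full,
                               add = TRUE)
    if (is.null(step) || !is_better(step$value, value, criterion)) break
    current <- step$vars; fit <- step$fit; value <- step$value
    path <- c(path, list(fit$subset))
  }
  attr(fit, "path") <- path
  attr(fit, "criterion_value") <- value
  fit
}

# best single addition (add = TRUE) or deletion of a non-forced variable
# (add = FALSE); ascending scan, strict improvement keeps the first hit
best_single_change <- function(data, current, forced, criterion, sigma2_full,
                               add) {
  p <- length(data$names)
  cand <- if (add) setdiff(seq_len(p), current) else setdiff(current, forced)
  if (!length(cand)) return(NULL)
  best <- NULL
  for (v in cand) {
    vars <- if (add) sort(c(current, v)) else setdiff(current, v)
    if (add && length(vars) + 1L >= length(data$outcome)) next
    fit <- fit_ols(data, vars)
    value <- criterion_value(fit, criterion, sigma2_full)
    if (is.null(best) || is_better(value, best$value, criterion))
      best <- list(vars = vars, fit = fit, value = value, changed = v)
  }
  best
}

#' Stepwise selection
#'
#' `direction = "both"` (forward stepwise) proceeds like
#' [forward_selection()] but, after every accepted addition, attempts
#' single-variable deletions for as long as they strictly improve the
#' criterion.  `direction = "backward"` starts from the full model, which
#' requires `n > p + 1`, and deletes while deleting improves.  Forced
#' variables are never deleted.
#'
#' @inheritParams forward_selection
#' @param direction `"both"` or `"backward"`.
#' @return The final [fit_ols()] summary with `attr(, "path")` as in
#'   [forward_selection()].
#' @export
stepwise <- function(data, criterion = "BIC", base = "forced",
                     forced = integer(0), direction = c("both", "backward")) {
  direction <- match.arg(direction)
  criterion <- criterion(criterion)
  if (criterion$size_monotone)
    stop("stepwise selection under a size-monotone criterion (",
         criterion$name, ") never stops; use a penalized criterion",
         call. = FALSE)
  forced <- resolve_vars(data, forced, "forced")
  sigma2_full <- cp_sigma2(data, criterion)
  p <- length(data$names)

  if (direction == "backward") {
    if (length(data$outcome) <= p + 1L)
      stop("backward stepwise starts from the full model, impossible here: ",
           "n = ", length(data$outcome), " <= p + 1 = ", p + 1L,
           call. = FALSE)
    current <- seq_len(p)
  } else {
    current <- base_model_vars(data, base, forced)
  }
  fit <- fit_ols(data, current)
  value <- criterion_value(fit, criterion, sigma2_full)
  path <- list(fit$subset)

  drop_while_improving <- function() {
    repeat {
      step <- best_single_change(data, current, forced, criterion,
                                 sigma2_full, add = FALSE)
      if (is.null(step) || !is_better(step$value, value, criterion)) break
      current <<- step$vars; fit <<- step$fit; value <<- step$value
      path <<- c(path, list(fit$subset))
    }
  }

  if (direction == "backward") {
    drop_while_improving()
  } else {
    repeat {
      step <- best_single_change(data, current, forced, criterion,
                                 sigma2_full, add = TRUE)
      if (is.null(step) || !is_better(step$value, value, criterion)) break
      current <- step$vars; fit <- step$fit; value <- step$value
      path <- c(path, list(fit$subset))
      drop_while_improving()
    }
  }
  attr(fit, "path") <- path
  attr(fit, "criterion_value") <- value
  fit
}

#' Exhaustive all-subsets regression
#'
#' Global criterion optimum over every subset of the non-forced variables,
#' obtained by delegating to [search_best_subsets()] with the full variable
#' set as the pool.  Only feasible for small problems: the candidate count
#' is `2^(p - |forced|)`.
#'
#' @inheritParams forward_selection
#' @param max_free Cap on the number of free variables in the model.
#' @param hard_cap Refuse problems with more than this many free variables
#'   (default 20); for larger problems use [run_farms()].
#' @return The best [fit_ols()] summary under the criterion.
#' @export
all_subsets_regression <- function(data, forced = integer(0),
                                   criterion = "BIC", max_free = NULL,
                                   hard_cap = 20L) {
  criterion <- criterion(criterion)
  forced <- resolve_vars(data, forced, "forced")
  pool <- setdiff(seq_len(length(data$names)), forced)
  if (length(pool) > hard_cap)
    stop(length(pool), " free variables exceed the all-subsets cap of ",
         hard_cap, "; use run_farms() for problems of this size",
         call. = FALSE)
  sigma2_full <- cp_sigma2(data, criterion)
  res <- search_best_subsets(data, pool = pool, forced = forced,
                             c1 = criterion, c2 = "BIC",
                             max_free = max_free,
                             hard_cap = max(hard_cap, length(pool)),
                             sigma2_full = sigma2_full)
  fit <- res$best_overall
  attr(fit, "criterion_value") <- res$best_value
  fit
}
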