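#' Configuration for a FARMS run
#'
#' Collects the user-tunable knobs of the algorithm.  The two structural
#' parameters are the size of the random starting set and the size of the
#' groups in which remaining variables are injected; both default to the
#' values found to work well on the motivating HIV cohorts (10 and 8).
#'
#' @param start_size Number of variables in the random starting set `Ps`
#'   (ignored when `start_vars` is given).
#' @param add_size Size of the adding groups `Pa` into which the
#'   not-yet-included variables are partitioned at each iteration.
#' @param c1 Subset-selection criterion used inside each pool
#'   (see [criterion()]); default BIC.
#' @param c2 Model-comparison criterion used to accept or reject the
#'   iteration's champion; default BIC.
#' @param forced Variables (indices or names) forced into every model.
#' @param start_vars Optional explicit starting set, disjoint from `forced`;
#'   overrides the random start.
#' @param max_model_size Cap on the total number of variables (forced
#'   included) in any candidate model; default `NULL` means no cap beyond
#'   the number of available variables.
#' @param max_time_s Optional wall-clock budget in seconds; when exceeded
#'   the current model is returned with `converged = FALSE`.
#' @param seed Integer seed controlling the random start and the shuffling
#'   of remaining variables.
#' @param reshuffle Logical; reshuffle the remaining variables before
#'   partitioning at every iteration (default) or keep dataset order
#'   (useful for debugging).
#' @param hard_cap Passed to [search_best_subsets()]; pools larger than
#'   this are refused, so `start_size + add_size` must stay within it.
#' @return An object of class `"farms_config"`.
#' @seealso [run_farms()]
#' @export
farms_config <- function(start_size = 10L, add_size = 8L,
                         c1 = "BIC", c2 = "BIC",
                         forced = integer(0), start_vars = NULL,
                         max_model_size = NULL, max_time_s = NULL,
                         seed = 1L, reshuffle = TRUE, hard_cap = 25L) {
  start_size <- as.integer(start_size); add_size <- as.integer(add_size)
  if (start_size < 1L) stop("start_size must be >= 1", call. = FALSE)
  if (add_size < 1L) stop("add_size must be >= 1", call. = FALSE)
  cfg <- structure(list(start_size = start_size, add_size = add_size,
                        c1 = criterion(c1), c2 = criterion(c2),
                        forced = forced, start_vars = start_vars,
                        max_model_size = max_model_size,
                        max_time_s = max_time_s, seed = as.integer(seed),
                        reshuffle = isTRUE(reshuffle),
                        hard_cap = as.integer(hard_cap)),
                   class = "farms_config")
  model_rank_criterion(cfg$c1, cfg$c2)  # validates the combination
  cfg
}

#' @export
print.farms_config <- function(x, ...) {
  cat("<farms_config: start_size = ", x$start_size, ", add_size = ",
      x$add_size, ", c1 = ", x$c1$name, ", c2 = ", x$c2$name,
      ", seed = ", x$seed, ">\n", sep = "")
  invisible(x)
}

# run `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Partition the remaining variables into adding groups
#'
#' Shuffles the given variable indices with the current RNG state and chunks
#' them into groups of `add_size`; all groups are full except possibly the
#' last.  Called once per FARMS iteration on the variables not in the
#' current model.
#'
#' @param remaining Integer vector of variable indices.
#' @param add_size Group size, `>= 1`.
#' @param shuffle Shuffle before chunking (default `TRUE`).
#' @return A list of disjoint integer vectors whose union is `remaining`.
#' @examples
#' set.seed(1)
#' partition_remaining(1:7, 3)  # group sizes 3, 3, 1
#' @export
partition_remaining <- function(remaining, add_size, shuffle = TRUE) {
  add_size <- as.integer(add_size)
  if (add_size < 1L) stop("add_size must be >= 1", call. = FALSE)
  remaining <- as.integer(remaining)
  if (length(remaining) == 0L) return(list())
  if (shuffle) remaining <- remaining[sample.int(length(remaining))]
  unname(split(remaining, ceiling(seq_along(remaining) / add_size)))
}

#' Run the FARMS variable-selection algorithm
#'
#' Starting from a model containing the forced variables plus a starting
#' set (random by default), each iteration (i) partitions the variables not
#' in the current model into groups of `add_size`, (ii) for each group runs
#' an exhaustive best-subset search over the group merged with the current
#' model's free variables (forced variables always included), (iii) picks
#' the champion across groups, and (iv) accepts it if it strictly improves
#' the current model under `c2`, stopping otherwise.  Variables dropped by
#' the inner search return to the candidate pool at later iterations.
#'
#' @param data A [design_data()] object.
#' @param config A [farms_config()].
#' @param trace_file Optional path; when given, a tab-delimited trace line
#'   is appended after every iteration (see [write_trace()] for the
#'   dialect), so a long run can be monitored from outside.
#' @return An object of class `"farms_result"`: list with
#'   `final_fit` (a [fit_ols()] summary of the selected model), `trace`
#'   (data frame with `iteration`, `elapsed_s`, `aic`, `bic`, `c2_value`),
#'   `inclusion` (iterations x p 0/1 matrix), `converged` (`FALSE` only
#'   when stopped by `max_time_s`), `n_iterations`, and the `config`.
#' @details The first trace record describes the starting model; every
#'   subsequent record corresponds to an accepted strict improvement, so
#'   the `c2_value` column is strictly improving down the trace and the
#'   algorithm must terminate.  Both properties, and the presence of every
#'   forced variable in every recorded model, are asserted before the
#'   result is returned.
#' @examples
#' cohort <- generate_cohort(n = 120, p = 12, n_signal = 2, seed = 7)
#' res <- run_farms(cohort$data, farms_config(start_size = 4, add_size = 4,
#'                                            seed = 1))
#' res$final_fit$subset
#' @export
run_farms <- function(data, config = farms_config(), trace_file = NULL) {
  stopifnot(inherits(data, "design_data"), inherits(config, "farms_config"))
  p <- length(data$names)
  forced <- resolve_vars(data, config$forced, "forced")
  start_vars <- resolve_vars(data, config$start_vars, "start_vars")
  if (length(intersect(forced, start_vars)))
    stop("forced and start_vars overlap", call. = FALSE)
  max_model_size <- if (is.null(config$max_model_size)) p else
    as.integer(config$max_model_size)
  if (max_model_size < length(forced))
    stop("max_model_size smaller than the forced set", call. = FALSE)
  start_size <- if (length(start_vars)) length(start_vars) else config$start_size
  if (start_size + length(forced) > p)
    stop("start_size + |forced| = ", start_size + length(forced),
         " exceeds the number of available variables (p = ", p, ")",
         call. = FALSE)
  if (start_size + length(forced) > max_model_size)
    stop("starting model would exceed max_model_size", call. = FALSE)
  max_free <- max_model_size - length(forced)
  c1 <- config$c1; c2 <- config$c2
  rank_crit <- model_rank_criterion(c1, c2)

  sigma2_full <- NULL
  if (c1$name == "CP" || c2$name == "CP") {
    if (length(data$outcome) <= p + 1L)
      stop("Mallows' Cp needs the full-model fit, impossible here: n = ",
           length(data$outcome), " <= p + 1 = ", p + 1L, call. = FALSE)
    full <- fit_ols(data, seq_len(p))
    sigma2_full <- full$rss / (full$n - full$k)
  }

  t0 <- proc.time()[["elapsed"]]
  elapsed <- function() proc.time()[["elapsed"]] - t0

  with_seed(config$seed, {
    current_free <- if (length(start_vars)) start_vars else
      sort(setdiff(seq_len(p), forced)[sample.int(p - length(forced), start_size)])
    current_fit <- fit_ols(data, c(forced, current_free))
    current_c2 <- criterion_value(current_fit, c2, sigma2_full)

    trace <- list(); inclusion <- list()
    add_record <- function(fit, c2v) {
      i <- length(trace) + 1L
      rec <- data.frame(iteration = i, elapsed_s = elapsed(),
                        aic = criterion_value(fit, "AIC"),
                        bic = criterion_value(fit, "BIC"),
                        c2_value = c2v)
      incl <- integer(p); incl[fit$subset] <- 1L
      trace[[i]] <<- rec; inclusion[[i]] <<- incl
      if (!is.null(trace_file))
        append_trace_line(trace_file, rec, incl, data$names, header = i == 1L)
      invisible(i)
    }
    add_record(current_fit, current_c2)

    converged <- TRUE
    repeat {
      if (!is.null(config$max_time_s) && elapsed() >= config$max_time_s) {
        converged <- FALSE
        break
      }
      remaining <- setdiff(seq_len(p), c(forced, current_free))
      groups <- partition_remaining(remaining, config$add_size,
                                    shuffle = config$reshuffle)
      if (length(groups) == 0L) groups <- list(integer(0))
      champion <- NULL
      for (g in groups) {
        res <- tryCatch(
          search_best_subsets(data, pool = sort(c(current_free, g)),
                              forced = forced, c1 = c1, c2 = c2,
                              max_free = max_free,
                              hard_cap = config$hard_cap,
                              sigma2_full = sigma2_full),
          error = function(e)
            stop("iteration ", length(trace), ": ", conditionMessage(e),
                 call. = FALSE))
        if (is.null(champion) ||
            is_better(res$best_value, champion$best_value, rank_crit) ||
            (res$best_value == champion$best_value &&
             better_tie(res$best_overall, champion$best_overall)))
          champion <- res
      }
      cand_fit <- champion$best_overall
      cand_c2 <- criterion_value(cand_fit, c2, sigma2_full)
      if (!is_better(cand_c2, current_c2, c2)) break
      current_fit <- cand_fit
      current_free <- sort(setdiff(cand_fit$subset, forced))
      current_c2 <- cand_c2
      add_record(current_fit, current_c2)
      if (length(trace) > 10000L) stop("iteration limit exceeded", call. = FALSE)
    }

    trace <- do.call(rbind, trace)
    inclusion <- do.call(rbind, inclusion)
    colnames(inclusion) <- data$names
    # post-run assertions: strict c2 improvement and forced inclusion
    if (nrow(trace) > 1L) {
      d <- diff(trace$c2_value)
      stopifnot(all(if (c2$direction == "minimize") d < 0 else d > 0))
    }
    if (length(forced)) stopifnot(all(inclusion[, forced, drop = FALSE] == 1L))
    stopifnot(length(current_fit$subset) <= max_model_size)

    structure(list(final_fit = current_fit, trace = trace,
                   inclusion = inclusion, converged = converged,
                   n_iterations = nrow(trace), config = config,
                   names = data$names),
              class = "farms_result")
  })
}

# tie-break between two fit summaries with equal criterion value:
# fewer free variables, then lexicographically smaller subset
better_tie <- function(a, b) {
  if (length(a$subset) != length(b$subset))
    return(length(a$subset) < length(b$subset))
  lex_lt(a$subset, b$subset)
}

#' @export
print.farms_result <- function(x, ...) {
  cat("FARMS result: ", length(x$final_fit$subset), " variable(s) after ",
      x$n_iterations, " iteration(s)",
      if (!x$converged) " [stopped by time cap]", "\n", sep = "")
  if (length(x$final_fit$subset))
    cat("  selected: ", paste(x$names[x$final_fit$subset], collapse = ", "),
        "\n", sep = "")
  cat("  AIC = ", format(x$trace$aic[nrow(x$trace)], digits = 8),
      ", BIC = ", format(x$trace$bic[nrow(x$trace)], digits = 8), "\n", sep = "")
  invisible(x)
}

#' Robustness grid over the FARMS tuning parameters
#'
#' Re-runs FARMS across a grid of starting-set and adding-group sizes with
#' fresh random starts, to check how stable the selected model is against
#' the algorithm's two structural parameters.
#'
#' @param data A [design_data()] object.
#' @param base_config A [farms_config()]; each cell inherits everything
#'   from it except `start_size`, `add_size`, `start_vars` (cleared) and
#'   `seed` (one distinct seed per cell, derived from `base_config$seed`).
#' @param start_sizes,add_sizes Integer vectors spanning the grid.
#' @param replicates Runs per (start_size, add_size) cell.
#' @return A data frame of class `"farms_grid"` with one row per run:
#'   the cell coordinates, seed, selected variables (comma-separated,
#'   sorted), model size, AIC/BIC, iteration count, elapsed seconds,
#'   convergence flag, and an `error` column (`NA` on success; a failed
#'   cell is recorded, not fatal).
#' @examples
#' cohort <- generate_cohort(n = 150, p = 10, n_signal = 2, seed = 3)
#' g <- robustness_grid(cohort$data, farms_config(seed = 1),
#'                      start_sizes = c(2, 4), add_sizes = c(2, 3))
#' length(unique(g$vars)) == 1  # stable selection?
#' @export
robustness_grid <- function(data, base_config = farms_config(),
                            start_sizes, add_sizes, replicates = 1L) {
  stopifnot(length(start_sizes) >= 1L, length(add_sizes) >= 1L,
            replicates >= 1L)
  cells <- expand.grid(start_size = as.integer(start_sizes),
                       add_size = as.integer(add_sizes),
                       replicate = seq_len(replicates))
  seeds <- with_seed(base_config$seed,
                     sample.int(.Machine$integer.max - 1L, nrow(cells)))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cfg <- base_config
    cfg$start_size <- cells$start_size[i]
    cfg$add_size <- cells$add_size[i]
    cfg$start_vars <- NULL
    cfg$seed <- seeds[i]
    out <- data.frame(start_size = cfg$start_size, add_size = cfg$add_size,
                      replicate = cells$replicate[i], seed = seeds[i],
                      n_vars = NA_integer_, vars = NA_character_,
                      aic = NA_real_, bic = NA_real_,
                      n_iterations = NA_integer_, elapsed_s = NA_real_,
                      converged = NA, error = NA_character_,
                      stringsAsFactors = FALSE)
    res <- tryCatch(run_farms(data, cfg), error = function(e) e)
    if (inherits(res, "error")) {
      out$error <- conditionMessage(res)
    } else {
      out$n_vars <- length(res$final_fit$subset)
      out$vars <- paste(data$names[res$final_fit$subset], collapse = ",")
      out$aic <- res$trace$aic[res$n_iterations]
      out$bic <- res$trace$bic[res$n_iterations]
      out$n_iterations <- res$n_iterations
      out$elapsed_s <- res$trace$elapsed_s[res$n_iterations]
      out$converged <- res$converged
    }
    out
  })
  structure(do.call(rbind, rows), class = c("farms_grid", "data.frame"))
}

#' @export
print.farms_grid <- function(x, ...) {
  cat("FARMS robustness grid: ", nrow(x), " run(s), ",
      length(unique(x$vars[!is.na(x$vars)])), " distinct final model(s)\n",
      sep = "")
  NextMethod()
}
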