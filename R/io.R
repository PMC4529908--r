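# Table and trace-file IO.  Designs travel as CSV/TSV with one outcome
# column; traces are tab-delimited text with one line per iteration so a
# long run can be watched with `tail -f`.

delim_for <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a design table from CSV/TSV
#'
#' Reads a rectangular table with a header, takes `outcome_column` as the
#' outcome and every other column as a covariate (order preserved), and
#' validates the result: the file must be non-empty, the outcome column
#' present and numeric, all covariates numeric, and no values missing
#' (missing cells are reported with their row and column).
#'
#' @param path File path; `.tsv`/`.txt` are read tab-delimited, anything
#'   else comma-delimited.
#' @param outcome_column Name of the outcome column.
#' @return A [design_data()] object.
#' @seealso [write_design()]
#' @export
read_design <- function(path, outcome_column) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    read.table(path, header = TRUE, sep = delim_for(path),
               check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("cannot read '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L || ncol(df) == 0L)
    stop("empty table in '", path, "'", call. = FALSE)
  if (!outcome_column %in% names(df))
    stop("outcome column '", outcome_column, "' not found in '", path,
         "' (columns: ", paste(head(names(df), 8L), collapse = ", "),
         if (ncol(df) > 8L) " ..." else "", ")", call. = FALSE)
  if (!is.numeric(df[[outcome_column]]))
    stop("outcome column '", outcome_column, "' is not numeric", call. = FALSE)
  covs <- df[setdiff(names(df), outcome_column)]
  for (nm in names(covs))
    if (!is.numeric(covs[[nm]]))
      stop("covariate column '", nm, "' is not numeric", call. = FALSE)
  mat <- as.matrix(covs)
  if (anyNA(mat) || anyNA(df[[outcome_column]])) {
    bad <- which(is.na(cbind(df[[outcome_column]], mat)), arr.ind = TRUE)
    cols <- c(outcome_column, colnames(mat))[bad[, 2L]]
    msg <- paste0("row ", bad[, 1L], "/column ", cols)
    stop("missing values in '", path, "': ",
         paste(head(msg, 5L), collapse = "; "),
         if (nrow(bad) > 5L) " ..." else "", call. = FALSE)
  }
  design_data(df[[outcome_column]], mat, colnames(mat))
}

#' Write a design table to CSV/TSV
#'
#' @param data A [design_data()] object.
#' @param path Output path; the extension picks the delimiter as in
#'   [read_design()].
#' @param outcome_column Name for the outcome column (default `"outcome"`).
#' @return `path`, invisibly.
#' @export
write_design <- function(data, path, outcome_column = "outcome") {
  stopifnot(inherits(data, "design_data"))
  if (outcome_column %in% data$names)
    stop("outcome column name clashes with a covariate", call. = FALSE)
  df <- data.frame(data$outcome, data$covariates, check.names = FALSE)
  names(df)[1L] <- outcome_column
  write.table(df, path, sep = delim_for(path), row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

trace_header <- function(names) {
  paste(c("iteration", "elapsed_s", "AIC", "BIC", names), collapse = "\t")
}

format_trace_line <- function(rec, inclusion) {
  paste(c(rec$iteration,
          sprintf("%.6f", c(rec$elapsed_s, rec$aic, rec$bic)),
          inclusion), collapse = "\t")
}

# used by run_farms() for live appending during a run
append_trace_line <- function(path, rec, inclusion, names, header = FALSE) {
  if (header) cat(trace_header(names), "\n", sep = "", file = path)
  cat(format_trace_line(rec, inclusion), "\n", sep = "", file = path,
      append = TRUE)
}

#' Write a FARMS iteration trace file
#'
#' Tab-delimited text: a header line `iteration elapsed_s AIC BIC` followed
#' by all covariate names, then one row per iteration with the criterion
#' values (6 decimals) and a 0/1 inclusion flag per covariate.  The same
#' format is appended live during [run_farms()] when its `trace_file`
#' argument is set.
#'
#' @param result A [run_farms()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_trace()]
#' @export
write_trace <- function(result, path) {
  stopifnot(inherits(result, "farms_result"))
  lines <- trace_header(result$names)
  for (i in seq_len(nrow(result$trace)))
    lines <- c(lines, format_trace_line(result$trace[i, ],
                                        result$inclusion[i, ]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FARMS iteration trace file
#'
#' @param path Path to a file written by [write_trace()] (or appended
#'   during a run).
#' @return A list with `trace` (data frame: `iteration`, `elapsed_s`,
#'   `aic`, `bic`) and `inclusion` (iterations x p 0/1 integer matrix with
#'   the covariate names as column names).
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines)) stop("empty trace file: ", path, call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 4L ||
      !identical(header[1:4], c("iteration", "elapsed_s", "AIC", "BIC")))
    stop("malformed trace header in '", path, "'", call. = FALSE)
  vars <- header[-(1:4)]
  body <- lines[-1L]
  body <- body[nzchar(body)]
  n <- length(body)
  trace <- data.frame(iteration = integer(n), elapsed_s = numeric(n),
                      aic = numeric(n), bic = numeric(n))
  inclusion <- matrix(0L, n, length(vars), dimnames = list(NULL, vars))
  for (i in seq_len(n)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 4L + length(vars))
      stop("malformed trace row at line ", i + 1L, ": expected ",
           4L + length(vars), " fields, found ", length(f), call. = FALSE)
    vals <- suppressWarnings(as.numeric(f))
    if (anyNA(vals))
      stop("non-numeric field in trace row at line ", i + 1L, call. = FALSE)
    incl <- as.integer(vals[-(1:4)])
    if (!all(incl %in% c(0L, 1L)))
      stop("inclusion flags must be 0/1 at line ", i + 1L, call. = FALSE)
    trace$iteration[i] <- as.integer(vals[1L])
    trace$elapsed_s[i] <- vals[2L]
    trace$aic[i] <- vals[3L]
    trace$bic[i] <- vals[4L]
    inclusion[i, ] <- incl
  }
  list(trace = trace, inclusion = inclusion)
}

#' Write a final-model report as JSON
#'
#' Machine-readable twin of the in-memory result: selected variable names,
#' subset size, `n`, `k`, RSS and all applicable criterion values, plus
#' iteration count and convergence flag for FARMS results.
#'
#' @param result A `"farms_result"` or `"fit_summary"`.
#' @param path Output path.
#' @param names Covariate names (taken from the result when available).
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, path, names = NULL) {
  if (inherits(result, "farms_result")) {
    fit <- result$final_fit
    if (is.null(names)) names <- result$names
    extra <- list(n_iterations = result$n_iterations,
                  converged = result$converged)
  } else if (inherits(result, "fit_summary")) {
    fit <- result
    extra <- list()
  } else stop("unsupported result object", call. = FALSE)
  crit <- list(rss = fit$rss,
               r2 = 1 - fit$rss / fit$tss,
               adjr2 = 1 - (fit$rss / (fit$n - fit$k)) /
                 (fit$tss / (fit$n - 1)))
  if (fit$rss > 0) {
    crit$aic <- criterion_value(fit, "AIC")
    crit$bic <- criterion_value(fit, "BIC")
  }
  obj <- c(list(variables = if (is.null(names)) fit$subset else
                  names[fit$subset],
                n_variables = length(fit$subset),
                n = fit$n, k = fit$k,
                rank_deficient = fit$rank_deficient),
           crit, extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
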