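#' Construct a regression design
#'
#' Bundles one continuous outcome with a matrix of candidate covariates.
#' In the motivating application the outcome is log10 HIV viral load and the
#' covariates are 0/1 carriage indicators for HLA class I alleles and
#' response indicators for overlapping peptides (OLP), but any numeric
#' covariates are accepted.
#'
#' @param outcome Numeric vector of length `n >= 2`, no missing values.
#' @param covariates Numeric `n x p` matrix (or data frame of numeric
#'   columns), no missing values; `p = 0` is allowed.
#' @param names Character vector of `p` unique column labels; defaults to
#'   the matrix column names.
#' @return An object of class `"design_data"`: a list with `outcome`,
#'   `covariates` (matrix with the labels as column names) and `names`.
#' @examples
#' d <- design_data(rnorm(10), matrix(rbinom(30, 1, 0.3), 10),
#'                  c("A*02", "B*35", "C*07"))
#' d
#' @export
design_data <- function(outcome, covariates, names = colnames(covariates)) {
  outcome <- as.numeric(outcome)
  if (is.data.frame(covariates)) covariates <- as.matrix(covariates)
  if (is.null(covariates)) covariates <- matrix(numeric(0), length(outcome), 0)
  if (!is.matrix(covariates)) covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  n <- length(outcome)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (nrow(covariates) != n)
    stop("covariates have ", nrow(covariates), " rows but outcome has length ",
         n, call. = FALSE)
  if (anyNA(outcome)) stop("missing values in outcome", call. = FALSE)
  if (anyNA(covariates)) {
    bad <- which(is.na(covariates), arr.ind = TRUE)
    stop("missing values in covariates (first at row ", bad[1, 1],
         ", column ", bad[1, 2], ")", call. = FALSE)
  }
  p <- ncol(covariates)
  if (is.null(names)) names <- if (p) paste0("V", seq_len(p)) else character(0)
  names <- as.character(names)
  if (length(names) != p) stop("need exactly ", p, " column names", call. = FALSE)
  if (anyDuplicated(names))
    stop("duplicate covariate names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "), call. = FALSE)
  colnames(covariates) <- names
  structure(list(outcome = outcome, covariates = covariates, names = names),
            class = "design_data")
}

#' @export
print.design_data <- function(x, ...) {
  cat("<design_data: n = ", length(x$outcome), ", p = ", length(x$names),
      " covariates>\n", sep = "")
  invisible(x)
}

# resolve a subset given as names or indices to sorted integer indices
resolve_vars <- function(data, vars, what = "subset") {
  if (is.null(vars) || length(vars) == 0L) return(integer(0))
  if (is.character(vars)) {
    idx <- match(vars, data$names)
    if (anyNA(idx))
      stop("unknown variable(s) in ", what, ": ",
           paste(vars[is.na(idx)], collapse = ", "), call. = FALSE)
  } else {
    idx <- as.integer(vars)
    p <- length(data$names)
    if (any(idx < 1L | idx > p))
      stop("invalid variable index in ", what, ": ",
           paste(idx[idx < 1L | idx > p], collapse = ", "),
           " (p = ", p, ")", call. = FALSE)
  }
  if (anyDuplicated(idx))
    stop("duplicated variables in ", what, call. = FALSE)
  sort(idx)
}

#' Ordinary least squares on a covariate subset
#'
#' Fits the linear model of the outcome on the given covariate subset, with
#' an intercept always included, and returns the summary quantities that the
#' selection criteria need.  Rank-deficient designs are handled by a pivoted
#' QR least-squares solution; the effective number of estimated coefficients
#' then drops to the design rank and the fit is flagged.
#'
#' @param data A [design_data()] object.
#' @param subset Covariate indices or names (possibly empty for the
#'   intercept-only model).
#' @return An object of class `"fit_summary"`: list with `subset` (sorted
#'   integer indices), `n`, `k` (estimated mean-model coefficients including
#'   the intercept), `rss`, `tss`, `rank_deficient`, and `coefficients`.
#' @examples
#' d <- design_data(rnorm(20), matrix(rnorm(60), 20), c("a", "b", "c"))
#' fit_ols(d, c("a", "c"))
#' fit_ols(d, integer(0))$rss  # == tss for the intercept-only model
#' @export
fit_ols <- function(data, subset = integer(0)) {
  stopifnot(inherits(data, "design_data"))
  subset <- resolve_vars(data, subset)
  y <- data$outcome
  n <- length(y)
  if (n <= length(subset) + 1L)
    stop("cannot fit subset {", paste(data$names[subset], collapse = ", "),
         "}: n = ", n, " <= k = ", length(subset) + 1L, call. = FALSE)
  X <- cbind(`(Intercept)` = 1, data$covariates[, subset, drop = FALSE])
  qx <- qr(X)
  rank <- qx$rank
  res <- qr.resid(qx, y)
  rss <- sum(res * res)
  tss <- sum((y - mean(y))^2)
  structure(list(subset = subset, n = n, k = rank, rss = rss, tss = tss,
                 rank_deficient = rank < ncol(X),
                 coefficients = qr.coef(qx, y)),
            class = "fit_summary")
}

#' @export
print.fit_summary <- function(x, ...) {
  cat("<fit_summary: ", length(x$subset), " covariate(s), n = ", x$n,
      ", k = ", x$k, ", rss = ", format(x$rss, digits = 6),
      if (x$rank_deficient) ", RANK DEFICIENT" else "", ">\n", sep = "")
  invisible(x)
}
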