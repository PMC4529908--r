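#' Log-transform viral loads with detection-limit flooring
#'
#' Plasma viral loads below the assay's lower detection limit (50 copies/mL
#' for the motivating cohorts) are set to a fixed value just under the
#' limit (49 copies/mL) and the whole vector is then log10-transformed,
#' yielding the outcome used throughout the package.
#'
#' @param values Viral loads in copies/mL; all entries must be positive.
#' @param detection_limit Assay lower detection limit (default 50).
#' @param floor_value Replacement for values below the limit (default 49).
#' @return `log10` of the floored values.
#' @examples
#' transform_viral_load(c(37800, 30, 131500))
#' @export
transform_viral_load <- function(values, detection_limit = 50,
                                 floor_value = 49) {
  values <- as.numeric(values)
  if (any(!is.finite(values) | values <= 0)) {
    bad <- which(!is.finite(values) | values <= 0)
    stop("non-positive viral load at position(s) ",
         paste(head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "", call. = FALSE)
  }
  values[values < detection_limit] <- floor_value
  log10(values)
}

#' Box-Cox transformation parameter by profile likelihood
#'
#' Maximum-likelihood estimate of the one-parameter Box-Cox lambda over a
#' grid (default -2 to 2 in steps of 0.001).  A lambda near 0 indicates
#' that a log transformation normalizes the data; near 1, that the data are
#' already close to normal.
#'
#' @param values Positive numeric vector, length >= 2, non-constant.
#' @param lambda_grid Candidate lambdas.
#' @return The grid value maximizing the profile log-likelihood, with the
#'   profile stored in `attr(, "profile")` (data frame `lambda`, `loglik`).
#' @examples
#' set.seed(1)
#' boxcox_lambda(exp(rnorm(500)))  # close to 0: log-normal data
#' @export
boxcox_lambda <- function(values, lambda_grid = seq(-2, 2, by = 0.001)) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (any(!is.finite(values) | values <= 0))
    stop("Box-Cox requires strictly positive values", call. = FALSE)
  if (max(values) == min(values))
    stop("constant input: lambda is unidentifiable", call. = FALSE)
  slog <- sum(log(values))
  ll <- vapply(lambda_grid, function(lam) {
    z <- if (abs(lam) < 1e-12) log(values) else (values^lam - 1) / lam
    v <- mean((z - mean(z))^2)
    -n / 2 * log(v) + (lam - 1) * slog
  }, numeric(1))
  out <- lambda_grid[which.max(ll)]
  attr(out, "profile") <- data.frame(lambda = lambda_grid, loglik = ll)
  out
}

#' Binary carriage matrix from long-format allele records
#'
#' Converts per-subject HLA typing records (one row per observed allele,
#' at most two per locus per subject) into a subjects x alleles 0/1
#' carriage matrix: homozygotes are coded 1, not 2.  Columns are the
#' distinct alleles observed, in lexicographic order; rows follow the order
#' in which subjects first appear.
#'
#' @param records Data frame with columns `subject_id`, `locus` (one of
#'   `"A"`, `"B"`, `"C"`) and `allele` (e.g. `"A*02"`).
#' @return Integer 0/1 matrix with subject ids as row names and alleles as
#'   column names.
#' @export
binarize_alleles <- function(records) {
  records <- as.data.frame(records)
  need <- c("subject_id", "locus", "allele")
  if (!all(need %in% names(records)))
    stop("records need columns subject_id, locus, allele", call. = FALSE)
  if (!all(records$locus %in% c("A", "B", "C")))
    stop("locus must be one of A, B, C", call. = FALSE)
  cnt <- table(records$subject_id, records$locus)
  if (any(cnt > 2L)) {
    bad <- which(cnt > 2L, arr.ind = TRUE)[1L, ]
    stop("subject ", rownames(cnt)[bad[1L]], " has more than 2 alleles at ",
         "locus ", colnames(cnt)[bad[2L]], call. = FALSE)
  }
  subjects <- unique(as.character(records$subject_id))
  alleles <- sort(unique(as.character(records$allele)))
  mat <- matrix(0L, length(subjects), length(alleles),
                dimnames = list(subjects, alleles))
  mat[cbind(match(as.character(records$subject_id), subjects),
            match(as.character(records$allele), alleles))] <- 1L
  mat
}

#' Binary response matrix from peptide-response magnitudes
#'
#' Converts an assay-magnitude matrix (subjects x peptides) into the 0/1
#' response indicators used as covariates.  By default any strictly
#' positive magnitude counts as a response (the qualitative response call
#' is made upstream of this package); an explicit `threshold` switches to
#' `magnitude >= threshold`.
#'
#' @param magnitudes Non-negative numeric matrix.
#' @param threshold Optional non-negative response threshold.
#' @return Integer 0/1 matrix with the same dimnames.
#' @export
binarize_olp <- function(magnitudes, threshold = NULL) {
  magnitudes <- as.matrix(magnitudes)
  if (any(magnitudes < 0))
    stop("negative response magnitudes are invalid", call. = FALSE)
  out <- if (is.null(threshold)) magnitudes > 0 else {
    if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
    magnitudes >= threshold
  }
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(magnitudes)
  out
}

#' Quadratic and interaction feature expansion
#'
#' Appends squared columns (named `name^2`) and/or pairwise products
#' (named `a:b`) to a design.  Columns that are constant after expansion --
#' notably squares of 0/1 covariates, which equal the original column and
#' would be aliased -- are dropped with a warning, so expansion is a no-op
#' on purely binary designs with `quadratic = TRUE`.
#'
#' @param data A [design_data()] object.
#' @param quadratic Add squared terms?
#' @param interactions Add pairwise products?
#' @return A new [design_data()] with the extra columns appended.
#' @export
expand_features <- function(data, quadratic = FALSE, interactions = FALSE) {
  stopifnot(inherits(data, "design_data"))
  X <- data$covariates
  p <- ncol(X)
  new_cols <- list()
  if (quadratic && p) for (j in seq_len(p))
    new_cols[[paste0(data$names[j], "^2")]] <- X[, j]^2
  if (interactions && p > 1L) for (j in seq_len(p - 1L)) for (l in (j + 1L):p)
    new_cols[[paste0(data$names[j], ":", data$names[l])]] <- X[, j] * X[, l]
  if (!length(new_cols)) return(data)
  keep <- vapply(new_cols, function(v) max(v) > min(v), logical(1))
  # a square of a 0/1 column duplicates it exactly; drop those too
  if (quadratic) for (j in seq_len(p)) {
    nm <- paste0(data$names[j], "^2")
    if (nm %in% names(new_cols)[keep] && all(new_cols[[nm]] == X[, j]))
      keep[nm] <- FALSE
  }
  if (any(!keep))
    warning("dropping ", sum(!keep), " constant or duplicate expansion ",
            "column(s): ", paste(head(names(new_cols)[!keep], 5L),
                                 collapse = ", "),
            if (sum(!keep) > 5L) " ..." else "", call. = FALSE)
  new_cols <- new_cols[keep]
  if (!length(new_cols)) return(data)
  if (any(names(new_cols) %in% data$names))
    stop("expansion name collision: ",
         paste(intersect(names(new_cols), data$names), collapse = ", "),
         call. = FALSE)
  design_data(data$outcome,
              cbind(X, do.call(cbind, new_cols)),
              c(data$names, names(new_cols)))
}
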