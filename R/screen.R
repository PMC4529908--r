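#' Univariate carriage screen with FDR q-values
#'
#' For every binary covariate, compares the outcome between carriers
#' (value 1) and non-carriers (value 0) with a two-sided Student's t-test
#' (pooled variance by default, Welch optional), then converts the p-values
#' to q-values and flags covariates significant at the requested false
#' discovery rate (default 10%).
#'
#' The pooled-variance t is computed in closed form so that the degenerate
#' case of identical outcomes in both groups yields `t = 0`, `p = 1`
#' rather than an error.  A covariate with an empty carrier or non-carrier
#' group cannot be tested and is flagged `untestable` with `NA` statistics;
#' q-values are computed over the testable covariates only.
#'
#' @param data A [design_data()] object whose covariates are all 0/1.
#' @param fdr Significance threshold on the q-value (default 0.10).
#' @param welch Use the Welch unequal-variance t-test instead of the
#'   pooled-variance Student test.
#' @param q_method `"BH"` (default): Benjamini-Hochberg adjusted p-values.
#'   `"storey"`: Storey-type q-values with the natural estimate
#'   \eqn{\hat\pi_0 = \min(1, 2\,\overline{I(p > 0.5)})}.
#' @return A data frame with one row per covariate: `variable`, `n1`
#'   (carriers), `n0`, `mean1`, `mean0`, `t_stat`, `p_value`, `q_value`,
#'   `significant`, `untestable`.
#' @examples
#' cohort <- generate_cohort(n = 80, p = 6, n_signal = 1, seed = 2)
#' univariate_screen(cohort$data)
#' @export
univariate_screen <- function(data, fdr = 0.10, welch = FALSE,
                              q_method = c("BH", "storey")) {
  stopifnot(inherits(data, "design_data"))
  q_method <- match.arg(q_method)
  X <- data$covariates; y <- data$outcome
  p <- ncol(X)
  for (j in seq_len(p))
    if (!all(X[, j] %in% c(0, 1)))
      stop("covariate '", data$names[j], "' is not binary; the univariate ",
           "screen requires 0/1 carriage indicators", call. = FALSE)

  rows <- lapply(seq_len(p), function(j) {
    carrier <- X[, j] == 1
    n1 <- sum(carrier); n0 <- sum(!carrier)
    if (n1 == 0L || n0 == 0L)
      return(data.frame(variable = data$names[j], n1 = n1, n0 = n0,
                        mean1 = NA_real_, mean0 = NA_real_,
                        t_stat = NA_real_, p_value = NA_real_,
                        untestable = TRUE, stringsAsFactors = FALSE))
    y1 <- y[carrier]; y0 <- y[!carrier]
    m1 <- mean(y1); m0 <- mean(y0)
    if (welch && n1 > 1L && n0 > 1L) {
      v1 <- var(y1) / n1; v0 <- var(y0) / n0
      se <- sqrt(v1 + v0)
      df <- (v1 + v0)^2 / (v1^2 / (n1 - 1) + v0^2 / (n0 - 1))
    } else {
      sp2 <- (sum((y1 - m1)^2) + sum((y0 - m0)^2)) / (n1 + n0 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n0))
      df <- n1 + n0 - 2
    }
    tval <- if (se == 0) {
      if (m1 == m0) 0 else sign(m1 - m0) * Inf
    } else (m1 - m0) / se
    pval <- if (is.infinite(tval)) 0 else 2 * pt(-abs(tval), df)
    data.frame(variable = data$names[j], n1 = n1, n0 = n0,
               mean1 = m1, mean0 = m0, t_stat = tval, p_value = pval,
               untestable = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  testable <- !out$untestable
  if (any(testable))
    out$q_value[testable] <- compute_q_values(out$p_value[testable], q_method)
  out$significant <- !is.na(out$q_value) & out$q_value <= fdr
  out[, c("variable", "n1", "n0", "mean1", "mean0", "t_stat",
          "p_value", "q_value", "significant", "untestable")]
}

compute_q_values <- function(p, method) {
  if (method == "BH") return(p.adjust(p, method = "BH"))
  # Storey: pi0 from the flat right half of the p-value distribution,
  # then the usual step-up construction
  m <- length(p)
  pi0 <- min(1, mean(p > 0.5) / 0.5)
  o <- order(p)
  q <- pi0 * m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}
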