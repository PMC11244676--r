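#' Spearman correlation matrix with pairwise-complete deletion
#'
#' Rank correlation (average ranks for ties) between every pair of the
#' requested variables. Each pair uses its own pairwise-complete
#' observations, so a variable with missing values (e.g. a case whose
#' blooming volume could not be segmented) only shrinks the sample for its
#' own pairs. Two-sided p-values use the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} degrees of freedom;
#' no multiplicity correction is applied.
#'
#' @param cases data frame (e.g. a loaded study table or [tally_scores()]
#'   output merged with metrics).
#' @param variables character vector of >= 2 column names; each column must
#'   be numeric.
#' @return An object of class `correlation_matrix`: list with `variables`,
#'   `rho` (symmetric, unit diagonal), `p`, `n_used`, and `flags` (character
#'   matrix, `"constant"` where a variable was constant in the pairwise
#'   sample and the coefficient is undefined).
#' @export
spearman_matrix <- function(cases, variables) {
  stopifnot(is.data.frame(cases), length(variables) >= 2L)
  missing_vars <- setdiff(variables, names(cases))
  if (length(missing_vars) > 0)
    stop("variables not found: ", paste(missing_vars, collapse = ", "))
  if (nrow(cases) < 4L) stop("need at least 4 cases")
  m <- length(variables)
  rho <- p <- matrix(NA_real_, m, m, dimnames = list(variables, variables))
  n_used <- matrix(0L, m, m, dimnames = list(variables, variables))
  flags <- matrix("", m, m, dimnames = list(variables, variables))
  diag(rho) <- 1; diag(p) <- 0
  for (i in seq_len(m)) {
    n_used[i, i] <- sum(!is.na(cases[[variables[i]]]))
    for (j in seq_len(m)) {
      if (j <= i) next
      x <- as.numeric(cases[[variables[i]]])
      y <- as.numeric(cases[[variables[j]]])
      ok <- stats::complete.cases(x, y)
      n <- sum(ok)
      n_used[i, j] <- n_used[j, i] <- n
      if (n < 4L) { flags[i, j] <- flags[j, i] <- "insufficient"; next }
      x <- x[ok]; y <- y[ok]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        flags[i, j] <- flags[j, i] <- "constant"
        next
      }
      r <- stats::cor(rank(x), rank(y))
      rho[i, j] <- rho[j, i] <- r
      if (abs(r) >= 1) {
        p[i, j] <- p[j, i] <- 0
      } else {
        tt <- r * sqrt((n - 2) / (1 - r^2))
        p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tt), n - 2)
      }
    }
  }
  structure(
    list(variables = variables, rho = rho, p = p, n_used = n_used,
         flags = flags),
    class = "correlation_matrix"
  )
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  cat("<correlation_matrix> Spearman rho (pairwise complete):\n")
  print(round(x$rho, digits))
  invisible(x)
}
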