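# Two-way (subjects x raters) ANOVA mean squares underlying both ICC forms.
anova_decomposition <- function(mat) {
  mat <- as.matrix(mat)
  if (any(is.na(mat))) stop("ICC requires a complete case-by-rater matrix")
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2L || k < 2L) stop("need at least 2 cases and 2 raters")
  grand <- mean(mat)
  rowm <- rowMeans(mat)
  colm <- colMeans(mat)
  ss_rows <- k * sum((rowm - grand)^2)
  ss_cols <- n * sum((colm - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- max(ss_tot - ss_rows - ss_cols, 0)
  structure(
    list(
      ms_rows = ss_rows / (n - 1),
      ms_cols = ss_cols / (k - 1),
      ms_error = ss_err / ((n - 1) * (k - 1)),
      n_subjects = n, n_raters = k
    ),
    class = "anova_decomposition"
  )
}

#' Inter-reader reliability: ICC(C,k), two-way random, average consistency
#'
#' The average-measures consistency intraclass correlation
#' \eqn{(MS_R - MS_E) / MS_R} from the two-way random-effects decomposition.
#' Consistency ICC ignores systematic between-reader offsets (a constant
#' shift of one reader is absorbed by the rater effect). Significance is the
#' F test \eqn{MS_R / MS_E} with \eqn{(n-1, (n-1)(k-1))} degrees of freedom;
#' the confidence interval is obtained by inverting that F statistic.
#'
#' @param mat complete numeric case-by-reader matrix (e.g. from
#'   [score_matrix()]).
#' @param conf_level confidence level (default 0.95).
#' @return A list of class `icc_result`: `icc`, `p_value`, `ci_low`,
#'   `ci_high`, `type = "ICC(C,k)"`, `anova` (the mean-square
#'   decomposition), and `degenerate` (`TRUE` when the between-case variance
#'   is zero, in which case `icc` is reported as 0).
#' @export
icc_inter <- function(mat, conf_level = 0.95) {
  a <- anova_decomposition(mat)
  n <- a$n_subjects; k <- a$n_raters
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  degenerate <- a$ms_rows <= .Machine$double.eps
  if (degenerate) {
    icc <- 0; p <- 1; ci <- c(NA_real_, NA_real_)
  } else {
    icc <- (a$ms_rows - a$ms_error) / a$ms_rows
    if (a$ms_error <= .Machine$double.eps) {
      p <- 0; ci <- c(1, 1)
    } else {
      f <- a$ms_rows / a$ms_error
      p <- stats::pf(f, df1, df2, lower.tail = FALSE)
      alpha <- 1 - conf_level
      fl <- f / stats::qf(1 - alpha / 2, df1, df2)
      fu <- f * stats::qf(1 - alpha / 2, df2, df1)
      ci <- c(1 - 1 / fl, 1 - 1 / fu)
    }
  }
  structure(
    list(icc = icc, p_value = p, ci_low = ci[1], ci_high = ci[2],
         type = "ICC(C,k)", anova = a, degenerate = degenerate),
    class = "icc_result"
  )
}

#' Intra-reader reliability: ICC(A,k), two-way random, average agreement
#'
#' The average-measures absolute-agreement intraclass correlation
#' \eqn{(MS_R - MS_E) / (MS_R + (MS_C - MS_E)/n)} from the two-way
#' random-effects decomposition, for a case-by-occasion matrix of repeated
#' readings. Unlike the consistency form, a systematic shift between
#' occasions lowers agreement. The confidence interval uses the
#' Satterthwaite construction for single-measure absolute agreement,
#' stepped up to average measures; the p-value is the \eqn{MS_R / MS_E}
#' F test.
#'
#' @param mat complete numeric case-by-occasion matrix.
#' @param conf_level confidence level (default 0.95).
#' @return A list of class `icc_result` (see [icc_inter()]), with
#'   `type = "ICC(A,k)"`.
#' @export
icc_intra <- function(mat, conf_level = 0.95) {
  a <- anova_decomposition(mat)
  n <- a$n_subjects; k <- a$n_raters
  degenerate <- a$ms_rows <= .Machine$double.eps
  denom <- a$ms_rows + (a$ms_cols - a$ms_error) / n
  if (degenerate || denom <= .Machine$double.eps) {
    out <- list(icc = 0, p_value = 1, ci_low = NA_real_, ci_high = NA_real_)
  } else {
    icc <- (a$ms_rows - a$ms_error) / denom
    if (a$ms_error <= .Machine$double.eps && a$ms_cols <= .Machine$double.eps) {
      out <- list(icc = icc, p_value = 0, ci_low = 1, ci_high = 1)
    } else {
      df1 <- n - 1; df2 <- (n - 1) * (k - 1)
      p <- stats::pf(a$ms_rows / max(a$ms_error, .Machine$double.xmin),
                     df1, df2, lower.tail = FALSE)
      # Single-measure absolute-agreement bounds, then Spearman-Brown step-up.
      r1 <- (a$ms_rows - a$ms_error) /
        (a$ms_rows + (k - 1) * a$ms_error + k * (a$ms_cols - a$ms_error) / n)
      aa <- k * r1 / (n * (1 - r1))
      bb <- 1 + k * r1 * (n - 1) / (n * (1 - r1))
      v <- (aa * a$ms_cols + bb * a$ms_error)^2 /
        ((aa * a$ms_cols)^2 / (k - 1) + (bb * a$ms_error)^2 / ((n - 1) * (k - 1)))
      alpha <- 1 - conf_level
      f_l <- stats::qf(1 - alpha / 2, n - 1, v)
      f_u <- stats::qf(1 - alpha / 2, v, n - 1)
      l1 <- n * (a$ms_rows - f_l * a$ms_error) /
        (f_l * (k * a$ms_cols + (k * n - k - n) * a$ms_error) + n * a$ms_rows)
      u1 <- n * (f_u * a$ms_rows - a$ms_error) /
        (k * a$ms_cols + (k * n - k - n) * a$ms_error + n * f_u * a$ms_rows)
      sb <- function(r) r * k / (1 + (k - 1) * r)
      out <- list(icc = icc, p_value = p, ci_low = sb(l1), ci_high = sb(u1))
    }
  }
  structure(
    c(out, list(type = "ICC(A,k)", anova = a, degenerate = degenerate)),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> %s = %.3f (95%% CI %.3f..%.3f, p = %.3g%s)\n",
              x$type, x$icc, x$ci_low, x$ci_high, x$p_value,
              if (x$degenerate) "; degenerate between-case variance" else ""))
  invisible(x)
}
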