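#' Baseline-category multinomial logit model of ordinal quality scores
#'
#' Fits \eqn{\ln P(score = s) / P(score = 1) = \beta_{0s} + x' \beta_s} for
#' each observed score category \eqn{s > 1} by maximum likelihood
#' (a baseline-category multinomial logit; each reader-case score is one
#' observation). Acquisition/reconstruction factors are compared against
#' fixed reference levels (by default iMAR `None`, keV `40`, kernel
#' `Qr36f`), which carry coefficient 0 by construction.
#'
#' @param scores a `reader_scores` data frame (columns `case_id`,
#'   `reader_id`, `question`, `score`).
#' @param question which question's scores to model.
#' @param covariates data frame with `case_id` plus predictor columns,
#'   merged onto the scores.
#' @param predictors character vector of covariate columns to use.
#' @param ref_levels named character vector of reference levels for factor
#'   predictors.
#' @param maxit maximum optimizer iterations passed to [nnet::multinom()].
#' @return An object of class `ordinal_fit`: `coefficients`, `std_errors`,
#'   `p_values` (Wald, per coefficient) — matrices with one row per
#'   non-reference response category — plus `log_likelihood`,
#'   `reference_levels`, `response_levels`, `excluded_categories` (score
#'   values never observed, excluded with a warning), `dropped_predictors`
#'   (zero-variance columns), `separation` (logical matrix flagging
#'   practically unbounded coefficients), and the underlying `model`.
#' @export
fit_ordinal_model <- function(scores, question, covariates,
                              predictors = c("kvp", "iq", "vmi", "imar",
                                             "kernel", "slice_mm"),
                              ref_levels = c(imar = "None", vmi = "40",
                                             kernel = "Qr36f"),
                              maxit = 500) {
  stopifnot(is.data.frame(scores), is.data.frame(covariates),
            "case_id" %in% names(covariates))
  sub <- scores[scores$question == question, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no scores for question ", question)
  missing_pred <- setdiff(predictors, names(covariates))
  if (length(missing_pred) > 0)
    stop("predictors not in covariates: ", paste(missing_pred, collapse = ", "))
  df <- merge(sub[c("case_id", "score")], covariates[c("case_id", predictors)],
              by = "case_id")

  observed <- sort(unique(df$score))
  if (length(observed) < 2L)
    stop("need at least 2 observed response categories")
  excluded <- setdiff(1:5, observed)
  if (length(excluded) > 0)
    warning("response categories never observed and excluded: ",
            paste(excluded, collapse = ", "))
  df$score <- factor(df$score, levels = observed)

  dropped <- character(0)
  for (v in predictors) {
    col <- df[[v]]
    if (is.character(col)) col <- df[[v]] <- factor(col)
    if (length(unique(col[!is.na(col)])) < 2L) {
      dropped <- c(dropped, v)
      df[[v]] <- NULL
    } else if (is.factor(col)) {
      col <- droplevels(col)
      if (v %in% names(ref_levels) && ref_levels[[v]] %in% levels(col))
        col <- stats::relevel(col, ref = ref_levels[[v]])
      df[[v]] <- col
    }
  }
  if (length(dropped) > 0)
    warning("zero-variance predictors dropped: ",
            paste(dropped, collapse = ", "))
  used <- setdiff(predictors, dropped)
  form <- if (length(used) == 0L) score ~ 1 else
    stats::as.formula(paste("score ~", paste(used, collapse = " + ")))

  fit <- nnet::multinom(form, data = df, trace = FALSE, maxit = maxit,
                        Hess = TRUE)
  co <- stats::coef(fit)
  if (is.null(dim(co)))
    co <- matrix(co, nrow = 1,
                 dimnames = list(levels(df$score)[2], names(co)))
  se <- summary(fit)$standard.errors
  if (is.null(dim(se)))
    se <- matrix(se, nrow = 1, dimnames = dimnames(co))
  z <- co / se
  pv <- 2 * stats::pnorm(-abs(z))
  separation <- abs(co) > 15
  if (any(separation))
    warning("possible complete separation: some coefficients are ",
            "practically unbounded")

  structure(
    list(
      coefficients = co, std_errors = se, p_values = pv,
      log_likelihood = as.numeric(stats::logLik(fit)),
      reference_levels = ref_levels,
      response_levels = observed,
      excluded_categories = excluded,
      dropped_predictors = dropped,
      separation = separation,
      n_obs = nrow(df),
      model = fit
    ),
    class = "ordinal_fit"
  )
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf(
    "<ordinal_fit> baseline-category logit, %d obs, categories %s (ref %s), logLik %.2f\n",
    x$n_obs, paste(x$response_levels, collapse = "/"),
    x$response_levels[1], x$log_likelihood))
  print(round(x$coefficients, 3))
  invisible(x)
}

#' @importFrom stats pnorm relevel
NULL
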