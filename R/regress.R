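#' Regression models for artifact metrics
#'
#' Fits an artifact metric (response) on acquisition/reconstruction
#' covariates by ordinary least squares, either on the original scale
#' (`link = "linear"`) or as a log-linear power-law model (`link = "log"`):
#' the response is log-transformed and numeric covariates enter
#' log-transformed, so a factor coefficient \eqn{\beta} means a
#' \eqn{(e^{\beta} - 1) \times 100} percent change in the predicted metric
#' and a numeric coefficient is a power-law exponent. Factors are dummy
#' coded against fixed reference levels. Optional bidirectional stepwise
#' selection by AIC starts from the main-effects model and may add the
#' requested interaction terms (interactions are only reachable when both
#' parents are in the model, and dropping a parent before its interaction
#' is never proposed).
#'
#' @param cases data frame of cases (e.g. [load_fixture()]`$records`).
#' @param response response column: one of the artifact metrics, e.g.
#'   `"bloom_vol"`, `"sd_artifact"`, `"amplitude_low_freq"`, `"diff_hu"`.
#' @param link `"linear"` or `"log"`. A log link requires a strictly
#'   positive response; a signed response (Diff_HU) is fit on its absolute
#'   value and the convention is recorded in the result.
#' @param candidate_terms character vector of main effects (column names)
#'   and optional interactions (`"a:b"`).
#' @param selection `"none"` (fit all candidate terms) or `"stepwise_aic"`.
#' @param ref_levels named character vector of factor reference levels.
#' @param vmi_coding `"factor"` keeps keV/T3D settings as unordered factor
#'   levels; `"numeric"` converts `vmi` to its keV value and drops cases
#'   with non-numeric levels (poly-energetic `T3D`, `SPP-70`), which is the
#'   coding a power-law model requires.
#' @return An object of class `metric_model_fit`: `response`, `link`,
#'   `terms` (selected), `coefficients` (estimate, SE, p), `adjusted_r2`,
#'   `aic`, `sigma` (residual SD on the fitted scale), `n_obs`,
#'   `n_dropped` (rows lost to missing response or non-numeric keV),
#'   `aliased` (terms dropped for rank deficiency), `sign_convention`, and
#'   the underlying `model`.
#' @export
fit_metric_model <- function(cases, response, link = c("linear", "log"),
                             candidate_terms = c("kvp", "iq", "vmi",
                                                 "imar", "kernel",
                                                 "slice_mm"),
                             selection = c("none", "stepwise_aic"),
                             ref_levels = c(imar = "None", vmi = "40",
                                            kernel = "Qr36f"),
                             vmi_coding = c("factor", "numeric")) {
  link <- match.arg(link)
  selection <- match.arg(selection)
  vmi_coding <- match.arg(vmi_coding)
  stopifnot(is.data.frame(cases))
  if (!response %in% names(cases)) stop("response column not found: ", response)

  main_terms <- unique(unlist(strsplit(candidate_terms, ":", fixed = TRUE)))
  missing_cols <- setdiff(main_terms, names(cases))
  if (length(missing_cols) > 0)
    stop("candidate term columns not found: ",
         paste(missing_cols, collapse = ", "))

  df <- cases[c(response, main_terms)]
  n0 <- nrow(df)
  df <- df[!is.na(df[[response]]), , drop = FALSE]

  sign_convention <- "as-is"
  y <- df[[response]]
  if (link == "log") {
    if (any(y < 0)) {
      sign_convention <- "absolute value"
      y <- abs(y)
    }
    if (any(y <= 0))
      stop("log link requires strictly positive responses")
    df[[response]] <- log(y)
  }

  if ("vmi" %in% main_terms && vmi_coding == "numeric") {
    kev <- suppressWarnings(as.numeric(as.character(df$vmi)))
    df$vmi <- kev
    df <- df[!is.na(df$vmi), , drop = FALSE]
  }

  for (v in main_terms) {
    col <- df[[v]]
    if (is.character(col)) col <- factor(col)
    if (is.factor(col)) {
      col <- droplevels(col)
      if (v %in% names(ref_levels) && ref_levels[[v]] %in% levels(col))
        col <- stats::relevel(col, ref = ref_levels[[v]])
      df[[v]] <- col
    } else if (link == "log") {
      if (any(col <= 0)) stop("log link requires positive covariate ", v)
      df[[v]] <- log(col)
    }
  }
  n_dropped <- n0 - nrow(df)

  # Constant columns cannot enter the design.
  usable <- vapply(main_terms, function(v)
    length(unique(df[[v]])) > 1L, logical(1))
  keep_main <- main_terms[usable]
  keep_terms <- candidate_terms[vapply(candidate_terms, function(tm) {
    all(strsplit(tm, ":", fixed = TRUE)[[1]] %in% keep_main)
  }, logical(1))]
  if (length(keep_terms) == 0L) stop("no usable (non-constant) candidate terms")

  full_form <- stats::as.formula(
    paste(response, "~", paste(keep_terms, collapse = " + ")))
  if (selection == "stepwise_aic") {
    start_form <- stats::as.formula(
      paste(response, "~",
            paste(intersect(keep_main, keep_terms), collapse = " + ")))
    fit0 <- stats::lm(start_form, data = df)
    fit <- stats::step(fit0,
                       scope = list(lower = stats::as.formula(paste(response, "~ 1")),
                                    upper = full_form),
                       direction = "both", trace = 0)
  } else {
    fit <- stats::lm(full_form, data = df)
  }

  sm <- summary(fit)
  aliased <- names(sm$aliased)[sm$aliased]
  ct <- sm$coefficients
  structure(
    list(
      response = response, link = link,
      terms = attr(stats::terms(fit), "term.labels"),
      coefficients = data.frame(
        term = rownames(ct), estimate = ct[, 1], std_error = ct[, 2],
        p_value = ct[, 4], row.names = NULL
      ),
      adjusted_r2 = sm$adj.r.squared,
      aic = stats::AIC(fit),
      sigma = sm$sigma,
      n_obs = nrow(df), n_dropped = n_dropped,
      aliased = aliased,
      sign_convention = sign_convention,
      ref_levels = ref_levels,
      model = fit
    ),
    class = "metric_model_fit"
  )
}

#' @export
print.metric_model_fit <- function(x, ...) {
  cat(sprintf(
    "<metric_model_fit> %s ~ %s (%s link%s), n = %d, adj R^2 = %.4f, AIC = %.1f\n",
    x$response, paste(x$terms, collapse = " + "), x$link,
    if (x$sign_convention != "as-is") paste0("; ", x$sign_convention) else "",
    x$n_obs, x$adjusted_r2, x$aic))
  invisible(x)
}

#' Express regression coefficients as percent change of the metric
#'
#' Under a log link, a coefficient \eqn{\beta} corresponds to a
#' \eqn{(e^{\beta} - 1) \times 100} percent change in the predicted metric
#' when that factor level replaces the reference level (or per unit of a
#' log-covariate), holding everything else constant. Under a linear link
#' coefficients are already in response units, so they are returned
#' unchanged with a unit flag.
#'
#' @param fit a [fit_metric_model()] result.
#' @return Data frame: `term`, `estimate` (the raw coefficient), `effect`
#'   (percent change for a log link; response-unit change for linear), and
#'   `unit` (`"percent"` or `"response units"`). The intercept is excluded.
#' @export
coefficients_as_percent_change <- function(fit) {
  stopifnot(inherits(fit, "metric_model_fit"))
  co <- fit$coefficients
  co <- co[co$term != "(Intercept)", , drop = FALSE]
  if (fit$link == "log") {
    data.frame(term = co$term, estimate = co$estimate,
               effect = (exp(co$estimate) - 1) * 100,
               unit = "percent", row.names = NULL)
  } else {
    data.frame(term = co$term, estimate = co$estimate,
               effect = co$estimate,
               unit = "response units", row.names = NULL)
  }
}
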