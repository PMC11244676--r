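ord_scores <- function(score) {
  data.frame(case_id = seq_along(score), reader_id = "R1",
             question = "Q1", score = score, stringsAsFactors = FALSE)
}

test_that("a saturated binary design recovers the closed-form log odds-ratio", {
  # counts: x=0 -> (a=12 score1, b=6 score3); x=1 -> (c=5, d=10)
  score <- c(rep(1, 12), rep(3, 6), rep(1, 5), rep(3, 10))
  x <- c(rep(0, 18), rep(1, 15))
  cov <- data.frame(case_id = seq_along(score), x = x)
  fit <- suppressWarnings(
    fit_ordinal_model(ord_scores(score), "Q1", cov, predictors = "x"))
  # saturated multinomial MLE: intercept ln(b/a), slope ln((d/c)/(b/a))
  expect_equal(fit$coefficients[1, "(Intercept)"], log(6 / 12),
               tolerance = 1e-4)
  expect_equal(fit$coefficients[1, "x"], log((10 / 5) / (6 / 12)),
               tolerance = 1e-4)
})

test_that("zero-variance predictors drop to an intercept-only closed form", {
  score <- c(rep(1, 20), rep(2, 8), rep(4, 12))
  cov <- data.frame(case_id = seq_along(score), kvp = 120)
  warns <- character(0)
  fit <- withCallingHandlers(
    fit_ordinal_model(ord_scores(score), "Q1", cov, predictors = "kvp"),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  expect_true(any(grepl("zero-variance", warns)))
  expect_equal(fit$dropped_predictors, "kvp")
  # intercept-only MLE: ln(n_k / n_1)
  expect_equal(unname(fit$coefficients[, "(Intercept)"]),
               c(log(8 / 20), log(12 / 20)), tolerance = 1e-4)
})

test_that("unobserved categories are excluded with a warning", {
  score <- c(rep(1, 10), rep(5, 10))
  cov <- data.frame(case_id = 1:20, x = rnorm(20))
  expect_warning(
    fit <- fit_ordinal_model(ord_scores(score), "Q1", cov,
                             predictors = "x"),
    "never observed")
  expect_equal(fit$excluded_categories, 2:4)
  expect_equal(fit$response_levels, c(1, 5))
})

test_that("factor reference levels are honoured", {
  set.seed(31)
  n <- 120
  imar <- sample(c("None", "Pacemaker", "HipImplants"), n, replace = TRUE)
  score <- 1 + (runif(n) < ifelse(imar == "None", 0.3, 0.7)) * 2
  cov <- data.frame(case_id = 1:n, imar = imar)
  fit <- suppressWarnings(
    fit_ordinal_model(ord_scores(score), "Q1", cov, predictors = "imar"))
  terms <- colnames(fit$coefficients)
  expect_false("imarNone" %in% terms)          # reference carries 0
  expect_true(all(c("imarPacemaker", "imarHipImplants") %in% terms))
})

test_that("log-likelihood never decreases when a term is added", {
  set.seed(32)
  n <- 150
  cov <- data.frame(case_id = 1:n,
                    x = rnorm(n),
                    z = sample(c("a", "b"), n, replace = TRUE))
  lin <- 0.8 * cov$x
  p3 <- exp(lin) / (1 + exp(lin))
  score <- ifelse(runif(n) < p3, 3, 1)
  s <- ord_scores(score)
  ll1 <- suppressWarnings(
    fit_ordinal_model(s, "Q1", cov, predictors = "x"))$log_likelihood
  ll2 <- suppressWarnings(
    fit_ordinal_model(s, "Q1", cov,
                      predictors = c("x", "z")))$log_likelihood
  expect_gte(ll2 + 1e-6, ll1)
  # exhaustive-grid likelihood oracle for the one-predictor model: the
  # fitted maximum is at least as good as every (intercept, slope) grid point
  grid <- expand.grid(b0 = seq(-2, 2, by = 0.1), b1 = seq(-2, 2, by = 0.1))
  ll_grid <- vapply(seq_len(nrow(grid)), function(i) {
    eta <- grid$b0[i] + grid$b1[i] * cov$x
    sum(ifelse(score == 3, eta, 0) - log(1 + exp(eta)))
  }, numeric(1))
  expect_gte(ll1 + 1e-6, max(ll_grid))
})

test_that("fewer than two observed categories is an error", {
  score <- rep(3, 10)
  cov <- data.frame(case_id = 1:10, x = rnorm(10))
  expect_error(fit_ordinal_model(ord_scores(score), "Q1", cov,
                                 predictors = "x"),
               "2 observed")
})
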