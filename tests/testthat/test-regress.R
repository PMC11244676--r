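test_that("a noiseless log-linear model is recovered to machine precision", {
  set.seed(51)
  n <- 50
  d <- data.frame(
    kvp = sample(c(90, 120, 140), n, replace = TRUE),
    slice_mm = sample(c(0.4, 1, 3), n, replace = TRUE),
    kernel = sample(c("Qr36f", "Qr40f", "Bv56f"), n, replace = TRUE)
  )
  beta <- c(int = 3, kvp = -2, sw = 0.25, k40 = -0.1, k56 = -0.4)
  d$bloom <- exp(beta["int"] + beta["kvp"] * log(d$kvp) +
                   beta["sw"] * log(d$slice_mm) +
                   beta["k40"] * (d$kernel == "Qr40f") +
                   beta["k56"] * (d$kernel == "Bv56f"))
  fit <- suppressWarnings(
    fit_metric_model(d, "bloom", link = "log",
                     candidate_terms = c("kvp", "slice_mm", "kernel")))
  co <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(unname(co["(Intercept)"]), 3, tolerance = 1e-10)
  expect_equal(unname(co["kvp"]), -2, tolerance = 1e-10)
  expect_equal(unname(co["slice_mm"]), 0.25, tolerance = 1e-10)
  expect_equal(unname(co["kernelQr40f"]), -0.1, tolerance = 1e-10)
  expect_equal(unname(co["kernelBv56f"]), -0.4, tolerance = 1e-10)
  expect_equal(fit$adjusted_r2, 1, tolerance = 1e-12)
})

test_that("a two-level factor coefficient is the log-ratio of geometric means", {
  base <- quiet_phantom_spec(seed = 9)
  bat <- generate_case_battery(base, list(bloom_sigma = c(0.3, 1.6)))
  vols <- vapply(bat$cases, function(cs)
    compute_bloom_vol(cs$volume, 800)$volume_cm3, numeric(1))
  # replicate each condition with jitter-free duplicates via a data frame
  d <- data.frame(group = factor(c("lo", "lo", "hi", "hi"),
                                 levels = c("lo", "hi")),
                  bloom = rep(vols, each = 2))
  fit <- suppressWarnings(
    fit_metric_model(d, "bloom", link = "log", candidate_terms = "group"))
  co <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  gm <- function(x) exp(mean(log(x)))
  expect_equal(unname(co["grouphi"]),
               log(gm(d$bloom[d$group == "hi"]) /
                     gm(d$bloom[d$group == "lo"])),
               tolerance = 1e-12)
})

test_that("signed responses under a log link are fit on absolute values", {
  d <- data.frame(kvp = c(90, 90, 120, 120, 140, 140),
                  diff_hu = c(-200, -180, -120, -110, -60, -55))
  fit <- fit_metric_model(d, "diff_hu", link = "log",
                          candidate_terms = "kvp")
  expect_equal(fit$sign_convention, "absolute value")
  expect_lt(fit$coefficients$estimate[2], 0)  # |Diff_HU| falls with kVp
})

test_that("stepwise AIC on pure noise stays parsimonious", {
  set.seed(53)
  hits <- 0L
  for (rep in 1:25) {
    n <- 40
    d <- data.frame(matrix(exp(rnorm(n * 6)), n, 6))
    names(d) <- paste0("x", 1:6)
    d$y <- exp(rnorm(n))
    fit <- fit_metric_model(d, "y", link = "log",
                            candidate_terms = paste0("x", 1:6),
                            selection = "stepwise_aic")
    if (length(fit$terms) <= 2L) hits <- hits + 1L
  }
  expect_gte(hits / 25, 0.6)
})

test_that("stepwise selection keeps a strong true predictor", {
  set.seed(54)
  n <- 60
  d <- data.frame(x1 = exp(rnorm(n)), x2 = exp(rnorm(n)),
                  x3 = exp(rnorm(n)))
  d$y <- exp(1 + 2 * log(d$x1) + rnorm(n, 0, 0.2))
  fit <- fit_metric_model(d, "y", link = "log",
                          candidate_terms = c("x1", "x2", "x3"),
                          selection = "stepwise_aic")
  expect_true("x1" %in% fit$terms)
})

test_that("numeric keV coding drops poly-energetic cases as documented", {
  rec <- load_fixture("patient")$records
  fit <- fit_metric_model(rec, "bloom_vol", link = "log",
                          candidate_terms = c("vmi", "kernel"),
                          vmi_coding = "numeric")
  # T3D (3 cases) and SPP-70 (1 case) have no numeric keV
  expect_equal(fit$n_dropped, 4L)
  expect_equal(fit$n_obs, 23L)
})

test_that("percent-change conversion follows the closed forms", {
  d <- data.frame(x = c(1, 2, 3, 4, 2, 5), y = exp(c(1, 2, 3, 4, 2.2, 5.1)))
  fit <- fit_metric_model(d, "y", link = "log", candidate_terms = "x")
  pc <- coefficients_as_percent_change(fit)
  expect_equal(pc$effect, (exp(pc$estimate) - 1) * 100)
  expect_false("(Intercept)" %in% pc$term)
  # beta = ln 2 -> +100 %; beta = -0.105 -> -9.97 %; beta = 0 -> 0 %
  expect_equal((exp(log(2)) - 1) * 100, 100)
  expect_equal((exp(-0.105) - 1) * 100, -9.9676, tolerance = 1e-4)

  lin <- fit_metric_model(d, "y", link = "linear", candidate_terms = "x")
  pl <- coefficients_as_percent_change(lin)
  expect_equal(pl$unit, "response units")
  expect_equal(pl$effect, pl$estimate)
})

test_that("log links refuse non-positive responses after the sign convention", {
  d <- data.frame(x = 1:6, y = c(2, 3, 0, 4, 5, 6))
  expect_error(fit_metric_model(d, "y", link = "log",
                                candidate_terms = "x"),
               "strictly positive")
})
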