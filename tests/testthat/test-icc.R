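test_that("perfect consistency yields ICC = 1 with MS_E = 0", {
  m <- matrix(rep(c(1, 3, 5, 2, 4), 4), ncol = 4)
  res <- icc_inter(m)
  expect_equal(res$icc, 1)
  expect_equal(res$anova$ms_error, 0)
  expect_equal(res$p_value, 0)
})

test_that("a constant reader shift leaves consistency ICC at 1 but lowers agreement", {
  base <- c(1, 3, 5, 2, 4, 3, 1, 5)
  m <- cbind(base, base + 1, base - 1)
  expect_equal(icc_inter(m)$icc, 1)
  intra <- icc_intra(m)
  expect_lt(intra$icc, 1)
  expect_gt(intra$icc, 0)
})

test_that("ICC(C,k) is invariant to arbitrary per-reader constant shifts", {
  set.seed(8)
  m <- matrix(rnorm(60, 3, 1), 20, 3) + rep(rnorm(20, 0, 2), 3)
  shifted <- sweep(m, 2, c(10, -4, 0.5), `+`)
  expect_equal(icc_inter(shifted)$icc, icc_inter(m)$icc, tolerance = 1e-12)
  # while agreement strictly decreases under a nonzero shift
  one_shift <- m; one_shift[, 2] <- one_shift[, 2] + 2
  expect_lt(icc_intra(one_shift)$icc, icc_intra(m)$icc)
})

test_that("identical repeated readings give intra-reader ICC = 1", {
  base <- c(2, 4, 1, 5, 3, 2, 4)
  expect_equal(icc_intra(cbind(base, base))$icc, 1)
})

test_that("ICC agrees with the mean-square definitions on a worked example", {
  # hand-decomposable 4 x 2 layout
  m <- matrix(c(9, 2, 5, 8,
                6, 1, 3, 2), ncol = 2)
  a <- metartiq:::anova_decomposition(m)
  n <- 4; k <- 2
  grand <- mean(m)
  expect_equal(a$ms_rows, k * sum((rowMeans(m) - grand)^2) / (n - 1))
  expect_equal(a$ms_cols, n * sum((colMeans(m) - grand)^2) / (k - 1))
  expect_equal(icc_inter(m)$icc, (a$ms_rows - a$ms_error) / a$ms_rows)
  expect_equal(icc_intra(m)$icc,
               (a$ms_rows - a$ms_error) /
                 (a$ms_rows + (a$ms_cols - a$ms_error) / n))
})

test_that("simulated matrices with known variance components are recovered", {
  # continuous two-way random model: subject sd 2, error sd 1, k = 5
  set.seed(12)
  n <- 200; k <- 5
  target1 <- 4 / (4 + 1)
  target_k <- k * target1 / (1 + (k - 1) * target1)
  m <- rep(rnorm(n, 0, 2), k) + rnorm(n * k, 0, 1) +
    rep(rnorm(k, 0, 0.5), each = n)
  dim(m) <- c(n, k)
  est <- icc_inter(m)
  expect_lt(abs(est$icc - target_k), 0.05)
  expect_true(est$ci_low < target_k && target_k < est$ci_high)
  # absolute agreement target includes the rater variance component
  target_a <- 4 / (4 + (0.5^2 + 1) / 1)
  target_ak <- k * target_a / (1 + (k - 1) * target_a)
  expect_lt(abs(icc_intra(m)$icc - target_ak), 0.07)
})

test_that("degenerate and malformed inputs are handled explicitly", {
  flat <- matrix(3, 10, 4)
  res <- icc_inter(flat)
  expect_true(res$degenerate)
  expect_equal(res$icc, 0)
  expect_error(icc_inter(matrix(c(1, NA, 2, 3), 2)), "complete")
  expect_error(icc_inter(matrix(1:4, 4, 1)), "at least 2")
})
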