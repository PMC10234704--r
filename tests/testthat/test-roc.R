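test_that("empirical AUC handles separation, ties, and matches brute force", {
  expect_equal(empirical_auc(c(2, 2, 2), c(0, 0))$auc, 1.0)
  expect_equal(empirical_auc(rep(1, 4), rep(1, 5))$auc, 0.5)
  cases <- c(3, 1, 4, 1, 5)
  controls <- c(2, 7, 1, 8, 2)
  expect_equal(empirical_auc(cases, controls)$auc,
               oracle_auc_bruteforce(cases, controls))
  expect_error(empirical_auc(numeric(0), 1), "non-empty")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(21)
  for (i in 1:20) {
    x <- sample(-1:8, 30, replace = TRUE)
    y <- sample(-1:8, 40, replace = TRUE)
    a <- empirical_auc(x, y)$auc
    expect_equal(empirical_auc(2 * x + 1, 2 * y + 1)$auc, a)
    expect_equal(empirical_auc(exp(x), exp(y))$auc, a)
  }
})

test_that("ROC points bracket (0,0)-(1,1) and integrate back to the AUC", {
  set.seed(22)
  for (i in 1:100) {
    x <- sample(0:5, sample(2:10, 1), replace = TRUE)
    y <- sample(0:5, sample(2:10, 1), replace = TRUE)
    pts <- roc_points(x, y)
    expect_equal(c(pts$fpr[1], pts$tpr[1]), c(0, 0))
    expect_equal(c(pts$fpr[nrow(pts)], pts$tpr[nrow(pts)]), c(1, 1))
    expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
    expect_equal(roc_auc_trapezoid(pts), empirical_auc(x, y)$auc, tolerance = 1e-12)
  }
  # integer scores on the RIPP support: at most 11 interior points
  x <- sample(-1:8, 200, replace = TRUE)
  y <- sample(-1:8, 200, replace = TRUE)
  expect_lte(nrow(roc_points(x, y)) - 2L, 11L)
  # perfect separation passes through (0, 1)
  pts <- roc_points(c(5, 6), c(1, 2))
  expect_true(any(pts$fpr == 0 & pts$tpr == 1))
})

test_that("a tool compared with itself has zero difference, variance and full p", {
  set.seed(23)
  s <- rnorm(100)
  labels <- rep(c("case", "control"), 50)
  cmp <- delong_compare(s, s, labels)
  expect_equal(cmp$difference, 0)
  expect_equal(cmp$variance, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("zero variance with nonzero difference is flagged as degenerate", {
  labels <- c("case", "case", "control", "control")
  a <- c(1, 1, 0, 0)
  b <- c(0, 0, 1, 1)
  expect_warning(cmp <- delong_compare(a, b, labels), "zero DeLong variance")
  expect_equal(cmp$p_value, 0)
  expect_true(cmp$degenerate)
})

test_that("independent score columns have near-zero component covariance", {
  set.seed(24)
  n <- 2000
  labels <- rep(c("case", "control"), each = n)
  a <- c(rnorm(n, 0.8), rnorm(n))
  b <- c(rnorm(n, 0.8), rnorm(n))  # independent of a by construction
  cmp <- delong_compare(a, b, labels)
  va <- empirical_auc(a[labels == "case"], a[labels == "control"])$variance
  vb <- empirical_auc(b[labels == "case"], b[labels == "control"])$variance
  # with zero covariance the paired variance approaches the sum of singles
  expect_equal(cmp$variance, va + vb, tolerance = 0.1)
})

test_that("delong_compare enforces the paired design", {
  expect_error(delong_compare(1:4, 1:3, rep("case", 4)), "unpaired")
  expect_error(delong_compare(1:4, 1:4, rep("case", 4)), "non-empty")
})

test_that("the pairwise AUC table labels both operands explicitly", {
  cohort <- generate_cohort(generator_config(n_cases = 120L, n_controls = 120L, seed = 3L))
  scores <- score_cohort(cohort)
  tab <- auc_comparison_table(scores)
  expect_setequal(tab$tool, c("addrs", "lovy", "aortas", "von_kodolitsch"))
  expect_equal(tab$difference, tab$auc_baseline - tab$auc_tool)
  expect_true(all(tab$ci_low <= tab$difference & tab$difference <= tab$ci_high))
})
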