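test_that("AUC matches hand-computable cases", {
  expect_equal(roc_curve(c(3, 4), c(1, 2))$auc, 1.0)
  expect_equal(roc_curve(c(1, 2), c(1, 2))$auc, 0.5)
  expect_equal(roc_curve(c(2, 3, 5), c(1, 2, 4))$auc, 6.5 / 9)
  expect_error(roc_curve(numeric(0), 1:3), "at least one")
})

test_that("AUC equals the brute-force pairwise statistic on random instances", {
  set.seed(401)
  for (i in 1:40) {
    n1 <- sample(1:50, 1)
    n2 <- sample(1:50, 1)
    # integer draws force heavy ties in about half the instances
    cases <- if (i %% 2) rnorm(n1) else sample(0:5, n1, replace = TRUE)
    controls <- if (i %% 2) rnorm(n2, 0.5) else sample(0:5, n2, replace = TRUE)
    expect_equal(roc_curve(cases, controls)$auc,
                 auc_bruteforce(cases, controls))
  }
})

test_that("orientation symmetry holds on tie-free data", {
  set.seed(402)
  cases <- rnorm(17); controls <- rnorm(23)
  a_hi <- roc_curve(cases, controls, "higher_positive")$auc
  a_lo <- roc_curve(cases, controls, "lower_positive")$auc
  expect_equal(a_hi + a_lo, 1)
})

test_that("ROC curve spans (0,0) to (1,1) with monotone coordinates", {
  set.seed(403)
  rc <- roc_curve(rnorm(15, 1), rnorm(20))
  fpr <- 1 - rc$specificity
  expect_equal(c(rc$sensitivity[1], fpr[1]), c(1, 1))
  expect_equal(c(rev(rc$sensitivity)[1], rev(fpr)[1]), c(0, 0))
  expect_true(all(diff(rc$sensitivity) <= 0))
  expect_true(all(diff(fpr) <= 0))
})

test_that("direction inference follows the AUC orientation with ties up", {
  set.seed(404)
  expect_equal(infer_direction(rnorm(30, 2), rnorm(30)), "up")
  expect_equal(infer_direction(rnorm(30, -2), rnorm(30)), "down")
  expect_equal(infer_direction(c(1, 2), c(1, 2)), "up")
})

test_that("constrained cut-off selection maximizes sensitivity above the floor", {
  rc <- roc_curve(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 10))
  op <- select_cutoff_at_specificity(rc, 0.80)
  expect_equal(op, list(threshold = 5, sensitivity = 1.0, specificity = 0.8))

  # perfectly separated classes
  rc2 <- roc_curve(c(10, 11), c(1, 2))
  op2 <- select_cutoff_at_specificity(rc2, 0.80)
  expect_equal(c(op2$sensitivity, op2$specificity), c(1, 1))

  # with 5 controls and a 0.80 floor, at most one control may be positive
  expect_lte(round((1 - op$specificity) * 5), 1)

  expect_error(select_cutoff_at_specificity(rc, 1.2), "min_specificity")
})

test_that("selection agrees with exhaustive enumeration and respects the floor", {
  set.seed(405)
  for (i in 1:30) {
    orient <- if (i %% 2) "higher_positive" else "lower_positive"
    cases <- sample(0:8, sample(3:25, 1), replace = TRUE)
    controls <- sample(0:8, sample(3:25, 1), replace = TRUE)
    floor_s <- sample(c(0.6, 0.8, 0.9), 1)
    rc <- roc_curve(cases, controls, orient)
    oracle <- cutoff_enumeration(cases, controls, floor_s, orient)
    if (is.null(oracle)) {
      expect_warning(op <- select_cutoff_at_specificity(rc, floor_s),
                     "all-negative")
      expect_equal(c(op$sensitivity, op$specificity), c(0, 1))
    } else {
      op <- select_cutoff_at_specificity(rc, floor_s)
      expect_equal(op, oracle)
      expect_gte(op$specificity, floor_s)
    }
  }
})

test_that("expected AUC is 0.5 under random relabeling", {
  set.seed(406)
  x <- rnorm(40)
  aucs <- replicate(400, {
    lab <- sample(rep(c(TRUE, FALSE), each = 20))
    roc_curve(x[lab], x[!lab])$auc
  })
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 1e-12)
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(407)
  for (i in 1:5) {
    cases <- sample(seq(0, 3, by = 0.5), 15, replace = TRUE)
    controls <- sample(seq(0, 3, by = 0.5), 20, replace = TRUE)
    ref <- suppressMessages(pROC::auc(
      pROC::roc(controls = controls, cases = cases, direction = "<")))
    expect_equal(roc_curve(cases, controls)$auc, as.numeric(ref))
  }
})
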