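test_that("binarization applies the asymmetric boundary rule", {
  panel <- default_panel()
  aim2_cut <- panel$cutoff[panel$gene == "AIM2"]    # up-regulated
  pgap3_cut <- panel$cutoff[panel$gene == "PGAP3"]  # down-regulated

  expr <- matrix(1, nrow = 2, ncol = 12, dimnames = list(c("a", "b"), panel$gene))
  expr[, "AIM2"] <- c(aim2_cut, aim2_cut - 1e-9)
  expr[, "PGAP3"] <- c(pgap3_cut, pgap3_cut - 1e-9)
  bits <- binarize(expr, panel)
  # up-gene: value equal to the cut-off scores 1 (inclusive >=)
  expect_equal(unname(bits[, "AIM2"]), c(1L, 0L))
  # down-gene: value equal to the cut-off scores 0 (strict <)
  expect_equal(unname(bits[, "PGAP3"]), c(0L, 1L))
})

test_that("extreme expression saturates the score at 0 and 12", {
  panel <- default_panel()
  hi <- ifelse(panel$direction == "up", 1e6, 1e-6)  # everything fires
  lo <- ifelse(panel$direction == "up", 1e-6, 1e6)  # nothing fires
  expr <- make_expr(rbind(hi, lo), panel$gene, c("all", "none"))
  s <- composite_score(binarize(expr, panel))
  expect_equal(unname(s), c(12L, 0L), ignore_attr = TRUE)
})

test_that("composite score sums indicator bits", {
  bits <- matrix(rep(c(1L, 0L), 6), nrow = 1,
                 dimnames = list("p", paste0("g", 1:12)))
  expect_equal(unname(composite_score(bits)), 6L)
  set.seed(501)
  b <- matrix(rbinom(120, 1, 0.4), 10, 12)
  expect_equal(unname(composite_score(b)), as.integer(rowSums(b)))
  # score conservation: total score mass equals the sum of per-gene means x n
  expect_equal(sum(composite_score(b)), sum(colMeans(b)) * nrow(b))
})

test_that("patients missing a panel gene are excluded and reported", {
  panel <- default_panel()
  expr <- make_expr(matrix(1, 3, 12), panel$gene)
  expr[2, "FASN"] <- NA
  bits <- binarize(expr, panel)
  expect_equal(attr(bits, "excluded"), "P2")
  expect_equal(rownames(bits), c("P1", "P3"))
  expect_error(binarize(expr[, -1], panel), "lacks panel gene")
})

test_that("Poisson-binomial DP matches full enumeration and closed forms", {
  expect_equal(unname(poisson_binomial(rep(0, 5))$pmf), c(1, rep(0, 5)))
  expect_equal(unname(poisson_binomial(rep(1, 12))$pmf), c(rep(0, 12), 1))
  expect_error(poisson_binomial(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(502)
  p12 <- runif(12)
  expect_equal(unname(poisson_binomial(p12)$pmf), pmf_enumeration(p12),
               tolerance = 1e-12)
  expect_equal(sum(poisson_binomial(p12)$pmf), 1, tolerance = 1e-12)

  # binomial special case
  expect_equal(unname(poisson_binomial(rep(0.3, 7))$pmf), dbinom(0:7, 7, 0.3))
})

test_that("DP tail probability matches Monte Carlo within 3 sigma", {
  rates <- derive_positivity_rates(default_panel(), "complement")
  p <- rates$rate_resistant
  d <- poisson_binomial(p)
  exact <- sum(d$pmf[as.integer(names(d$pmf)) >= 9])
  set.seed(503)
  n_mc <- 1e5
  draws <- colSums(matrix(runif(n_mc * 12) < p, nrow = 12))
  mc <- mean(draws >= 9)
  se <- sqrt(exact * (1 - exact) / n_mc)
  expect_lt(abs(mc - exact), 3 * se)
})

test_that("independence-model expected scores equal the panel column sums", {
  rates <- derive_positivity_rates(default_panel(), "complement")
  expect_equal(sum(rates$rate_resistant), 8.422, tolerance = 1e-3)
  expect_equal(sum(rates$rate_sensitive), 6.528, tolerance = 1e-3)
  # pmf means agree with the rate sums exactly
  for (r in list(rates$rate_resistant, rates$rate_sensitive)) {
    d <- poisson_binomial(r)
    expect_equal(sum(d$pmf * 0:12), sum(r), tolerance = 1e-12)
  }
})

test_that("augmenting the panel shifts the score distributions predictably", {
  # NOTE: a weakly informative extra gene can *decrease* the independence-model
  # AUC (its noise blurs the score), so the guaranteed gains are on the mean
  # separation, and on the AUC only for a perfect added marker.
  set.seed(504)
  for (i in 1:20) {
    k <- sample(3:11, 1)
    p_res <- runif(k); p_sen <- runif(k)
    pmf_res <- poisson_binomial(p_res)$pmf
    pmf_sen <- poisson_binomial(p_sen)$pmf
    base_auc <- auc_from_pmfs(pmf_res, pmf_sen)
    extra_sen <- runif(1, 0, 0.9)
    extra_res <- runif(1, extra_sen, 1)  # rate_resistant > rate_sensitive

    mean_of <- function(pmf) sum(pmf * (seq_along(pmf) - 1))
    aug_res <- poisson_binomial(c(p_res, extra_res))$pmf
    aug_sen <- poisson_binomial(c(p_sen, extra_sen))$pmf
    gap_gain <- (mean_of(aug_res) - mean_of(aug_sen)) -
      (mean_of(pmf_res) - mean_of(pmf_sen))
    expect_equal(gap_gain, extra_res - extra_sen, tolerance = 1e-12)

    perfect_auc <- auc_from_pmfs(poisson_binomial(c(p_res, 1))$pmf,
                                 poisson_binomial(c(p_sen, 0))$pmf)
    expect_gte(perfect_auc + 1e-12, base_auc)
  }
})

test_that("score classifier reports ROC-consistent operating points", {
  scores <- c(rep(12L, 5), rep(0L, 8))
  labels <- c(rep(TRUE, 5), rep(FALSE, 8))
  sc <- score_classifier(scores, labels, 0.8)
  expect_equal(c(sc$cutoff, sc$sensitivity, sc$specificity, sc$auc),
               c(12, 1, 1, 1))
  expect_error(score_classifier(scores, rep(TRUE, 13)), "both classes")

  # a legacy real-valued cut-off of 8.8 means positivity at score >= 9
  set.seed(505)
  s <- sample(0:12, 60, replace = TRUE)
  lab <- rep(c(TRUE, FALSE), 30)
  sc2 <- score_classifier(s, lab, legacy_cutoff = 8.8)
  expect_equal(sc2$cutoff, 9)
  expect_equal(sc2$sensitivity, mean(s[lab] >= 9))
  expect_equal(sc2$specificity, mean(s[!lab] < 9))
})

test_that("empirical score AUC matches the closed-form pmf AUC within 3 sigma", {
  rates <- derive_positivity_rates(default_panel(), "complement")
  pmf_res <- poisson_binomial(rates$rate_resistant)$pmf
  pmf_sen <- poisson_binomial(rates$rate_sensitive)$pmf
  theo <- auc_from_pmfs(pmf_res, pmf_sen)

  set.seed(506)
  n <- 2000
  s_res <- colSums(matrix(runif(n * 12) < rates$rate_resistant, nrow = 12))
  s_sen <- colSums(matrix(runif(n * 12) < rates$rate_sensitive, nrow = 12))
  emp <- score_classifier(c(s_res, s_sen),
                          rep(c(TRUE, FALSE), each = n))$auc
  # conservative SE bound for an AUC of a Mann-Whitney statistic
  se <- sqrt(theo * (1 - theo) * (2 * n + 1) / (n * n))
  expect_lt(abs(emp - theo), 3 * se)
})
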