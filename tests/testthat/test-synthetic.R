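test_that("probit calibration is exact in closed form", {
  panel <- default_panel()
  rates <- derive_positivity_rates(panel)
  model <- calibrate_gene_model(panel, rates, loading = 0)
  # analytic firing probabilities reproduce the targets to 1e-10
  expect_equal(1 - pnorm(model$latent_threshold), rates$rate_sensitive,
               tolerance = 1e-10)
  expect_equal(1 - pnorm(model$latent_threshold - model$shift),
               rates$rate_resistant, tolerance = 1e-10)
  # frozen probit identities for the rate pair (0.844, 0.200)
  one <- calibrate_gene_model(
    panel_spec("G", 1, 0.844, 0.200, 0.8),
    data.frame(gene = "G", direction = "up",
               rate_resistant = 0.844, rate_sensitive = 0.200))
  expect_equal(one$latent_threshold, -qnorm(0.200))
  expect_equal(one$shift, qnorm(0.844) - qnorm(0.200))
})

test_that("degenerate rates become point masses with a warning", {
  perfect <- panel_spec("X", 2, 1.0, 0.0, 0.99)
  rates <- derive_positivity_rates(perfect)
  expect_warning(model <- calibrate_gene_model(perfect, rates), "point mass")
  expect_true(model$degenerate)
  cfg <- generator_config(n_sensitive = 50, n_resistant = 50, seed = 1)
  co <- generate_cohort(cfg, panel = perfect)
  bits <- binarize(co$expression, perfect)
  expect_true(all(bits[co$labels, ] == 1L))
  expect_true(all(bits[!co$labels, ] == 0L))
  expect_true(all(co$expression > 0))
})

test_that("generation is byte-identical given the seed", {
  cfg <- generator_config(seed = 20260920)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$covariates, b$covariates)
  c2 <- generate_cohort(generator_config(seed = 20260921))
  expect_false(identical(a$expression, c2$expression))
})

test_that("default cohort matches the pooled study layout", {
  co <- generate_cohort(generator_config(seed = 7))
  expect_equal(nrow(co$covariates), 47)
  expect_equal(sum(co$labels), 16)
  expect_equal(sum(!co$labels), 31)
  expect_true(all(co$expression > 0))
  cs <- covariate_spec()
  for (g in c("sensitive", "resistant")) {
    rows <- co$covariates[co$covariates$group == g, ]
    expect_true(all(rows$age >= cs[[g]]$age["min"] &
                    rows$age <= cs[[g]]$age["max"]))
    expect_true(all(rows$edss_prior %% 0.5 == 0))
    expect_true(all(rows$gc_dose_mg >= cs[[g]]$dose["min"] &
                    rows$gc_dose_mg <= cs[[g]]$dose["max"]))
    expect_true(all(rows$immunotherapy %in% c("none", "mild_moderate", "high")))
  }
  expect_error(generator_config(n_sensitive = 0), ">= 1")
  expect_error(generator_config(loading = 1), "\\[0, 1\\)")
})

test_that("sampled female fraction matches the target within binomial error", {
  co <- generate_cohort(generator_config(n_sensitive = 2000, n_resistant = 2000,
                                         seed = 8))
  cs <- covariate_spec()
  for (g in c("sensitive", "resistant")) {
    f <- mean(co$covariates$sex[co$covariates$group == g] == "F")
    target <- cs[[g]]$female  # 25/34 and 12/16
    expect_lt(abs(f - target), 3 * sqrt(target * (1 - target) / 2000))
  }
})

test_that("indicators are near-independent at zero loading", {
  co <- generate_cohort(generator_config(n_sensitive = 5000, n_resistant = 5000,
                                         loading = 0, seed = 9))
  bits <- binarize(co$expression, default_panel())
  r <- cor(bits[co$labels, ])
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)
})

test_that("within-group score variance is non-decreasing in the loading", {
  vars <- vapply(c(0, 0.3, 0.6, 0.9), function(lam) {
    co <- generate_cohort(generator_config(n_sensitive = 5000, n_resistant = 5000,
                                           loading = lam, seed = 10))
    s <- composite_score(binarize(co$expression, default_panel()))
    var(s[co$labels])
  }, numeric(1))
  expect_true(all(diff(vars) > 0))
})

test_that("covariate spec validation catches inconsistent marginals", {
  cs <- covariate_spec()
  cs$sensitive$age["mean"] <- 200
  expect_error(generate_cohort(generator_config(), covspec = cs),
               "min <= mean <= max")
  cs2 <- covariate_spec()
  cs2$resistant$immunotherapy <- c(none = 0.5, mild_moderate = 0.4, high = 0.4)
  expect_error(generate_cohort(generator_config(), covspec = cs2), "sum to 1")
})

test_that("cohort CSV export round-trips", {
  co <- generate_cohort(generator_config(seed = 12))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_equal(read_expression_matrix(paths["expression"]), co$expression,
               tolerance = 1e-13)
  cov <- utils::read.csv(paths["covariates"], stringsAsFactors = FALSE)
  expect_equal(cov$patient_id, co$covariates$patient_id)
})
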