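#' Pearson chi-square test on a contingency table
#'
#' Pearson chi-square without continuity correction (the convention used for
#' the cohort's baseline comparisons), df = (r-1)(c-1), p-value from the
#' upper tail of the chi-square distribution.
#'
#' @param counts integer matrix of counts, at least 2x2 (rows = groups,
#'   columns = categories).
#' @return A list with `statistic`, `df`, `p_value`.
#' @examples
#' chi_square_test(matrix(c(25, 12, 9, 4), nrow = 2))  # p ~ 0.91
#' @export
chi_square_test <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) stop("table must be at least 2x2")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  zero_row <- which(rowSums(counts) == 0)
  zero_col <- which(colSums(counts) == 0)
  if (length(zero_row) > 0) {
    stop("degenerate margin: row(s) ", paste(zero_row, collapse = ", "),
         " have zero total")
  }
  if (length(zero_col) > 0) {
    stop("degenerate margin: column(s) ", paste(zero_col, collapse = ", "),
         " have zero total")
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples. The exact distribution is
#' enumerated when the combined sample size is at most 12 and there are no
#' ties; otherwise the tie-corrected normal approximation is used. U is the
#' number of (x, y) pairs with x > y, counting ties as 1/2, so
#' U(x, y) + U(y, x) = n_x * n_y.
#'
#' @param x,y numeric samples.
#' @return A list with `u`, `p_value`, `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) + length(y)) <= 12
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE)
  )
  list(u = unname(res$statistic), p_value = unname(res$p.value),
       method = if (exact) "exact" else "normal approximation, tie-corrected")
}

#' Confounder-adjusted logistic regression
#'
#' Fits a binary-outcome logistic regression by maximum likelihood (IRLS,
#' via [stats::glm()]) and reports, per predictor, the coefficient, odds
#' ratio, Wald 95% confidence interval and Wald p-value — the reporting
#' layout of a clinical odds-ratio table.
#'
#' Encoding contract (fixed so fits are reproducible): the outcome is
#' GC-resistant = 1; sex enters as female = 1; immunotherapy as a single
#' ordinal covariate 0/1/2 (none / mild-to-moderate / high efficacy);
#' center as a 0/1 indicator. Perfect or quasi-perfect separation and
#' collinear (aliased) predictors are diagnosed explicitly, never returned
#' silently.
#'
#' @param data data frame holding outcome and predictors.
#' @param outcome name of the binary outcome column (logical or 0/1).
#' @param predictors character vector of predictor column names.
#' @return A list of class `logistic_fit`: `table` (data frame with
#'   `predictor`, `coef`, `odds_ratio`, `ci_lower`, `ci_upper`, `p_value`),
#'   `converged`, `separation`, `n`, `loglik`, and the underlying `model`.
#' @export
fit_logistic <- function(data, outcome, predictors) {
  stopifnot(is.data.frame(data), outcome %in% names(data),
            all(predictors %in% names(data)))
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary (0/1 or logical)")
  if (length(unique(y)) < 2) stop("outcome has a single level")
  X <- data[, predictors, drop = FALSE]
  const <- vapply(X, function(v) length(unique(v)) < 2, logical(1))
  if (any(const)) {
    stop("constant predictor(s): ", paste(predictors[const], collapse = ", "))
  }
  if (nrow(X) <= length(predictors) + 1) {
    stop("more predictors than the sample size supports")
  }
  df <- cbind(.outcome = y, X)
  form <- stats::as.formula(paste(".outcome ~", paste(predictors, collapse = " + ")))

  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear predictor(s) aliased in the design: ",
         paste(aliased, collapse = ", "))
  }
  co <- summary(fit)$coefficients
  keep <- rownames(co) != "(Intercept)"
  z <- stats::qnorm(0.975)
  tab <- data.frame(
    predictor = rownames(co)[keep],
    coef = co[keep, "Estimate"],
    odds_ratio = exp(co[keep, "Estimate"]),
    ci_lower = exp(co[keep, "Estimate"] - z * co[keep, "Std. Error"]),
    ci_upper = exp(co[keep, "Estimate"] + z * co[keep, "Std. Error"]),
    p_value = co[keep, "Pr(>|z|)"],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  out <- list(table = tab, converged = fit$converged, separation = separation,
              n = nrow(X), loglik = as.numeric(stats::logLik(fit)), model = fit)
  class(out) <- "logistic_fit"
  if (separation) {
    warning("(quasi-)perfect separation detected; Wald intervals unreliable")
  }
  if (!fit$converged) warning("IRLS did not converge")
  out
}

#' @export
print.logistic_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Logistic regression (n = %d, logLik = %.2f%s)\n", x$n, x$loglik,
              if (x$separation) ", SEPARATION" else ""))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) signif(v, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Baseline group comparisons for a cohort table
#'
#' Compares GC-sensitive and GC-resistant patients on the standard baseline
#' variables: chi-square (no continuity correction) for sex, immunotherapy
#' class and center; Mann-Whitney U for age, disease duration, EDSS before
#' and after GC, and GC dose. Expects the covariate layout produced by
#' [generate_cohort()].
#'
#' @param covariates covariate data frame with a `group` column
#'   (`"sensitive"` / `"resistant"`).
#' @return A data frame with `variable`, `test`, `statistic`, `p_value`.
#' @export
baseline_comparisons <- function(covariates) {
  stopifnot("group" %in% names(covariates))
  res_mask <- covariates$group == "resistant"
  out <- list()

  cat_vars <- intersect(c("sex", "immunotherapy", "center"), names(covariates))
  for (v in cat_vars) {
    tab <- table(covariates$group, covariates[[v]])
    ok <- tryCatch({
      ct <- chi_square_test(as.matrix(tab))
      out[[v]] <- data.frame(variable = v, test = "chi-square",
                             statistic = ct$statistic, p_value = ct$p_value)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      out[[v]] <- data.frame(variable = v, test = "chi-square",
                             statistic = NA_real_, p_value = NA_real_)
    }
  }
  num_vars <- intersect(
    c("age", "disease_duration", "edss_prior", "edss_post", "gc_dose_mg"),
    names(covariates))
  for (v in num_vars) {
    mw <- mann_whitney_u(covariates[[v]][res_mask], covariates[[v]][!res_mask])
    out[[v]] <- data.frame(variable = v, test = "Mann-Whitney U",
                           statistic = mw$u, p_value = mw$p_value)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
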