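#' Generator configuration for synthetic cohorts
#'
#' @param n_sensitive,n_resistant group sizes; defaults are the pooled
#'   qPCR cohort (31 GC-sensitive, 16 GC-resistant, 47 in total).
#' @param loading shared latent-factor loading lambda in \[0, 1): 0 gives
#'   independent gene indicators within a patient, larger values induce
#'   positive correlation between panel genes (co-regulation / shared
#'   blood-composition drivers).
#' @param seed integer RNG seed; recorded in every downstream report.
#' @param rate_interpretation how printed operating points map to indicator
#'   firing rates; see [derive_positivity_rates()].
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_sensitive = 31, n_resistant = 16,
                             loading = 0.3, seed = 1,
                             rate_interpretation = c("complement", "as_printed")) {
  rate_interpretation <- match.arg(rate_interpretation)
  if (n_sensitive < 1 || n_resistant < 1) stop("group sizes must be >= 1")
  if (!is.numeric(loading) || loading < 0 || loading >= 1) {
    stop("loading must lie in [0, 1)")
  }
  structure(
    list(n_sensitive = as.integer(n_sensitive),
         n_resistant = as.integer(n_resistant),
         loading = loading, seed = as.integer(seed),
         rate_interpretation = rate_interpretation),
    class = "generator_config"
  )
}

#' Covariate distributions of the relapse groups
#'
#' Per-group marginal distributions used to sample clinical covariates:
#' age and disease duration as truncated normals matching a printed
#' mean/min/max; EDSS on a 0.5-step grid matching median/min/max; GC dose
#' as a truncated normal (mg); sex, immunotherapy class and recruitment
#' center as categorical draws. Defaults reproduce the pooled two-center
#' relapse cohort's baseline table (GC-sensitive n = 34 / GC-resistant
#' n = 16 marginals; Bern-vs-Athens composition of the 47-patient qPCR
#' cohort). No covariate-expression dependence is induced.
#'
#' @return A list of class `covariate_spec` with elements `sensitive` and
#'   `resistant`, each holding the group's marginal parameters.
#' @export
covariate_spec <- function() {
  grp <- function(age, female, duration, edss_prior, edss_post, dose,
                  immunotherapy, p_bern) {
    list(age = age, female = female, duration = duration,
         edss_prior = edss_prior, edss_post = edss_post, dose = dose,
         immunotherapy = immunotherapy, p_bern = p_bern)
  }
  spec <- list(
    sensitive = grp(
      age = c(mean = 35.3, min = 18, max = 64),
      female = 25 / 34,
      duration = c(mean = 4.1, min = 0, max = 19),
      edss_prior = c(median = 2.5, min = 1.0, max = 6.0),
      edss_post = c(median = 1.5, min = 0.0, max = 5.0),
      dose = c(mean = 4956, min = 1500, max = 13000),
      immunotherapy = c(none = 18, mild_moderate = 10, high = 6) / 34,
      p_bern = 10 / 31
    ),
    resistant = grp(
      age = c(mean = 34.8, min = 23, max = 57),
      female = 12 / 16,
      duration = c(mean = 1.6, min = 0, max = 13),
      edss_prior = c(median = 2.89, min = 1.5, max = 5.0),
      edss_post = c(median = 3.25, min = 1.5, max = 5.0),
      dose = c(mean = 5794, min = 1200, max = 11000),
      immunotherapy = c(none = 12, mild_moderate = 4, high = 0) / 16,
      p_bern = 15 / 16
    )
  )
  class(spec) <- "covariate_spec"
  spec
}

validate_covariate_spec <- function(spec) {
  for (g in c("sensitive", "resistant")) {
    s <- spec[[g]]
    for (v in c("age", "duration", "dose")) {
      x <- s[[v]]
      if (!(x["min"] <= x["mean"] && x["mean"] <= x["max"])) {
        stop(g, " ", v, ": need min <= mean <= max")
      }
    }
    for (v in c("edss_prior", "edss_post")) {
      x <- s[[v]]
      if (!(x["min"] <= x["median"] && x["median"] <= x["max"])) {
        stop(g, " ", v, ": need min <= median <= max")
      }
    }
    if (abs(sum(s$immunotherapy) - 1) > 1e-8) {
      stop(g, ": immunotherapy probabilities must sum to 1")
    }
    if (s$female < 0 || s$female > 1 || s$p_bern < 0 || s$p_bern > 1) {
      stop(g, ": fractions must lie in [0, 1]")
    }
  }
  invisible(spec)
}

# Inverse-CDF truncated normal draw on [lo, hi].
rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Calibrate the latent-liability gene model
#'
#' Under the single-factor Gaussian liability model
#' `X_ij = shift_j * 1[resistant_i] + lambda * L_i + sqrt(1 - lambda^2) * e_ij`
#' (with `L_i`, `e_ij` independent standard normals), each gene's indicator
#' fires when `X_ij >= latent_threshold_j`. Because the marginal variance of
#' `X` is 1 for any `lambda`, the probit calibration
#' `latent_threshold = qnorm(1 - rate_sensitive)` and
#' `shift = latent_threshold - qnorm(1 - rate_resistant)` makes the firing
#' probability equal the target rate in each group exactly, for any loading.
#' An affine map with slope `scale` (sign set by the gene's direction)
#' places the indicator boundary exactly at the published cut-off on the
#' expression-ratio scale.
#'
#' Rates of exactly 0 or 1 cannot be calibrated continuously; those genes are
#' flagged degenerate (point mass on the appropriate side of the cut-off)
#' with a warning.
#'
#' @param panel a [panel_spec()].
#' @param rates data frame from [derive_positivity_rates()].
#' @param loading shared latent loading lambda in \[0, 1).
#' @param scale slope of the latent-to-ratio affine map, in ratio units per
#'   latent SD (default 0.1, a realistic spread for Ct-ratio panels).
#' @return Data frame with columns `gene`, `direction`, `cutoff`, `shift`,
#'   `latent_threshold`, `scale`, `rate_resistant`, `rate_sensitive`,
#'   `degenerate`.
#' @export
calibrate_gene_model <- function(panel, rates = derive_positivity_rates(panel),
                                 loading = 0, scale = 0.1) {
  validate_panel_spec(panel)
  stopifnot(all(rates$gene == panel$gene))
  if (loading < 0 || loading >= 1) stop("loading must lie in [0, 1)")
  p_res <- rates$rate_resistant
  p_sen <- rates$rate_sensitive
  degenerate <- p_res %in% c(0, 1) | p_sen %in% c(0, 1)
  if (any(degenerate)) {
    warning("degenerate firing rate(s) (0 or 1) for: ",
            paste(panel$gene[degenerate], collapse = ", "),
            "; represented as point masses")
  }
  thr <- stats::qnorm(1 - p_sen)
  shift <- thr - stats::qnorm(1 - p_res)
  data.frame(
    gene = panel$gene,
    direction = panel$direction,
    cutoff = panel$cutoff,
    shift = shift,
    latent_threshold = thr,
    scale = scale,
    rate_resistant = p_res,
    rate_sensitive = p_sen,
    degenerate = degenerate,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic two-group relapse cohort
#'
#' Draws clinical covariates from the per-group marginals of a
#' [covariate_spec()] and 12-gene relative-expression values from the
#' calibrated latent-liability model, so that each gene's directional
#' indicator fires at its target rate in each group and indicators are
#' correlated within a patient through the shared loading. Output is fully
#' reproducible from the seed in `config`.
#'
#' @param config a [generator_config()].
#' @param panel a [panel_spec()]; defaults to the packaged 12-gene panel.
#' @param covspec a [covariate_spec()].
#' @return A list with `covariates` (data frame: `patient_id`, `group`,
#'   `age`, `sex`, `disease_duration`, `edss_prior`, `edss_post`,
#'   `gc_dose_mg`, `immunotherapy`, `center`), `expression` (patients x
#'   genes matrix of positive ratios), and `labels` (logical, TRUE =
#'   resistant), plus the `config` and gene `model` used.
#' @export
generate_cohort <- function(config = generator_config(),
                            panel = default_panel(),
                            covspec = covariate_spec()) {
  stopifnot(inherits(config, "generator_config"))
  validate_covariate_spec(covspec)
  rates <- derive_positivity_rates(panel, config$rate_interpretation)
  model <- withCallingHandlers(
    calibrate_gene_model(panel, rates, loading = config$loading),
    warning = function(w) invokeRestart("muffleWarning")
  )

  set.seed(config$seed)
  n <- config$n_sensitive + config$n_resistant
  group <- rep(c("sensitive", "resistant"),
               c(config$n_sensitive, config$n_resistant))
  ids <- sprintf("P%04d", seq_len(n))

  covariates <- do.call(rbind, lapply(c("sensitive", "resistant"), function(g) {
    s <- covspec[[g]]
    m <- sum(group == g)
    sd4 <- function(x) (x["max"] - x["min"]) / 4
    edss <- function(x) {
      raw <- rtruncnorm(m, x["median"], sd4(x), x["min"], x["max"])
      pmin(pmax(round(raw * 2) / 2, ceiling(x["min"] * 2) / 2),
           floor(x["max"] * 2) / 2)
    }
    data.frame(
      group = g,
      age = rtruncnorm(m, s$age["mean"], sd4(s$age), s$age["min"], s$age["max"]),
      sex = ifelse(stats::runif(m) < s$female, "F", "M"),
      disease_duration = rtruncnorm(m, s$duration["mean"], sd4(s$duration),
                                    s$duration["min"], s$duration["max"]),
      edss_prior = edss(s$edss_prior),
      edss_post = edss(s$edss_post),
      gc_dose_mg = rtruncnorm(m, s$dose["mean"], sd4(s$dose),
                              s$dose["min"], s$dose["max"]),
      immunotherapy = sample(names(s$immunotherapy), m, replace = TRUE,
                             prob = s$immunotherapy),
      center = ifelse(stats::runif(m) < s$p_bern, "bern", "athens"),
      stringsAsFactors = FALSE
    )
  }))
  covariates <- cbind(patient_id = ids, covariates, stringsAsFactors = FALSE)
  rownames(covariates) <- NULL

  lambda <- config$loading
  L <- stats::rnorm(n)
  expr <- matrix(NA_real_, nrow = n, ncol = nrow(model),
                 dimnames = list(ids, model$gene))
  is_res <- group == "resistant"
  for (j in seq_len(nrow(model))) {
    # group-specific latent threshold u = qnorm(1 - p); equivalent to the
    # shift/threshold parametrization (x - t = x0 - u) but finite-safe when
    # one group's rate is degenerate
    p <- ifelse(is_res, model$rate_resistant[j], model$rate_sensitive[j])
    x0 <- lambda * L + sqrt(1 - lambda^2) * stats::rnorm(n)
    u <- stats::qnorm(1 - p)
    sgn <- if (model$direction[j] == "up") 1 else -1
    point_mass <- p %in% c(0, 1)
    dev <- ifelse(point_mass,
                  ifelse((p == 1) == (model$direction[j] == "up"), 1, -1) * sgn,
                  x0 - u)
    expr[, j] <- model$cutoff[j] + sgn * model$scale[j] * dev
    # ratios are physically positive; clamp far tails without crossing cutoff
    expr[, j] <- pmax(expr[, j], model$cutoff[j] * 1e-6)
  }

  list(covariates = covariates, expression = expr,
       labels = stats::setNames(is_res, ids),
       config = config, model = model)
}

#' Write a synthetic cohort to CSV files
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written (`covariates.csv`, `expression.csv`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cov_path <- file.path(dir, "covariates.csv")
  expr_path <- file.path(dir, "expression.csv")
  utils::write.csv(cohort$covariates, cov_path, row.names = FALSE, quote = FALSE)
  write_expression_matrix(cohort$expression, expr_path)
  invisible(c(covariates = cov_path, expression = expr_path))
}
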