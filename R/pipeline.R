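#' End-to-end run configuration
#'
#' @param input `"synthetic"` (simulate a cohort) or `"csv"` (load one).
#' @param generator a [generator_config()] (synthetic mode).
#' @param covariates_csv,expression_csv input paths (csv mode): covariate
#'   table and a wide relative-expression matrix.
#' @param panel a [panel_spec()]; defaults to the packaged 12-gene panel.
#' @param min_specificity specificity floor for cut-off selection
#'   (default 0.80).
#' @param legacy_cutoff optional fixed score cut-off (e.g. 8.8, applied as
#'   score >= 9); `NULL` selects the cut-off under the specificity floor.
#' @param seed integer seed; in synthetic mode it overrides the generator's.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = c("synthetic", "csv"),
                       generator = generator_config(),
                       covariates_csv = NULL, expression_csv = NULL,
                       panel = default_panel(),
                       min_specificity = 0.80, legacy_cutoff = NULL,
                       seed = generator$seed) {
  input <- match.arg(input)
  if (min_specificity <= 0 || min_specificity >= 1) {
    stop("min_specificity must lie in (0, 1)")
  }
  if (input == "csv" && (is.null(covariates_csv) || is.null(expression_csv))) {
    stop("csv mode requires covariates_csv and expression_csv")
  }
  generator$seed <- as.integer(seed)
  structure(
    list(input = input, generator = generator,
         covariates_csv = covariates_csv, expression_csv = expression_csv,
         panel = panel, min_specificity = min_specificity,
         legacy_cutoff = legacy_cutoff, seed = as.integer(seed)),
    class = "run_config"
  )
}

config_hash <- function(config) {
  stripped <- config[setdiff(names(config), "panel")]
  stripped$generator <- unclass(config$generator)
  stripped$panel_genes <- config$panel$gene
  stripped$panel_cutoffs <- config$panel$cutoff
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(stripped, auto_unbox = TRUE,
                                           digits = NA, null = "null")), tmp)
  unname(tools::md5sum(tmp))
}

# numeric design encoding: female = 1, immunotherapy ordinal 0/1/2,
# center bern = 1, outcome resistant = 1
encode_design <- function(covariates, labels, scores) {
  immu_levels <- c(none = 0, mild_moderate = 1, high = 2)
  bad <- setdiff(unique(covariates$immunotherapy), names(immu_levels))
  if (length(bad) > 0) stop("unknown immunotherapy class: ", paste(bad, collapse = ", "))
  data.frame(
    resistant = as.integer(labels),
    score = as.numeric(scores),
    female = as.integer(covariates$sex == "F"),
    age = covariates$age,
    disease_duration = covariates$disease_duration,
    immunotherapy_group = unname(immu_levels[covariates$immunotherapy]),
    edss_prior = covariates$edss_prior,
    gc_dose_mg = covariates$gc_dose_mg,
    center_bern = as.integer(covariates$center == "bern")
  )
}

#' Run the full GC-resistance scoring pipeline
#'
#' Simulates (or loads) a two-group relapse cohort, scores every complete
#' patient against the panel cut-offs, characterizes the composite score as
#' a classifier of GC resistance, computes baseline group comparisons, and
#' fits the confounder-adjusted logistic regression (score + sex + age +
#' disease duration + immunotherapy group + EDSS prior GC + GC dose), plus
#' a second model additionally adjusted for recruitment center. The run is
#' deterministic given the seed; the report embeds seed, config hash and
#' package version.
#'
#' @param config a [run_config()].
#' @return A list of class `run_report`; see the elements it prints.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  panel <- config$panel

  if (config$input == "synthetic") {
    cohort <- generate_cohort(config$generator, panel = panel)
    covariates <- cohort$covariates
    expr <- cohort$expression
  } else {
    covariates <- utils::read.csv(config$covariates_csv, stringsAsFactors = FALSE)
    required <- c("patient_id", "group", "age", "sex", "disease_duration",
                  "edss_prior", "edss_post", "gc_dose_mg", "immunotherapy",
                  "center")
    miss <- setdiff(required, names(covariates))
    if (length(miss) > 0) {
      stop("covariate CSV lacks column(s): ", paste(miss, collapse = ", "))
    }
    expr <- read_expression_matrix(config$expression_csv)
    covariates <- covariates[match(rownames(expr), covariates$patient_id), ]
    if (any(is.na(covariates$patient_id))) {
      stop("expression rows without covariate rows: ",
           paste(setdiff(rownames(expr), covariates$patient_id), collapse = ", "))
    }
  }
  labels <- stats::setNames(covariates$group == "resistant",
                            covariates$patient_id)

  bits <- binarize(expr, panel)
  scores <- composite_score(bits)
  excluded <- attr(bits, "excluded")
  keep <- setdiff(rownames(expr), excluded)
  labels_kept <- labels[keep]
  cov_kept <- covariates[match(keep, covariates$patient_id), ]

  # per-gene empirical operating points in this cohort at the fixed cut-offs
  per_gene <- do.call(rbind, lapply(seq_len(nrow(panel)), function(j) {
    g <- panel$gene[j]
    cases <- expr[keep, g][labels_kept]
    controls <- expr[keep, g][!labels_kept]
    orient <- if (panel$direction[j] == "up") "higher_positive" else "lower_positive"
    curve <- roc_curve(cases, controls, orientation = orient)
    fire <- bits[, g] == 1L
    data.frame(
      gene = g, direction = panel$direction[j], cutoff = panel$cutoff[j],
      auc = curve$auc,
      rate_resistant = mean(fire[labels_kept]),
      rate_sensitive = mean(fire[!labels_kept]),
      stringsAsFactors = FALSE
    )
  }))

  classifier <- score_classifier(scores[keep], labels_kept,
                                 min_specificity = config$min_specificity,
                                 legacy_cutoff = config$legacy_cutoff)
  score_dist <- table(
    group = factor(ifelse(labels_kept, "resistant", "sensitive")),
    score = factor(scores[keep], levels = 0:nrow(panel))
  )

  baseline <- baseline_comparisons(cov_kept)
  design <- encode_design(cov_kept, labels_kept, scores[keep])
  adj_predictors <- c("score", "female", "age", "disease_duration",
                      "immunotherapy_group", "edss_prior", "gc_dose_mg")
  fit_try <- function(preds) {
    tryCatch(suppressWarnings(fit_logistic(design, "resistant", preds)),
             error = function(e) structure(list(error = conditionMessage(e)),
                                           class = "logistic_fit_failure"))
  }
  fit_adjusted <- fit_try(adj_predictors)
  fit_center <- fit_try(c(adj_predictors, "center_bern"))

  report <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("gcpanel")),
    n_patients = nrow(covariates),
    n_scored = length(keep),
    excluded_patients = excluded,
    n_sensitive = sum(!labels_kept),
    n_resistant = sum(labels_kept),
    per_gene = per_gene,
    score_distribution = score_dist,
    classifier = classifier,
    baseline = baseline,
    fit_adjusted = fit_adjusted,
    fit_center = fit_center,
    min_specificity = config$min_specificity,
    legacy_cutoff = config$legacy_cutoff,
    rate_interpretation = config$generator$rate_interpretation,
    input = config$input
  )
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("GC-resistance panel run (gcpanel %s, seed %d, config %s)\n",
              x$package_version, x$seed, substr(x$config_hash, 1, 8)))
  cat(sprintf("Cohort: %d patients (%d sensitive / %d resistant), %d scored",
              x$n_patients, x$n_sensitive, x$n_resistant, x$n_scored))
  if (length(x$excluded_patients) > 0) {
    cat(sprintf(", %d excluded for missing panel genes", length(x$excluded_patients)))
  }
  cat("\n\n")
  print(x$classifier)
  if (inherits(x$fit_adjusted, "logistic_fit")) {
    cat("\nAdjusted logistic model:\n")
    print(x$fit_adjusted)
  } else {
    cat("\nAdjusted logistic model failed: ", x$fit_adjusted$error, "\n")
  }
  invisible(x)
}

fit_to_list <- function(fit) {
  if (inherits(fit, "logistic_fit")) {
    list(converged = fit$converged, separation = fit$separation,
         n = fit$n, loglik = fit$loglik, table = fit$table)
  } else {
    list(error = fit$error)
  }
}

#' Write a run report to JSON and Markdown
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  md_path <- file.path(dir, "report.md")

  payload <- list(
    seed = report$seed,
    config_hash = report$config_hash,
    package_version = report$package_version,
    input = report$input,
    rate_interpretation = report$rate_interpretation,
    cohort = list(n_patients = report$n_patients, n_scored = report$n_scored,
                  n_sensitive = report$n_sensitive,
                  n_resistant = report$n_resistant,
                  excluded_patients = report$excluded_patients),
    per_gene = report$per_gene,
    score_distribution = list(
      scores = as.integer(colnames(report$score_distribution)),
      sensitive = as.integer(report$score_distribution["sensitive", ]),
      resistant = as.integer(report$score_distribution["resistant", ])
    ),
    classifier = list(auc = report$classifier$auc,
                      cutoff = report$classifier$cutoff,
                      sensitivity = report$classifier$sensitivity,
                      specificity = report$classifier$specificity,
                      min_specificity = report$min_specificity,
                      legacy_cutoff = report$legacy_cutoff),
    baseline = report$baseline,
    logistic_adjusted = fit_to_list(report$fit_adjusted),
    logistic_center = fit_to_list(report$fit_center)
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")

  md <- c(
    "# GC-resistance panel run report",
    "",
    sprintf("- package: gcpanel %s", report$package_version),
    sprintf("- seed: %d; config hash: %s", report$seed, report$config_hash),
    sprintf("- cohort: %d patients (%d sensitive / %d resistant); %d scored; %d excluded",
            report$n_patients, report$n_sensitive, report$n_resistant,
            report$n_scored, length(report$excluded_patients)),
    "",
    "## Composite score classifier",
    "",
    sprintf("- AUC: %.3f", report$classifier$auc),
    sprintf("- cut-off: score >= %s (specificity floor %.2f%s)",
            format(report$classifier$cutoff), report$min_specificity,
            if (!is.null(report$legacy_cutoff))
              sprintf("; legacy cut-off %.1f applied", report$legacy_cutoff)
            else ""),
    sprintf("- sensitivity %.1f%%, specificity %.1f%%",
            100 * report$classifier$sensitivity,
            100 * report$classifier$specificity),
    "",
    "## Per-gene operating points (fixed panel cut-offs)",
    "",
    paste0("| gene | direction | cutoff | auc | rate resistant | rate sensitive |"),
    paste0("|---|---|---|---|---|---|"),
    sprintf("| %s | %s | %.6f | %.3f | %.3f | %.3f |",
            report$per_gene$gene, report$per_gene$direction,
            report$per_gene$cutoff, report$per_gene$auc,
            report$per_gene$rate_resistant, report$per_gene$rate_sensitive),
    "",
    "## Baseline comparisons",
    "",
    "| variable | test | statistic | p |",
    "|---|---|---|---|",
    sprintf("| %s | %s | %.3f | %.3f |", report$baseline$variable,
            report$baseline$test, report$baseline$statistic,
            report$baseline$p_value)
  )
  fits <- list(`Adjusted logistic model` = report$fit_adjusted,
               `Adjusted logistic model + center` = report$fit_center)
  for (title in names(fits)) {
    fit <- fits[[title]]
    md <- c(md, "", paste0("## ", title), "")
    if (inherits(fit, "logistic_fit")) {
      md <- c(md,
              sprintf("n = %d; converged: %s; separation: %s", fit$n,
                      fit$converged, fit$separation),
              "",
              "| predictor | odds ratio | 95% CI LL | 95% CI UL | p |",
              "|---|---|---|---|---|",
              sprintf("| %s | %.2f | %.2f | %.2f | %.3f |",
                      fit$table$predictor, fit$table$odds_ratio,
                      fit$table$ci_lower, fit$table$ci_upper,
                      fit$table$p_value))
    } else {
      md <- c(md, paste0("fit failed: ", fit$error))
    }
  }
  writeLines(md, md_path)
  invisible(c(json = json_path, markdown = md_path))
}
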