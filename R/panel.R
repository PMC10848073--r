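#' Panel specification: per-gene ROC cut-offs and operating points
#'
#' A `panel_spec` is a data frame describing a fixed gene panel: for each
#' gene, the ROC-defined cut-off on the relative-expression (Ct ratio) scale,
#' the sensitivity and 1 - specificity attained at that cut-off in the
#' derivation cohort, the AUC, and the direction of regulation in
#' GC-resistant patients. Direction is `"up"` exactly when the AUC exceeds
#' 0.5 under the higher-positive orientation: up-regulated genes score a
#' point when expression is at or above the cut-off, down-regulated genes
#' when expression is strictly below it.
#'
#' @param gene character vector of gene symbols.
#' @param cutoff positive numeric cut-offs on the relative-expression scale.
#' @param sensitivity,one_minus_specificity operating point fractions in
#'   \[0, 1\] attained at `cutoff`.
#' @param auc area under the ROC curve in \[0, 1\] (higher-positive
#'   orientation, GC-resistant as positive class).
#' @return A data frame of class `panel_spec` with columns `gene`, `cutoff`,
#'   `sensitivity`, `one_minus_specificity`, `auc`, `direction`.
#' @seealso [read_panel_spec()], [default_panel()], [derive_positivity_rates()]
#' @export
panel_spec <- function(gene, cutoff, sensitivity, one_minus_specificity, auc) {
  spec <- data.frame(
    gene = as.character(gene),
    cutoff = as.numeric(cutoff),
    sensitivity = as.numeric(sensitivity),
    one_minus_specificity = as.numeric(one_minus_specificity),
    auc = as.numeric(auc),
    stringsAsFactors = FALSE
  )
  spec$direction <- ifelse(spec$auc > 0.5, "up", "down")
  validate_panel_spec(spec)
  class(spec) <- c("panel_spec", "data.frame")
  spec
}

validate_panel_spec <- function(spec) {
  stopifnot(is.data.frame(spec))
  required <- c("gene", "cutoff", "sensitivity", "one_minus_specificity", "auc")
  missing_cols <- setdiff(required, names(spec))
  if (length(missing_cols) > 0) {
    stop("panel spec is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(spec$gene)) stop("panel spec has duplicated gene ids")
  fracs <- c(spec$sensitivity, spec$one_minus_specificity, spec$auc)
  if (any(!is.finite(fracs)) || any(fracs < 0) || any(fracs > 1)) {
    stop("sensitivity, one_minus_specificity and auc must lie in [0, 1]")
  }
  if (any(!is.finite(spec$cutoff)) || any(spec$cutoff <= 0)) {
    stop("cut-offs must be strictly positive")
  }
  if ("direction" %in% names(spec)) {
    expected <- ifelse(spec$auc > 0.5, "up", "down")
    if (!all(spec$direction == expected)) {
      stop("direction must be 'up' exactly when auc > 0.5")
    }
  }
  invisible(spec)
}

#' Read a panel specification from CSV
#'
#' Expects columns `gene`, `cutoff`, `sensitivity`, `one_minus_specificity`,
#' `auc` (the column layout of the shipped 12-gene fixture).
#'
#' @param path path to a CSV file.
#' @return A `panel_spec` data frame.
#' @export
read_panel_spec <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  panel_spec(raw$gene, raw$cutoff, raw$sensitivity,
             raw$one_minus_specificity, raw$auc)
}

#' The 12-gene GC-resistance panel
#'
#' Returns the packaged 12-gene panel (PGAP3, LDLRAP1, SNPH, DDX54, ABHD8,
#' FASN, SNX2, RHOT1, EAF2, ANXA1, AIM2, N4BP2L2) with its published
#' qPCR-ratio cut-offs, operating points and AUCs, derived in a cohort of
#' 10 GC-sensitive and 15 GC-resistant MS relapses. Six genes are
#' up-regulated in GC-resistant relapses (AUC > 0.5) and six down-regulated.
#'
#' @return A `panel_spec` data frame with 12 rows.
#' @export
default_panel <- function() {
  path <- system.file("extdata", "panel_cutoffs.csv", package = "gcpanel",
                      mustWork = TRUE)
  read_panel_spec(path)
}

#' Per-gene indicator positivity rates implied by a panel's operating points
#'
#' Converts each gene's published (sensitivity, 1 - specificity) at its
#' cut-off into the probability that the gene's scoring indicator fires in
#' GC-resistant and GC-sensitive patients.
#'
#' Under `interpretation = "complement"` (the default), the printed
#' operating points are taken in a fixed higher-positive orientation, so for
#' down-regulated genes -- which score a point when expression falls *below*
#' the cut-off -- the firing rates are the complements
#' (1 - sensitivity, 1 - (1 - specificity)). Under `"as_printed"` the
#' printed pair is used unchanged for every gene. Up-regulated genes are
#' identical under both interpretations.
#'
#' @param panel a `panel_spec`.
#' @param interpretation `"complement"` or `"as_printed"`.
#' @return A data frame with columns `gene`, `direction`, `rate_resistant`,
#'   `rate_sensitive`.
#' @export
derive_positivity_rates <- function(panel,
                                    interpretation = c("complement", "as_printed")) {
  interpretation <- match.arg(interpretation)
  validate_panel_spec(panel)
  down <- panel$direction == "down"
  rate_res <- panel$sensitivity
  rate_sen <- panel$one_minus_specificity
  if (interpretation == "complement") {
    rate_res[down] <- 1 - panel$sensitivity[down]
    rate_sen[down] <- 1 - panel$one_minus_specificity[down]
  }
  data.frame(
    gene = panel$gene,
    direction = panel$direction,
    rate_resistant = rate_res,
    rate_sensitive = rate_sen,
    stringsAsFactors = FALSE
  )
}
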