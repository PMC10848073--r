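#' Binarize expression against panel cut-offs
#'
#' Applies each panel gene's directional scoring rule to a patients-by-genes
#' relative-expression matrix: a gene up-regulated in GC-resistant relapses
#' scores 1 when its value is greater than *or equal to* the cut-off; a
#' down-regulated gene scores 1 when its value is *strictly below* the
#' cut-off. The asymmetric boundary (inclusive for up, exclusive for down)
#' is deliberate and matches the panel's published scoring rule.
#'
#' Patients missing any panel gene are excluded (complete-case scoring) and
#' reported via the `excluded` attribute.
#'
#' @param expr numeric matrix, patients in rows, genes in columns, values on
#'   the relative-expression (Ct ratio) scale.
#' @param panel a [panel_spec()].
#' @return Integer 0/1 matrix (patients x panel genes) with attribute
#'   `excluded` listing patient ids dropped for missing panel genes.
#' @export
binarize <- function(expr, panel) {
  validate_panel_spec(panel)
  missing_genes <- setdiff(panel$gene, colnames(expr))
  if (length(missing_genes) > 0) {
    stop("expression matrix lacks panel gene(s): ",
         paste(missing_genes, collapse = ", "))
  }
  x <- expr[, panel$gene, drop = FALSE]
  complete <- stats::complete.cases(x)
  excluded <- rownames(x)[!complete]
  x <- x[complete, , drop = FALSE]
  bits <- matrix(0L, nrow = nrow(x), ncol = ncol(x), dimnames = dimnames(x))
  for (j in seq_len(ncol(x))) {
    bits[, j] <- if (panel$direction[j] == "up") {
      as.integer(x[, j] >= panel$cutoff[j])
    } else {
      as.integer(x[, j] < panel$cutoff[j])
    }
  }
  attr(bits, "excluded") <- excluded
  bits
}

#' Composite panel score
#'
#' Sums per-gene indicator bits into an integer score between 0 and the
#' number of panel genes (0-12 for the default panel).
#'
#' @param bits integer 0/1 matrix from [binarize()].
#' @return Named integer vector of scores, one per patient; the `excluded`
#'   attribute of `bits` is carried over.
#' @export
composite_score <- function(bits) {
  stopifnot(is.matrix(bits), all(bits %in% c(0L, 1L)))
  s <- as.integer(rowSums(bits))
  names(s) <- rownames(bits)
  attr(s, "excluded") <- attr(bits, "excluded")
  s
}

#' Characterize the composite score as a classifier
#'
#' Builds the ROC of the integer score (higher-positive: GC-resistant
#' patients tend to high scores), reports the AUC, and selects the score
#' cut-off maximizing sensitivity under a specificity floor. A real-valued
#' `legacy_cutoff` (for example the published 8.8) overrides the selection
#' and is applied as positivity at score >= ceiling(cutoff), since achieved
#' scores are integers.
#'
#' @param scores integer score vector.
#' @param labels logical or 0/1 vector, `TRUE`/1 = GC-resistant (positive).
#' @param min_specificity specificity floor for cut-off selection.
#' @param legacy_cutoff optional fixed score cut-off to apply instead of
#'   constrained selection.
#' @return A list of class `score_classifier` with `auc`, `cutoff`,
#'   `sensitivity`, `specificity`, `curve` (the score [roc_curve()]), and
#'   `n_cases` / `n_controls`.
#' @export
score_classifier <- function(scores, labels, min_specificity = 0.80,
                             legacy_cutoff = NULL) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (!any(labels) || all(labels)) stop("both classes must be present")
  cases <- scores[labels]
  controls <- scores[!labels]
  curve <- roc_curve(cases, controls, orientation = "higher_positive")
  if (is.null(legacy_cutoff)) {
    op <- select_cutoff_at_specificity(curve, min_specificity)
  } else {
    t <- ceiling(legacy_cutoff)
    op <- list(threshold = t,
               sensitivity = mean(cases >= t),
               specificity = mean(controls < t))
  }
  structure(
    list(auc = curve$auc, cutoff = op$threshold,
         sensitivity = op$sensitivity, specificity = op$specificity,
         curve = curve, n_cases = length(cases), n_controls = length(controls)),
    class = "score_classifier"
  )
}

#' @export
print.score_classifier <- function(x, ...) {
  cat(sprintf(
    "Composite score classifier (%d cases / %d controls)\n  AUC = %.3f; cutoff >= %s: sensitivity %.1f%%, specificity %.1f%%\n",
    x$n_cases, x$n_controls, x$auc, format(x$cutoff),
    100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Exact Poisson-binomial distribution of the composite score
#'
#' Distribution of a sum of independent Bernoulli indicators with
#' gene-specific firing probabilities — the independence-model reference
#' for the composite score. Computed exactly by iterative convolution
#' (dynamic programming, O(n^2)).
#'
#' @param probabilities per-gene firing probabilities in \[0, 1\].
#' @return A list of class `poisson_binomial` with `probabilities` and `pmf`
#'   (a numeric vector over scores `0:length(probabilities)`).
#' @examples
#' d <- poisson_binomial(rep(0.5, 3))
#' d$pmf  # 1/8, 3/8, 3/8, 1/8
#' @export
poisson_binomial <- function(probabilities) {
  p <- as.numeric(probabilities)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  pmf <- 1
  for (pj in p) {
    pmf <- c(pmf * (1 - pj), 0) + c(0, pmf * pj)
  }
  names(pmf) <- 0:length(p)
  structure(list(probabilities = p, pmf = pmf), class = "poisson_binomial")
}

#' Closed-form AUC between two integer score distributions
#'
#' P(S_case > S_control) + P(S_case = S_control)/2 for independent scores
#' drawn from the two pmfs (supports starting at 0).
#'
#' @param pmf_cases,pmf_controls numeric pmf vectors over scores
#'   `0:(length - 1)`.
#' @return AUC in \[0, 1\].
#' @export
auc_from_pmfs <- function(pmf_cases, pmf_controls) {
  k <- max(length(pmf_cases), length(pmf_controls))
  a <- c(pmf_cases, rep(0, k - length(pmf_cases)))
  b <- c(pmf_controls, rep(0, k - length(pmf_controls)))
  cdf_b <- cumsum(b)
  below <- c(0, cdf_b[-k])        # P(control < s)
  sum(a * (below + b / 2))
}
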