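#' Two-group differential-expression contrast
#'
#' Generic per-gene contrast on log-scale expression: Welch two-sample
#' t-test per gene, log fold change as the difference of group means, and
#' Benjamini-Hochberg adjustment across all tested genes. Genes pass the
#' volcano filter when |logFC| exceeds `lfc_threshold` and the adjusted
#' p-value is below `alpha` (strict inequalities). Genes with zero variance
#' in both groups are handled with a small variance floor and reported.
#'
#' @param log_expr numeric matrix of log-scale expression, samples in rows,
#'   genes in columns.
#' @param groups two-level factor/vector of group labels, one per row; the
#'   log fold change is mean(second level) - mean(first level), so pass a
#'   factor with explicit levels to fix the contrast direction.
#' @param lfc_threshold absolute log fold-change threshold (default 0.5).
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @return Data frame with `gene`, `logfc`, `p_value`, `adj_p`, `pass`.
#' @export
de_contrast <- function(log_expr, groups, lfc_threshold = 0.5, alpha = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (min(table(groups)) < 2) stop("each group needs n >= 2")
  a <- log_expr[groups == levels(groups)[2], , drop = FALSE]  # contrast group
  b <- log_expr[groups == levels(groups)[1], , drop = FALSE]  # reference
  floor_var <- 1e-12
  floored <- 0L
  res <- vapply(seq_len(ncol(log_expr)), function(j) {
    va <- stats::var(a[, j]); vb <- stats::var(b[, j])
    if (va < floor_var && vb < floor_var) {
      floored <<- floored + 1L
      d <- mean(a[, j]) - mean(b[, j])
      return(c(d, if (abs(d) < .Machine$double.eps) 1 else 0))
    }
    tt <- stats::t.test(a[, j], b[, j], var.equal = FALSE)
    c(mean(a[, j]) - mean(b[, j]), tt$p.value)
  }, numeric(2))
  if (floored > 0L) {
    message(floored, " gene(s) had zero variance in both groups (variance floor applied)")
  }
  logfc <- res[1, ]
  p <- res[2, ]
  adj <- bh_adjust(p)
  out <- data.frame(
    gene = colnames(log_expr) %||% paste0("g", seq_along(p)),
    logfc = logfc, p_value = p, adj_p = adj,
    pass = abs(logfc) > lfc_threshold & adj < alpha,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p-values (monotone, order-preserving).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' AUC-based panel prefilter
#'
#' Reproduces the panel-candidate selection: keep genes whose
#' group-separating AUC is extreme (strictly above `upper` or strictly below
#' `lower`), then drop non-protein-coding genes. Step-wise counts are
#' attached so filter attrition is auditable.
#'
#' @param aucs named numeric vector of per-gene AUCs in \[0, 1\].
#' @param annotations data frame with columns `gene_id` and `biotype`
#'   (`"protein_coding"` / `"non_coding"`); every AUC survivor must be
#'   annotated.
#' @param upper,lower strict AUC bounds (defaults 0.86 and 0.14).
#' @return Character vector of retained gene ids, with attribute `counts`
#'   (named: `input`, `auc_pass`, `non_coding_dropped`, `retained`).
#' @export
prefilter_by_auc <- function(aucs, annotations, upper = 0.86, lower = 0.14) {
  if (any(aucs < 0 | aucs > 1)) stop("AUCs must lie in [0, 1]")
  if (is.null(names(aucs))) stop("aucs must be named by gene id")
  pass <- names(aucs)[aucs > upper | aucs < lower]
  unannotated <- setdiff(pass, annotations$gene_id)
  if (length(unannotated) > 0) {
    stop("unannotated gene(s) among AUC survivors: ",
         paste(unannotated, collapse = ", "))
  }
  biotype <- annotations$biotype[match(pass, annotations$gene_id)]
  retained <- pass[biotype == "protein_coding"]
  structure(retained, counts = c(
    input = length(aucs),
    auc_pass = length(pass),
    non_coding_dropped = sum(biotype != "protein_coding"),
    retained = length(retained)
  ))
}
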