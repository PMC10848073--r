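#' Read a long-format qPCR Ct table
#'
#' Expects columns `patient_id`, `gene_id`, `replicate`, `ct`. Each row is
#' one technical replicate of one gene in one patient. Ct values must be
#' positive and (patient, gene, replicate) combinations unique.
#'
#' @param path CSV file path.
#' @return A validated data frame of Ct records.
#' @export
read_ct_table <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_ct_records(records)
}

validate_ct_records <- function(records) {
  required <- c("patient_id", "gene_id", "replicate", "ct")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("Ct table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) == 0) stop("Ct table is empty")
  bad <- which(!is.finite(records$ct) | records$ct <= 0)
  if (length(bad) > 0) {
    stop("non-positive or missing Ct values at rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  key <- paste(records$patient_id, records$gene_id, records$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (patient_id, gene_id, replicate) rows at: ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "))
  }
  records
}

#' Aggregate technical qPCR replicates
#'
#' Collapses replicate Ct measurements to one value per (patient, gene),
#' by mean (the default, standard practice for triplicate qPCR) or median.
#'
#' @param records long-format Ct data frame (`patient_id`, `gene_id`,
#'   `replicate`, `ct`).
#' @param method `"mean"` or `"median"`.
#' @return A data frame with columns `patient_id`, `gene_id`, `ct`,
#'   `n_replicates`.
#' @export
aggregate_replicates <- function(records, method = c("mean", "median")) {
  method <- match.arg(method)
  validate_ct_records(records)
  f <- if (method == "mean") mean else stats::median
  agg <- stats::aggregate(ct ~ patient_id + gene_id, data = records, FUN = f)
  n <- stats::aggregate(ct ~ patient_id + gene_id, data = records, FUN = length)
  agg$n_replicates <- n$ct[match(paste(agg$patient_id, agg$gene_id),
                                 paste(n$patient_id, n$gene_id))]
  agg[order(agg$patient_id, agg$gene_id), , drop = FALSE]
}

#' Relative expression from Ct values
#'
#' Computes the relative expression ratio Ct_target / Ct_housekeeping.
#' Because fewer amplification cycles mean more transcript, a lower Ct
#' indicates higher abundance: the ratio is an inverse-abundance scale.
#' All panel cut-offs operate on this measured ratio scale directly.
#'
#' @param ct_gene target-gene Ct value(s), positive.
#' @param ct_reference housekeeping-gene Ct value(s), positive.
#' @return `ct_gene / ct_reference`.
#' @examples
#' normalize_ct(30, 20)  # 1.5
#' @export
normalize_ct <- function(ct_gene, ct_reference) {
  if (any(!is.finite(ct_reference)) || any(ct_reference <= 0)) {
    stop("housekeeping Ct must be positive and present for every patient")
  }
  if (any(!is.finite(ct_gene)) || any(ct_gene <= 0)) {
    stop("target Ct must be positive")
  }
  ct_gene / ct_reference
}

#' Build a patients-by-genes relative-expression matrix from Ct records
#'
#' Aggregates replicates, then normalizes every target gene of a patient by
#' that patient's housekeeping-gene Ct. The housekeeping gene is consumed by
#' normalization and never appears as a column. Patients lacking the
#' housekeeping gene are dropped with a warning; genes a patient was not
#' measured for are `NA` in the matrix.
#'
#' @param records long-format Ct data frame.
#' @param reference_gene housekeeping gene id (default `"ACTB"`).
#' @param method replicate aggregation method, `"mean"` or `"median"`.
#' @return A numeric matrix, rownames = patient ids, colnames = gene ids.
#' @export
expression_matrix <- function(records, reference_gene = "ACTB",
                              method = c("mean", "median")) {
  method <- match.arg(method)
  agg <- aggregate_replicates(records, method = method)
  ref <- agg[agg$gene_id == reference_gene, c("patient_id", "ct")]
  if (nrow(ref) == 0) {
    stop("housekeeping gene '", reference_gene, "' not found in Ct table")
  }
  tgt <- agg[agg$gene_id != reference_gene, , drop = FALSE]
  no_ref <- setdiff(unique(tgt$patient_id), ref$patient_id)
  if (length(no_ref) > 0) {
    warning("dropping ", length(no_ref), " patient(s) without ",
            reference_gene, ": ", paste(no_ref, collapse = ", "))
    tgt <- tgt[!tgt$patient_id %in% no_ref, , drop = FALSE]
  }
  tgt$ratio <- normalize_ct(tgt$ct, ref$ct[match(tgt$patient_id, ref$patient_id)])
  patients <- sort(unique(tgt$patient_id))
  genes <- sort(unique(tgt$gene_id))
  m <- matrix(NA_real_, nrow = length(patients), ncol = length(genes),
              dimnames = list(patients, genes))
  m[cbind(match(tgt$patient_id, patients), match(tgt$gene_id, genes))] <- tgt$ratio
  m
}

#' Write / read a relative-expression matrix as CSV
#'
#' Wide format: first column `patient_id`, one column per gene. Values are
#' written with full double precision so a round-trip is lossless to at
#' least 12 significant digits.
#'
#' @param m numeric matrix, patients in rows (rownames), genes in columns.
#' @param path CSV file path.
#' @return `write_expression_matrix` returns `path` invisibly;
#'   `read_expression_matrix` returns the matrix.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(patient_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "patient_id") {
    stop("expression CSV must have 'patient_id' as its first column")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$patient_id
  storage.mode(m) <- "double"
  if (any(m[!is.na(m)] <= 0)) stop("relative expression values must be positive")
  m
}
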