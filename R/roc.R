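#' Empirical ROC curve
#'
#' Builds the empirical ROC curve of a continuous (or integer) marker for
#' separating cases (GC-resistant) from controls (GC-sensitive). Candidate
#' thresholds are the distinct observed marker values; positivity is
#' inclusive of the threshold (value >= t for `"higher_positive"`,
#' value <= t for `"lower_positive"`), matching the scoring convention that
#' a gene at its cut-off counts as positive. The AUC is the tie-corrected
#' Mann-Whitney statistic U / (n_cases * n_controls), i.e. the probability
#' that a random case outranks a random control with half credit for ties.
#'
#' @param cases numeric marker values of the positive class.
#' @param controls numeric marker values of the negative class.
#' @param orientation `"higher_positive"` (default) or `"lower_positive"`.
#' @return An object of class `roc_curve`: a list with `thresholds` (sorted
#'   distinct observed values, plus one infinite sentinel so the curve spans
#'   (0,0) to (1,1)), `sensitivity`, `specificity` (per threshold), `auc`,
#'   and `orientation`.
#' @examples
#' rc <- roc_curve(c(2, 3, 5), c(1, 2, 4))
#' rc$auc  # 6.5 / 9
#' @export
roc_curve <- function(cases, controls,
                      orientation = c("higher_positive", "lower_positive")) {
  orientation <- match.arg(orientation)
  cases <- as.numeric(cases)
  controls <- as.numeric(controls)
  if (length(cases) < 1 || length(controls) < 1) {
    stop("need at least one case and one control")
  }
  if (any(!is.finite(c(cases, controls)))) {
    stop("marker values must be finite")
  }
  thresholds <- sort(unique(c(cases, controls)))
  # sentinel beyond the extreme value: the all-negative endpoint (0,0)
  thresholds <- if (orientation == "higher_positive") c(thresholds, Inf) else c(-Inf, thresholds)
  if (orientation == "higher_positive") {
    sens <- vapply(thresholds, function(t) mean(cases >= t), numeric(1))
    spec <- vapply(thresholds, function(t) mean(controls < t), numeric(1))
  } else {
    sens <- vapply(thresholds, function(t) mean(cases <= t), numeric(1))
    spec <- vapply(thresholds, function(t) mean(controls > t), numeric(1))
  }
  structure(
    list(
      thresholds = thresholds,
      sensitivity = sens,
      specificity = spec,
      auc = auc_mann_whitney(cases, controls, orientation),
      orientation = orientation
    ),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("Empirical ROC curve (%s): %d thresholds, AUC = %.4f\n",
              x$orientation, length(x$thresholds), x$auc))
  invisible(x)
}

# Tie-corrected AUC via mid-ranks: U/(n1*n2) where U counts case-control
# pairs with the case on the positive side, ties worth 1/2.
auc_mann_whitney <- function(cases, controls, orientation = "higher_positive") {
  n1 <- length(cases)
  n2 <- length(controls)
  r <- rank(c(cases, controls))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  a <- u / (n1 * n2)
  if (orientation == "lower_positive") a <- 1 - a
  a
}

#' Infer a marker's direction of regulation in the positive class
#'
#' `"up"` if the higher-positive AUC exceeds 0.5 (the marker tends to be
#' higher in cases), `"down"` if below; exact ties break to `"up"`.
#'
#' @inheritParams roc_curve
#' @return `"up"` or `"down"`.
#' @export
infer_direction <- function(cases, controls) {
  a <- auc_mann_whitney(cases, controls)
  if (a >= 0.5) "up" else "down"
}

#' Select a cut-off under a specificity constraint
#'
#' Among thresholds of an empirical ROC curve whose specificity is at least
#' `min_specificity`, returns the one maximizing sensitivity; ties are broken
#' toward higher specificity and then toward the more extreme threshold
#' (larger for higher-positive curves, smaller for lower-positive). If no
#' threshold meets the constraint the degenerate all-negative operating
#' point (sensitivity 0, specificity 1) is returned with a warning, with an
#' infinite threshold in the direction that classifies everyone negative.
#'
#' @param curve a `roc_curve`.
#' @param min_specificity required specificity floor, in (0, 1).
#' @return A list with `threshold`, `sensitivity`, `specificity`.
#' @export
select_cutoff_at_specificity <- function(curve, min_specificity = 0.80) {
  stopifnot(inherits(curve, "roc_curve"))
  if (!is.numeric(min_specificity) || length(min_specificity) != 1 ||
      min_specificity <= 0 || min_specificity >= 1) {
    stop("min_specificity must be a single value in (0, 1)")
  }
  ok <- curve$specificity >= min_specificity & is.finite(curve$thresholds)
  if (!any(ok)) {
    warning("no threshold attains the required specificity; ",
            "returning the all-negative operating point")
    t_deg <- if (curve$orientation == "higher_positive") Inf else -Inf
    return(list(threshold = t_deg, sensitivity = 0, specificity = 1))
  }
  idx <- which(ok)
  best_sens <- max(curve$sensitivity[idx])
  idx <- idx[curve$sensitivity[idx] == best_sens]
  best_spec <- max(curve$specificity[idx])
  idx <- idx[curve$specificity[idx] == best_spec]
  t <- if (curve$orientation == "higher_positive") {
    max(curve$thresholds[idx])
  } else {
    min(curve$thresholds[idx])
  }
  i <- idx[match(t, curve$thresholds[idx])]
  list(threshold = t,
       sensitivity = curve$sensitivity[i],
       specificity = curve$specificity[i])
}

#' Export a ROC curve as a data frame
#'
#' @param x a `roc_curve`.
#' @param row.names,optional,... passed for S3 compatibility; unused.
#' @return data frame with columns `threshold`, `sensitivity`, `specificity`.
#' @export
as.data.frame.roc_curve <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(threshold = x$thresholds,
             sensitivity = x$sensitivity,
             specificity = x$specificity)
}
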