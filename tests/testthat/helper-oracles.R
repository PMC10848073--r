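# Independent brute-force oracles, kept deliberately naive and separate from
# the implementation paths they check.

# AUC as a double loop over all case-control pairs, half credit for ties.
auc_bruteforce <- function(cases, controls) {
  wins <- 0
  for (x in cases) {
    for (y in controls) {
      wins <- wins + (x > y) + 0.5 * (x == y)
    }
  }
  wins / (length(cases) * length(controls))
}

# Benjamini-Hochberg by its step-up definition: adj_(i) = min over j >= i of
# min(1, m * p_(j) / j), mapped back to input order.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Poisson-binomial pmf by full enumeration over all 2^n indicator patterns.
pmf_enumeration <- function(p) {
  n <- length(p)
  pmf <- numeric(n + 1)
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    prob <- prod(ifelse(bits == 1, p, 1 - p))
    pmf[sum(bits) + 1] <- pmf[sum(bits) + 1] + prob
  }
  pmf
}

# Constrained cut-off selection by exhaustive enumeration of observed
# thresholds (inclusive positivity), mirroring the stated selection rule.
cutoff_enumeration <- function(cases, controls, min_specificity,
                               orientation = "higher_positive") {
  thresholds <- sort(unique(c(cases, controls)))
  best <- NULL
  for (t in thresholds) {
    if (orientation == "higher_positive") {
      sens <- mean(cases >= t); spec <- mean(controls < t)
    } else {
      sens <- mean(cases <= t); spec <- mean(controls > t)
    }
    if (spec < min_specificity) next
    if (is.null(best) || sens > best$sensitivity ||
        (sens == best$sensitivity && spec > best$specificity) ||
        (sens == best$sensitivity && spec == best$specificity &&
         ((orientation == "higher_positive" && t > best$threshold) ||
          (orientation == "lower_positive" && t < best$threshold)))) {
      best <- list(threshold = t, sensitivity = sens, specificity = spec)
    }
  }
  best
}

make_expr <- function(values, genes, patients = paste0("P", seq_len(nrow(values)))) {
  m <- as.matrix(values)
  dimnames(m) <- list(patients, genes)
  m
}

tiny_panel <- function() {
  panel_spec(
    gene = c("UP1", "UP2", "DN1"),
    cutoff = c(1.2, 0.9, 1.5),
    sensitivity = c(0.8, 0.6, 0.1),
    one_minus_specificity = c(0.2, 0.1, 0.05),
    auc = c(0.85, 0.75, 0.2)
  )
}
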