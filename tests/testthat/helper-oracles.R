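# Independent brute-force oracles used to freeze expected values.

# Exhaustive 1-D two-cluster split: naive within-cluster SS at every split
# of the sorted values; midpoint of the two cluster means at the best one.
oracleSplitCutoff <- function(values) {
  x <- sort(values)
  n <- length(x)
  ss <- vapply(seq_len(n - 1L), function(k) {
    lo <- x[1:k]; hi <- x[(k + 1):n]
    sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }, numeric(1))
  k <- which.min(ss)
  (mean(x[1:k]) + mean(x[(k + 1):n])) / 2
}

# Full permutation enumeration of the Mann-Whitney p-value: every
# assignment of the pooled values to the two groups.
oracleMWp <- function(a, b, alternative = "two.sided") {
  pool <- c(a, b)
  n1 <- length(a)
  uOf <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  obs <- uOf(a, b)
  combos <- utils::combn(length(pool), n1)
  us <- apply(combos, 2, function(ix) uOf(pool[ix], pool[-ix]))
  mu <- n1 * length(b) / 2
  switch(alternative,
         less = mean(us <= obs),
         greater = mean(us >= obs),
         two.sided = mean(abs(us - mu) >= abs(obs - mu) - 1e-12))
}

# Exhaustive likelihood-ratio-optimal cutoff over midpoint candidates,
# applying the perfect-specificity rule and the stated tie-breaks.
oracleOptimalCutoff <- function(scores, pos) {
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  best <- NULL
  for (cf in cand) {
    sens <- mean(scores[pos] > cf)
    spec <- mean(scores[!pos] <= cf)
    if (sens == 0) next
    lr <- if (spec == 1) Inf else sens / (1 - spec)
    rec <- list(cutoff = cf, sensitivity = sens, specificity = spec, lr = lr)
    if (is.null(best) ||
        lr > best$lr ||
        (lr == best$lr && sens > best$sensitivity) ||
        (lr == best$lr && sens == best$sensitivity && cf < best$cutoff)) {
      best <- rec
    }
  }
  best
}

# Match segmented cells to ground truth by centroid proximity (within the
# truth radius); returns recall and precision.
matchSegmentation <- function(cells, truth, slack = 3) {
  if (nrow(cells) == 0L) return(c(recall = 0, precision = if (nrow(cells)) 0 else 1, matched = 0))
  d <- sqrt(outer(truth$row, cells$row, "-")^2 +
            outer(truth$col, cells$col, "-")^2)
  used <- rep(FALSE, nrow(cells))
  matched <- 0L
  for (i in order(apply(d, 1, min))) {
    j <- which.min(ifelse(used, Inf, d[i, ]))
    if (is.finite(d[i, j]) && d[i, j] <= truth$radius[i] + slack && !used[j]) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  c(recall = matched / nrow(truth), precision = matched / nrow(cells),
    matched = matched)
}

# Map simulated truth labels to the label classifyCells() should emit.
expectedLabel <- function(truthLabel) {
  ifelse(truthLabel == "WBC", "EXCLUDED", truthLabel)
}
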