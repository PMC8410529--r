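## Sample-level enumeration, group comparison, ROC with
## likelihood-ratio-optimal cutoff, and longitudinal threshold-crossing
## reports.

#' Enumerate a sample's CTC densities from phenotype calls
#'
#' Counts countable cells (non-QC-flagged CTC phenotypes) per phenotype
#' and divides by the blood volume. EXCLUDED and TRIPLE_NEG cells never
#' contribute. ALL_CTC density is the sum of the three subtype densities;
#' CK_PLUS pools CK_S and DP.
#'
#' @param calls PhenotypeCall data.frame from [classifyCells()].
#' @param volume Blood volume in mL (> 0).
#' @param sampleId,response,therapy,week Optional sample metadata carried
#'   into the summary (response in responding/progressing/untreated,
#'   therapy in ICI/TKI/other).
#' @return One-row data.frame (SampleSummary): metadata, n_<PHENOTYPE>
#'   and density_<PHENOTYPE> for CAXII_S, DP, CK_S, ALL_CTC, CK_PLUS.
#' @examples
#' calls <- data.frame(label = factor(c("CAXII_S", "CK_S", "EXCLUDED"),
#'                                    levels = allLabels()),
#'                     countable = c(TRUE, TRUE, FALSE))
#' enumerateSample(calls, volume = 2)$density_ALL_CTC
#' @export
enumerateSample <- function(calls, volume, sampleId = NA_character_,
                            response = NA_character_,
                            therapy = NA_character_, week = NA_real_) {
  if (!is.numeric(volume) || length(volume) != 1L || volume <= 0) {
    stop("volume must be a single value > 0 (mL)")
  }
  countable <- calls[calls$countable & calls$label %in% ctcLabels(), ,
                     drop = FALSE]
  out <- data.frame(sample_id = sampleId, volume = volume,
                    response = response, therapy = therapy, week = week,
                    stringsAsFactors = FALSE)
  for (ph in ctcLabels()) {
    nph <- sum(countable$label == ph)
    out[[paste0("n_", ph)]] <- nph
    out[[paste0("density_", ph)]] <- nph / volume
  }
  out$n_ALL_CTC <- nrow(countable)
  out$density_ALL_CTC <- nrow(countable) / volume
  out$n_CK_PLUS <- sum(countable$label %in% c("CK_S", "DP"))
  out$density_CK_PLUS <- out$n_CK_PLUS / volume
  out
}

#' Compare CTC densities between two groups
#'
#' Mann-Whitney (Wilcoxon rank-sum) or Welch t test. For the rank-sum
#' test, the p-value is from the exact permutation distribution when the
#' combined sample size is at most 12 and there are no ties; otherwise the
#' normal approximation with tie correction is used.
#'
#' @param a,b Numeric vectors of per-sample densities.
#' @param test "wilcox" (default) or "t" (Welch, unequal variance).
#' @param alternative "two.sided" (default), "less" or "greater"
#'   (alternative: `a` tends less/greater than `b`).
#' @return List of class `groupTest`: statistic (U or t), p.value, method,
#'   alternative, exact flag, and per-group summaries (n, mean, min, max).
#' @examples
#' compareGroups(c(1, 2, 3), c(10, 20, 30), alternative = "less")$p.value
#' @export
compareGroups <- function(a, b, test = c("wilcox", "t"),
                          alternative = c("two.sided", "less", "greater")) {
  test <- match.arg(test)
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (test == "t") {
    if (length(a) < 2L || length(b) < 2L) {
      stop("the t test needs at least 2 values per group")
    }
    ht <- stats::t.test(a, b, alternative = alternative, var.equal = FALSE)
    exact <- FALSE
  } else {
    exact <- (length(a) + length(b)) <= 12L && !anyDuplicated(c(a, b))
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                         correct = !exact))
  }
  summarise <- function(x) c(n = length(x), mean = mean(x), min = min(x),
                             max = max(x))
  structure(list(statistic = unname(ht$statistic), p.value = ht$p.value,
                 method = test, alternative = alternative, exact = exact,
                 groups = rbind(a = summarise(a), b = summarise(b))),
            class = "groupTest")
}

#' @export
print.groupTest <- function(x, ...) {
  cat(sprintf("%s test (%s%s): statistic = %.4g, p = %.4g\n",
              if (x$method == "wilcox") "Mann-Whitney" else "Welch t",
              x$alternative, if (x$exact) ", exact" else "",
              x$statistic, x$p.value))
  cat(sprintf("  group a: n = %.0f, mean = %.3g; group b: n = %.0f, mean = %.3g\n",
              x$groups["a", "n"], x$groups["a", "mean"],
              x$groups["b", "n"], x$groups["b", "mean"]))
  invisible(x)
}

#' ROC analysis of a density score against response labels
#'
#' Progressing samples form the positive class and higher scores indicate
#' progression; responding samples are the control group. Candidate
#' cutoffs are the midpoints between consecutive distinct sorted scores
#' plus infinite sentinels, so the reported optimal cutoff falls between
#' observed sample values. The AUC is computed by the trapezoidal rule,
#' which (including ties) equals the Mann-Whitney U statistic divided by
#' n1 * n2; the p-value tests AUC = 0.5 through the tie-corrected normal
#' approximation of U.
#'
#' @param scores Numeric per-sample scores (e.g. CTC densities).
#' @param labels Vector of class labels, same length as scores.
#' @param positive Label of the positive (progressing) class.
#' @return A [ROCResult-class] with the curve, AUC, p-value and the
#'   likelihood-ratio-optimal operating point.
#' @examples
#' r <- rocCurve(c(5, 6, 7, 1, 2, 3),
#'               rep(c("progressing", "responding"), each = 3))
#' auc(r)
#' @export
rocCurve <- function(scores, labels, positive = "progressing") {
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("both the positive and the control class must be present")
  }
  s <- sort(unique(scores))
  cutoffs <- c(-Inf, if (length(s) > 1L) (s[-1] + s[-length(s)]) / 2, Inf)
  sens <- vapply(cutoffs, function(cf) mean(scores[pos] > cf), numeric(1))
  spec <- vapply(cutoffs, function(cf) mean(scores[!pos] <= cf), numeric(1))
  curve <- data.frame(cutoff = cutoffs, sensitivity = sens,
                      specificity = spec)
  fpr <- 1 - spec
  aucVal <- sum((fpr[-length(fpr)] - fpr[-1]) *
                (sens[-length(sens)] + sens[-1]) / 2)
  ## normal approximation of U with tie correction, against AUC = 0.5
  U <- aucVal * n1 * n0
  N <- n1 + n0
  ties <- table(scores)
  sigma2 <- n1 * n0 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  pvalue <- if (sigma2 <= 0) 1 else {
    2 * stats::pnorm(-abs((U - n1 * n0 / 2) / sqrt(sigma2)))
  }
  res <- new("ROCResult", curve = curve, auc = aucVal, pvalue = pvalue,
             nPositive = as.integer(n1), nNegative = as.integer(n0),
             optimum = list())
  res@optimum <- optimalCutoff(res)
  res
}

#' Likelihood-ratio-optimal ROC cutoff
#'
#' Selects the cutoff maximising the positive likelihood ratio
#' LR = sensitivity / (1 - specificity) among cutoffs with sensitivity
#' greater than 0. Cutoffs achieving perfect specificity with non-zero
#' sensitivity have infinite LR and win whenever present; the result then
#' carries `perfectSpecificity = TRUE` so the degenerate LR is explicit.
#' Ties are broken toward higher sensitivity, then toward the lower
#' cutoff.
#'
#' @param x A [ROCResult-class] or a curve data.frame with cutoff,
#'   sensitivity and specificity columns.
#' @param requireFinite Restrict the search to cutoffs with
#'   specificity < 1, so the returned likelihood ratio is always finite
#'   (the operating point a clinical report would print). Default FALSE:
#'   perfect-specificity cutoffs win with LR = Inf, flagged.
#' @return List: cutoff, sensitivity, specificity, lr,
#'   perfectSpecificity.
#' @examples
#' r <- rocCurve(c(5, 6, 7, 1, 2, 3),
#'               rep(c("progressing", "responding"), each = 3))
#' optimalCutoff(r)$perfectSpecificity
#' @export
optimalCutoff <- function(x, requireFinite = FALSE) {
  curve <- if (is(x, "ROCResult")) rocPoints(x) else x
  stopifnot(is.data.frame(curve), nrow(curve) > 0L)
  cand <- curve[curve$sensitivity > 0, , drop = FALSE]
  if (requireFinite) cand <- cand[cand$specificity < 1, , drop = FALSE]
  if (nrow(cand) == 0L) stop("no cutoff with sensitivity > 0")
  lr <- ifelse(cand$specificity == 1, Inf,
               cand$sensitivity / (1 - cand$specificity))
  ord <- order(-lr, -cand$sensitivity, cand$cutoff)
  best <- ord[1]
  list(cutoff = cand$cutoff[best], sensitivity = cand$sensitivity[best],
       specificity = cand$specificity[best], lr = lr[best],
       perfectSpecificity = is.infinite(lr[best]))
}

#' Longitudinal threshold-crossing report
#'
#' Scans one phenotype's density trajectory and emits an event whenever
#' the density crosses the supplied cutoff between consecutive
#' timepoints. A value exactly at the cutoff is treated as below it, so a
#' move from at-cutoff to above counts as one upward crossing.
#'
#' @param series data.frame with a strictly increasing `week` column and
#'   a `density_<phenotype>` column (e.g. from [simulateLongitudinal()]
#'   or stacked [enumerateSample()] rows).
#' @param cutoff Density threshold, cells/mL (e.g. the CK+ optimal cutoff
#'   from a cohort ROC).
#' @param phenotype Phenotype whose trajectory is scanned (default
#'   CK_PLUS).
#' @return List: `events` (data.frame week_from, week, phenotype,
#'   direction "up"/"down") and `table` (all phenotype trajectories with
#'   the above/below state of the scanned one).
#' @examples
#' ser <- data.frame(week = c(5, 11), density_CK_PLUS = c(0.4, 5.6))
#' longitudinalReport(ser, cutoff = 2.6)$events
#' @export
longitudinalReport <- function(series, cutoff, phenotype = "CK_PLUS") {
  if (!"week" %in% names(series)) stop("series needs a week column")
  if (is.unsorted(series$week, strictly = TRUE)) {
    stop("weeks must be strictly increasing")
  }
  col <- paste0("density_", phenotype)
  if (!col %in% names(series)) {
    stop(sprintf("series lacks column %s", col))
  }
  above <- series[[col]] > cutoff
  events <- data.frame(week_from = numeric(0), week = numeric(0),
                       phenotype = character(0), direction = character(0),
                       stringsAsFactors = FALSE)
  if (nrow(series) > 1L) {
    chg <- which(above[-1] != above[-length(above)])
    if (length(chg)) {
      events <- data.frame(week_from = series$week[chg],
                           week = series$week[chg + 1L],
                           phenotype = phenotype,
                           direction = ifelse(above[chg + 1L], "up", "down"),
                           stringsAsFactors = FALSE)
    }
  }
  tab <- series
  tab$above_cutoff <- above
  list(events = events, table = tab, cutoff = cutoff)
}
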