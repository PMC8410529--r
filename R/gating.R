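## Positivity cutoffs "using the principles of clustering as in flow
## cytometry": one-dimensional two-cluster minimum-variance partitioning
## with a midpoint cutoff, exclusion-first phenotype classification, and
## per-subpopulation biomarker scoring.

#' Fit a positivity cutoff on background-subtracted intensities
#'
#' Default method partitions the sorted values into two clusters minimising
#' the total within-cluster sum of squares (every split point is
#' evaluated, so the optimum is exact), and returns the midpoint of the
#' two cluster means. When the best partition does not actually separate
#' two populations (cluster separation below `separationThreshold` pooled
#' within-cluster SDs) the sample is treated as unimodal -- a single
#' negative population -- and the fallback cutoff mean + 3 SD is returned.
#' The cutoff is translation-equivariant: shifting all values by c shifts
#' the cutoff by exactly c.
#'
#' @param values Numeric intensities (background-subtracted; may be
#'   negative). At least 2 finite values are required.
#' @param method "cluster" (default) or "manual" (return `manual`).
#' @param manual Cutoff value for method "manual".
#' @param separationThreshold Minimum (mean2 - mean1) / pooled-SD for the
#'   two-cluster solution to be accepted; below it the unimodal fallback
#'   applies. The optimal split of a single Gaussian already achieves a
#'   ratio of about 2.65, so the default of 3 treats anything at or below
#'   that as one population while accepting mixtures whose components are
#'   4 SDs apart or more.
#' @return Cutoff intensity, with attribute `"method"` recording whether
#'   the cluster partition or the unimodal fallback produced it.
#' @examples
#' fitCutoff(c(0, 0, 0, 10, 10, 10))  # 5
#' @export
fitCutoff <- function(values, method = c("cluster", "manual"),
                      manual = NA_real_, separationThreshold = 3) {
  method <- match.arg(method)
  if (method == "manual") {
    if (!is.finite(manual)) stop("manual cutoff must be finite")
    return(structure(manual, method = "manual"))
  }
  x <- values[is.finite(values)]
  if (length(x) < 2L) stop("cutoff fitting needs at least 2 finite values")
  x <- sort(x)
  n <- length(x)
  if (x[1] == x[n]) {
    warning("all values identical; falling back to mean + 3 SD")
    return(structure(x[1], method = "fallback"))
  }
  ## exact optimum over all n-1 splits of the sorted values via prefix sums
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  k <- seq_len(n - 1L)
  ssLow <- cs2[k] - cs[k]^2 / k
  ssHigh <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  best <- which.min(ssLow + ssHigh)
  m1 <- cs[best] / best
  m2 <- (cs[n] - cs[best]) / (n - best)
  v1 <- ssLow[best] / best
  v2 <- ssHigh[best] / (n - best)
  pooledSd <- sqrt((v1 + v2) / 2)
  sepStat <- if (pooledSd == 0) Inf else (m2 - m1) / pooledSd
  if (sepStat < separationThreshold) {
    return(structure(mean(x) + 3 * stats::sd(x), method = "fallback"))
  }
  structure((m1 + m2) / 2, method = "cluster")
}

#' Fit a full GatingConfig from a cell table
#'
#' Fits one cutoff per channel role from the table's background-subtracted
#' intensity columns (per-sample by default, reflecting sample-to-sample
#' washing variability; pool tables beforehand for a cohort-global
#' config). Manual overrides replace fitted values.
#'
#' @param table CellTable data.frame with `bgsub_<ROLE>` columns.
#' @param roles Roles to fit cutoffs for.
#' @param overrides Named numeric vector of manual cutoffs.
#' @param ... Passed to [fitCutoff()].
#' @return A [GatingConfig-class].
#' @export
fitGatingConfig <- function(table,
                            roles = c("EXCLUSION", "CAXII", "CK",
                                      "BIOMARKER"),
                            overrides = NULL, ...) {
  cutoffs <- vapply(roles, function(role) {
    col <- paste0("bgsub_", role)
    if (!col %in% names(table)) {
      stop(sprintf("table lacks column '%s' needed for role %s", col, role))
    }
    as.numeric(fitCutoff(table[[col]], ...))
  }, numeric(1))
  method <- "cluster"
  if (length(overrides)) {
    cutoffs[names(overrides)] <- overrides
    method <- "cluster+manual"
  }
  GatingConfig(cutoffs, method = method)
}

#' Classify cells into CTC phenotypes
#'
#' Applies the exclusion-first rule set: a cell at or above the exclusion
#' cutoff is EXCLUDED regardless of tumor-marker staining; otherwise
#' CAXII+/CK- is CAXII_S, CAXII+/CK+ is DP, CAXII-/CK+ is CK_S, and
#' CAXII-/CK- is TRIPLE_NEG -- a captured cell that is never counted as a
#' CTC. QC-flagged cells are classified but marked non-countable.
#' Classification is a pure row-wise function of the intensity columns.
#'
#' @param table CellTable data.frame with `bgsub_EXCLUSION`, `bgsub_CAXII`
#'   and `bgsub_CK` columns (and optionally `bgsub_BIOMARKER`, `qc_pass`).
#' @param config A [GatingConfig-class] with cutoffs for the roles above.
#' @return data.frame (PhenotypeCall): cell_id, exclusion_pos, caxii_pos,
#'   ck_pos, label, biomarker (background-subtracted value or NA),
#'   biomarker_pos (if a BIOMARKER cutoff is configured), countable.
#' @examples
#' tab <- simulateCellTable(c(CAXII_S = 1, WBC = 1), nCells = 50, seed = 2)
#' cfg <- fitGatingConfig(tab, roles = c("EXCLUSION", "CAXII", "CK"))
#' table(classifyCells(tab, cfg)$label)
#' @export
classifyCells <- function(table, config) {
  stopifnot(is(config, "GatingConfig"))
  cutoffs <- gatingCutoffs(config)
  for (role in c("EXCLUSION", "CAXII", "CK")) {
    if (!role %in% names(cutoffs)) {
      stop(sprintf("GatingConfig lacks a cutoff for role %s", role))
    }
    if (!paste0("bgsub_", role) %in% names(table)) {
      stop(sprintf("table lacks column bgsub_%s", role))
    }
  }
  excl <- table$bgsub_EXCLUSION >= cutoffs[["EXCLUSION"]]
  caxii <- table$bgsub_CAXII >= cutoffs[["CAXII"]]
  ck <- table$bgsub_CK >= cutoffs[["CK"]]
  label <- ifelse(excl, "EXCLUDED",
           ifelse(caxii & !ck, "CAXII_S",
           ifelse(caxii & ck, "DP",
           ifelse(ck, "CK_S", "TRIPLE_NEG"))))
  calls <- data.frame(
    cell_id = if ("cell_id" %in% names(table)) table$cell_id
              else seq_len(nrow(table)),
    exclusion_pos = excl, caxii_pos = caxii, ck_pos = ck,
    label = factor(label, levels = allLabels()),
    stringsAsFactors = FALSE)
  calls$biomarker <- if ("bgsub_BIOMARKER" %in% names(table)) {
    table$bgsub_BIOMARKER
  } else NA_real_
  calls$biomarker_pos <- if ("BIOMARKER" %in% names(cutoffs)) {
    calls$biomarker > cutoffs[["BIOMARKER"]]
  } else NA
  qc <- if ("qc_pass" %in% names(table)) table$qc_pass else TRUE
  calls$countable <- calls$label %in% ctcLabels() & qc
  rownames(calls) <- NULL
  calls
}

#' Score a biomarker per CTC subpopulation
#'
#' For each subpopulation (ALL_CTC, CAXII_S, DP, CK_S, and the pooled
#' CK_PLUS = CK_S plus DP): the number of countable CTCs, the percentage
#' with background-subtracted biomarker expression above the cutoff, and
#' the mean expression. The two statistics are independent: the mean is
#' reported regardless of the cutoff. Subpopulations with no cells are
#' reported missing (NA), not zero.
#'
#' @param calls PhenotypeCall data.frame from [classifyCells()].
#' @param cutoff Biomarker positivity cutoff (background-subtracted
#'   intensity units).
#' @return data.frame: subpopulation, n, pct_positive, mean_expression.
#' @examples
#' calls <- data.frame(label = factor(rep("CK_S", 3), levels = allLabels()),
#'                     biomarker = c(-1, 2, 9), countable = TRUE)
#' scoreBiomarker(calls, cutoff = 1)
#' @export
scoreBiomarker <- function(calls, cutoff) {
  stopifnot(is.finite(cutoff))
  ctc <- calls[calls$countable & calls$label %in% ctcLabels(), , drop = FALSE]
  one <- function(sub) {
    vals <- switch(sub,
      ALL_CTC = ctc$biomarker,
      CK_PLUS = ctc$biomarker[ctc$label %in% c("CK_S", "DP")],
      ctc$biomarker[ctc$label == sub])
    n <- length(vals)
    data.frame(subpopulation = sub, n = n,
               pct_positive = if (n) 100 * mean(vals > cutoff) else NA_real_,
               mean_expression = if (n) mean(vals) else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(subpopulations(), one))
  rownames(out) <- NULL
  out
}

#' Marker co-expression frequencies among exclusion-negative cells
#'
#' Tabulates, over the exclusion-negative subset, the frequency of every
#' combination of the supplied boolean markers (the numbers behind an
#' Euler diagram); frequencies across the 2^k combinations sum to 100%.
#' When a CK column is present, per-marker marginal frequencies are also
#' reported within the CK+ and CK- strata.
#'
#' @param markers data.frame of logical columns, one per marker
#'   (e.g. CK, EpCAM, CAIX, CAXII).
#' @param exclusion Optional logical vector; TRUE rows (exclusion-positive
#'   cells) are removed before tabulation.
#' @return List: `combinations` (combination, count, frequency %),
#'   `marginals` (stratum, marker, frequency % within stratum; NULL
#'   without a CK column), `n` cells tabulated.
#' @examples
#' mk <- data.frame(CK = c(TRUE, TRUE, FALSE), CAIX = c(TRUE, FALSE, TRUE))
#' compositionTable(mk)$combinations
#' @export
compositionTable <- function(markers, exclusion = NULL) {
  if (!is.data.frame(markers) || ncol(markers) == 0L) {
    stop("markers must be a data.frame of logical columns")
  }
  if (!all(vapply(markers, is.logical, logical(1)))) {
    stop("all marker columns must be logical")
  }
  if (!is.null(exclusion)) {
    markers <- markers[!exclusion, , drop = FALSE]
  }
  n <- nrow(markers)
  if (n == 0L) stop("no exclusion-negative cells to tabulate")
  nm <- names(markers)
  combo <- apply(markers, 1, function(r) {
    paste0(nm, ifelse(r, "+", "-"), collapse = "")
  })
  ## enumerate all 2^k combinations so absent ones appear with frequency 0
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), length(nm)))
  names(grid) <- nm
  levelsAll <- apply(grid, 1, function(r) {
    paste0(nm, ifelse(r, "+", "-"), collapse = "")
  })
  counts <- table(factor(combo, levels = levelsAll))
  combinations <- data.frame(combination = names(counts),
                             count = as.integer(counts),
                             frequency = 100 * as.integer(counts) / n,
                             stringsAsFactors = FALSE)
  marginals <- NULL
  if ("CK" %in% nm && length(nm) > 1L) {
    marginals <- do.call(rbind, lapply(c(TRUE, FALSE), function(ckPos) {
      sel <- markers$CK == ckPos
      if (!any(sel)) return(NULL)
      data.frame(stratum = if (ckPos) "CK+" else "CK-",
                 marker = setdiff(nm, "CK"),
                 frequency = vapply(setdiff(nm, "CK"), function(m) {
                   100 * mean(markers[[m]][sel])
                 }, numeric(1)),
                 stringsAsFactors = FALSE)
    }))
    rownames(marginals) <- NULL
  }
  list(combinations = combinations, marginals = marginals, n = n)
}
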