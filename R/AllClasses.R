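#' @import methods
NULL

#' Channel roles recognised by the pipeline
#'
#' The five fluorescence channel roles of the multiplexed CTC panel:
#' nuclear stain, CAXII, pan-cytokeratin, the pooled exclusion channel
#' (CD34/CD45/CD66b on one dye), and the per-cell biomarker channel
#' (PD-L1 or HLA-I, never both on the same cell).
#'
#' @return Character vector of role names.
#' @export
channelRoles <- function() {
  c("NUCLEAR", "CAXII", "CK", "EXCLUSION", "BIOMARKER")
}

#' Phenotype labels
#'
#' `ctcLabels()` are the three countable CTC phenotypes (CAXII
#' single-positive, double-positive, CK single-positive); `allLabels()`
#' additionally includes EXCLUDED (exclusion-channel positive) and
#' TRIPLE_NEG (marker-negative captured cells, never counted as CTCs).
#'
#' @return Character vector of labels.
#' @export
ctcLabels <- function() c("CAXII_S", "DP", "CK_S")

#' @rdname ctcLabels
#' @export
allLabels <- function() c("EXCLUDED", "CAXII_S", "DP", "CK_S", "TRIPLE_NEG")

#' CTC subpopulations reported by biomarker scoring
#'
#' ALL_CTC pools the three phenotypes; CK_PLUS pools CK_S and DP, the
#' cytokeratin-expressing fraction used for the clinical cutoff analyses.
#'
#' @return Character vector of subpopulation names.
#' @export
subpopulations <- function() c("ALL_CTC", "CAXII_S", "DP", "CK_S", "CK_PLUS")

## ---------------------------------------------------------------------------
## ChannelStack
## ---------------------------------------------------------------------------

#' ChannelStack: one registered multichannel imaging field
#'
#' Holds one 2-D intensity array per channel role (all the same shape,
#' 0-based pixel geometry is not used: R matrices are 1-based and indexed
#' (row, col)). Intensities are in arbitrary fluorescence units.
#'
#' @slot channels Named list of numeric matrices, names in
#'   [channelRoles()], at most one matrix per role, all of identical
#'   dimension.
#' @slot metadata List of free-form field metadata (e.g. sample ID).
#' @export
setClass("ChannelStack",
  representation(channels = "list", metadata = "list"),
  prototype(channels = list(), metadata = list())
)

setValidity("ChannelStack", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("at least one channel is required")
  nms <- names(ch)
  if (is.null(nms) || anyNA(nms) || any(nms == "")) {
    return("channels must be named by role")
  }
  if (anyDuplicated(nms)) return("exactly one array per channel role")
  if (!all(nms %in% channelRoles())) {
    return(sprintf("unknown channel role(s): %s",
                   paste(setdiff(nms, channelRoles()), collapse = ", ")))
  }
  if (!all(vapply(ch, function(m) is.matrix(m) && is.numeric(m), logical(1)))) {
    return("every channel must be a numeric matrix")
  }
  dims <- vapply(ch, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    return("all channels must share the same dimensions")
  }
  TRUE
})

#' Construct a ChannelStack
#'
#' @param channels Named list of numeric matrices; names are channel roles
#'   (see [channelRoles()]).
#' @param metadata Optional list of field metadata.
#' @return A [ChannelStack-class] object.
#' @examples
#' stk <- ChannelStack(list(NUCLEAR = matrix(0, 8, 8)))
#' dim(stk)
#' @export
ChannelStack <- function(channels, metadata = list()) {
  new("ChannelStack", channels = channels, metadata = metadata)
}

#' @describeIn ChannelStack Retrieve one channel's intensity matrix by role.
#' @param x A `ChannelStack`.
#' @param role Channel role name.
#' @export
getChannel <- function(x, role) {
  stopifnot(is(x, "ChannelStack"))
  if (!role %in% names(x@channels)) {
    stop(sprintf("channel role '%s' is not present in this stack", role))
  }
  x@channels[[role]]
}

#' @describeIn ChannelStack Roles present in the stack.
#' @export
stackRoles <- function(x) names(x@channels)

#' @export
setMethod("dim", "ChannelStack", function(x) dim(x@channels[[1]]))

setMethod("show", "ChannelStack", function(object) {
  d <- dim(object)
  cat(sprintf("ChannelStack: %d x %d pixels, %d channel(s)\n",
              d[1], d[2], length(object@channels)))
  cat("  roles:", paste(names(object@channels), collapse = ", "), "\n")
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## PhenotypeSpec
## ---------------------------------------------------------------------------

#' PhenotypeSpec: intensity laws for one simulated cell phenotype
#'
#' Describes, for one phenotype, the per-channel law of the cell's mean
#' signal *above local background* and the two-component mixture governing
#' its biomarker (PD-L1/HLA-I) expression. Signal laws are log-normal
#' (fluorescence intensities are non-negative and right-skewed) or normal,
#' parametrised by arithmetic mean and SD.
#'
#' @slot label Phenotype label, one of CAXII_S, DP, CK_S, WBC, TRIPLE_NEG.
#' @slot channels Named list (by channel role) of laws
#'   `list(dist = "lnorm"|"norm", mean =, sd =)`; mean is the signal added
#'   above background, so a marker-negative channel has mean near 0.
#' @slot biomarker List with `posFraction` (in \[0, 1\]), `posMean`,
#'   `posSd`, `negMean`, `negSd` for the bimodal biomarker mixture.
#' @export
setClass("PhenotypeSpec",
  representation(label = "character", channels = "list", biomarker = "list")
)

setValidity("PhenotypeSpec", function(object) {
  if (!object@label %in% c(allLabels()[-1], "WBC")) {
    return(sprintf("unknown phenotype label '%s'", object@label))
  }
  for (role in names(object@channels)) {
    law <- object@channels[[role]]
    if (!is.list(law) || is.null(law$mean) || is.null(law$sd)) {
      return(sprintf("channel '%s' law needs mean and sd", role))
    }
    if (law$mean < 0 || law$sd < 0) {
      return("intensity law means and sds must be >= 0")
    }
  }
  bm <- object@biomarker
  if (length(bm)) {
    if (bm$posFraction < 0 || bm$posFraction > 1) {
      return("biomarker posFraction must lie in [0, 1]")
    }
  }
  TRUE
})

setMethod("show", "PhenotypeSpec", function(object) {
  cat(sprintf("PhenotypeSpec '%s'\n", object@label))
  for (role in names(object@channels)) {
    law <- object@channels[[role]]
    cat(sprintf("  %-9s %s(mean = %g, sd = %g)\n", role, law$dist,
                law$mean, law$sd))
  }
  if (length(object@biomarker)) {
    bm <- object@biomarker
    cat(sprintf("  biomarker: %.0f%% positive, pos N(%g, %g), neg N(%g, %g)\n",
                100 * bm$posFraction, bm$posMean, bm$posSd, bm$negMean,
                bm$negSd))
  }
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## GatingConfig
## ---------------------------------------------------------------------------

#' GatingConfig: per-channel positivity cutoffs and rule-set version
#'
#' Cutoffs are intensities on the background-subtracted scale. The
#' phenotype rule set is exclusion-first: an exclusion-positive cell is
#' EXCLUDED regardless of tumor-marker staining, and a cell negative for
#' CAXII, CK and exclusion is TRIPLE_NEG and never counted as a CTC.
#'
#' @slot cutoffs Named numeric vector of finite cutoffs, names are channel
#'   roles.
#' @slot method Character tag recording how cutoffs were derived
#'   (e.g. "cluster", "manual").
#' @slot rulesVersion Version tag of the phenotype rule set.
#' @export
setClass("GatingConfig",
  representation(cutoffs = "numeric", method = "character",
                 rulesVersion = "character"),
  prototype(method = "cluster", rulesVersion = "exclusion-first-1")
)

setValidity("GatingConfig", function(object) {
  if (length(object@cutoffs) == 0L) return("at least one cutoff is required")
  if (is.null(names(object@cutoffs))) return("cutoffs must be named by role")
  if (!all(names(object@cutoffs) %in% channelRoles())) {
    return("cutoff names must be channel roles")
  }
  if (!all(is.finite(object@cutoffs))) return("cutoffs must be finite")
  TRUE
})

#' Construct a GatingConfig
#'
#' @param cutoffs Named numeric vector of per-role positivity cutoffs
#'   (background-subtracted intensity units).
#' @param method Tag recording the cutoff derivation method.
#' @param rulesVersion Phenotype rule-set version tag.
#' @return A [GatingConfig-class] object.
#' @examples
#' GatingConfig(c(EXCLUSION = 50, CAXII = 40, CK = 45))
#' @export
GatingConfig <- function(cutoffs, method = "manual",
                         rulesVersion = "exclusion-first-1") {
  new("GatingConfig", cutoffs = cutoffs, method = method,
      rulesVersion = rulesVersion)
}

#' @describeIn GatingConfig Named cutoff vector.
#' @param x A `GatingConfig`.
#' @export
gatingCutoffs <- function(x) {
  stopifnot(is(x, "GatingConfig"))
  x@cutoffs
}

setMethod("show", "GatingConfig", function(object) {
  cat(sprintf("GatingConfig (method: %s, rules: %s)\n", object@method,
              object@rulesVersion))
  for (role in names(object@cutoffs)) {
    cat(sprintf("  %-9s cutoff %.4g\n", role, object@cutoffs[[role]]))
  }
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## ROCResult
## ---------------------------------------------------------------------------

#' ROCResult: ROC curve, AUC and likelihood-ratio-optimal cutoff
#'
#' The curve is evaluated at cutoffs placed midway between consecutive
#' distinct scores (plus infinite sentinels), so a reported cutoff falls
#' between observed sample values, as a prospective decision threshold
#' would. AUC equals the Mann-Whitney U statistic divided by
#' `nPositive * nNegative` (ties counted 1/2), and the p-value tests
#' AUC = 0.5 via the tie-corrected normal approximation of U.
#'
#' @slot curve data.frame with columns cutoff, sensitivity, specificity,
#'   ordered by increasing cutoff (sensitivity non-increasing).
#' @slot auc Area under the curve, in \[0, 1\].
#' @slot pvalue Two-sided p-value against AUC = 0.5.
#' @slot nPositive,nNegative Class sizes (positive = progressing).
#' @slot optimum List: cutoff, sensitivity, specificity, lr,
#'   perfectSpecificity flag (TRUE when the winning cutoff has
#'   specificity 1 and hence infinite positive likelihood ratio).
#' @export
setClass("ROCResult",
  representation(curve = "data.frame", auc = "numeric", pvalue = "numeric",
                 nPositive = "integer", nNegative = "integer",
                 optimum = "list")
)

setValidity("ROCResult", function(object) {
  cv <- object@curve
  need <- c("cutoff", "sensitivity", "specificity")
  if (!all(need %in% names(cv))) {
    return("curve needs cutoff, sensitivity, specificity columns")
  }
  if (any(cv$sensitivity < 0 | cv$sensitivity > 1) ||
      any(cv$specificity < 0 | cv$specificity > 1)) {
    return("sensitivity and specificity must lie in [0, 1]")
  }
  if (is.unsorted(cv$cutoff)) return("curve must be ordered by cutoff")
  if (any(diff(cv$sensitivity) > 1e-12)) {
    return("sensitivity must be non-increasing in the cutoff")
  }
  if (object@auc < 0 || object@auc > 1) return("AUC must lie in [0, 1]")
  TRUE
})

#' @describeIn ROCResult Area under the curve.
#' @param x A `ROCResult`.
#' @export
auc <- function(x) {
  stopifnot(is(x, "ROCResult"))
  x@auc
}

#' @describeIn ROCResult The ROC curve as a data.frame.
#' @export
rocPoints <- function(x) {
  stopifnot(is(x, "ROCResult"))
  x@curve
}

setMethod("show", "ROCResult", function(object) {
  cat(sprintf("ROCResult: %d progressing vs %d responding samples\n",
              object@nPositive, object@nNegative))
  cat(sprintf("  AUC = %.3f (p = %.4g vs chance)\n", object@auc,
              object@pvalue))
  opt <- object@optimum
  lr <- if (isTRUE(opt$perfectSpecificity)) "Inf (perfect specificity)"
        else sprintf("%.2f", opt$lr)
  cat(sprintf("  optimal cutoff %.3g: sensitivity %.0f%%, specificity %.0f%%, LR %s\n",
              opt$cutoff, 100 * opt$sensitivity, 100 * opt$specificity, lr))
  invisible(NULL)
})
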