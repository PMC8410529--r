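---
title: "Methods: multiplexed CTC immunofluorescence analytics"
author: "ctcQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiplexed CTC immunofluorescence analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcQuant)
```

## The assay and its analysis model

Circulating tumor cells (CTCs) in clear cell renal cell carcinoma often
lack the epithelial markers (EpCAM, cytokeratin) that classical CTC
assays depend on, so the panel analysed here identifies CTCs with the
renal marker CAXII alongside pan-cytokeratin (CK), rejects leukocytes
and endothelial cells with a pooled exclusion channel (CD34/CD45/CD66b
on a single dye), anchors every cell on a nuclear stain, and scores one
immune biomarker per slide (PD-L1 or HLA-I, never both on the same
cell). The pipeline turns a registered multichannel field into:

1. a per-cell measurement table (image stage),
2. phenotype calls under an exclusion-first rule set (gating),
3. per-subpopulation biomarker summaries and per-mL densities,
4. cohort-level statistics (group tests, ROC, longitudinal reports).

A cell is a CTC if and only if it has an intact nucleus, is
exclusion-negative, and is CAXII-positive or CK-positive. Exclusion
positivity dominates everything else (specificity first: a
CAXII+/CK+/exclusion+ cell is EXCLUDED), and exclusion-negative cells
that are negative for both CAXII and CK are TRIPLE_NEG and never
counted. The three CTC phenotypes are CAXII single-positive (CAXII S+),
CAXII/CK double-positive (DP), and CK single-positive (CK S+); analyses
additionally pool CK+ = CK S+ ∪ DP, the cytokeratin-expressing fraction
used for the clinical cutoff analyses.

## Image stage

**Background subtraction.** `rollingBallSubtract()` estimates the smooth
background as the morphological grey-opening of the image with a disc of
radius 50 px (configurable; the radius only needs to exceed the cell
diameter) and subtracts it, clipping at zero. Opening is a min-then-max
filter, so the operation is exactly invariant to adding a constant to
the whole image — a property the tests assert. The underlying morphology
comes from EBImage; because its grey-scale kernels clamp to [0, 1], the
image is affinely normalised before the opening and mapped back, which
is exact for rank filters.

**Segmentation.** The cell boundary is defined on the
background-subtracted nuclear channel by a binary threshold (Otsu by
default; fixed-value and quantile alternatives in
`segmentationConfig()`). The thresholded mask is smoothed by a binary
opening of radius 2 px before connected-component labelling: without it,
pixel noise at the nuclear boundary grows ragged stragglers that inflate
the measurement regions and bias quantification. Objects are filtered to
a nuclear area of [50, 2000] px (discards are logged, not silently
dropped). "Intact nucleus" is operationalised as this area window plus
solidity ≥ 0.8 (area over convex-hull area) — an automatable proxy for
the manual review an analyst would otherwise perform; low-solidity and
border-touching objects are kept but QC-flagged and excluded from
enumeration by default.

**Measurement regions.** The assay's markers (CAXII, CK, PD-L1, HLA-I)
are membrane/cytoplasmic, while segmentation is nuclear, so each cell is
quantified over its nuclear mask dilated by `ringWidth` = 4 px. Pixels
claimed by two cells' dilations are assigned to the nearer centroid, so
measurement regions partition the field — every pixel belongs to at most
one region (asserted against a nearest-centroid oracle).

**Quantification.** `estimateBackground()` averages each channel over
the pixels outside all measurement regions dilated by a guard band
(8 px), flagging the estimate unreliable below 1% of field pixels; this
captures slide-to-slide washing variability. `measureCells()` reports,
per cell and channel, the raw region mean and the background-subtracted
mean (raw − estimate). Subtracted means are deliberately **not** clipped
at zero: cutoff fitting needs the negative tail of the truly-negative
population.

## Gating

**Cutoffs.** Flow-style manual gating is replaced by a deterministic
analogue: the sorted background-subtracted intensities are split into
two clusters minimising the total within-cluster sum of squares (every
split point is evaluated via prefix sums, so the optimum is exact, and
it matches a naive exhaustive oracle in the tests), and the cutoff is
the midpoint of the two cluster means. The best split of even a single
Gaussian separates its two halves by ≈ 2.65 pooled within-cluster SDs,
so a separation below 3 (default `separationThreshold`) is read as
unimodality and the fallback cutoff mean + 3 SD is returned — the
sample is then treated as one negative population. The cutoff is
translation-equivariant. Cutoffs are fitted per sample by default
(washing efficiency varies between slides); pooling tables before
`fitGatingConfig()` gives a cohort-global config, and the choice is
recorded in the config's method tag. Whether the original assay fitted
per sample or per cohort is not documented; per-sample is the default
here because the background-subtraction rationale is itself per-sample.

**Scoring.** `scoreBiomarker()` reports, per subpopulation (ALL_CTC,
CAXII S+, DP, CK S+, CK+), the number of countable CTCs, the percentage
above the biomarker cutoff, and the mean background-subtracted
expression. The mean is reported independently of the cutoff, and empty
subpopulations are reported missing (NA), never as zero — a sample
without CTCs is a valid observation, not a zero-expression one.
"Average expression" is taken as the arithmetic mean (the natural
reading; a median variant would be a one-line change).
`compositionTable()` tabulates marker co-expression combinations among
exclusion-negative cells (the numbers behind an Euler diagram) plus
per-marker marginals within the CK+ and CK− strata.

## Cohort statistics

**Group tests.** `compareGroups()` wraps the Mann–Whitney and Welch t
tests. The rank-sum p-value is exact (permutation distribution) for
combined n ≤ 12 without ties and the tie-corrected normal approximation
otherwise; the exact path is verified against full permutation
enumeration in the tests. Sidedness is a flag with a two-sided default —
enumeration comparisons in this field are sometimes reported one-tailed,
so the alternative is always explicit in the output.

**ROC.** Candidate cutoffs are midpoints between consecutive distinct
scores plus ±∞ sentinels, so a reported optimal cutoff falls *between*
observed sample densities, as a prospective decision threshold would.
The trapezoidal AUC then equals the Mann–Whitney U/(n₁n₂) identity
exactly, ties included (asserted on 1000 random instances against an
independently computed U). The p-value tests AUC = 0.5 through the
tie-corrected normal approximation of U.

**Optimal cutoff.** The operating point maximises the positive
likelihood ratio LR = sensitivity/(1 − specificity). A cutoff with
specificity 1 and sensitivity > 0 has LR = +∞ and wins whenever present;
rather than silently excluding this degenerate case, the result carries
a `perfectSpecificity` flag, and `requireFinite = TRUE` restricts the
search to specificity < 1 — the operating point a clinical report would
print. Ties break toward higher sensitivity, then the lower cutoff.
Note that printed clinical LR values derive from unrounded
sensitivity/specificity fractions, so an LR recomputed from rounded
percentages will differ in the first decimal; nothing in this package
hard-codes such a value.

**Longitudinal reports.** `longitudinalReport()` scans one phenotype's
density trajectory against a fixed cutoff and emits a crossing event
per sign change, with a value exactly at the cutoff treated as below it
(so at-cutoff → above counts as one upward crossing).

## The synthetic-data generator

The generator defines the conditions under which the pipeline is
validated; its defaults are fixed, not tuned.

* **Cells** are rendered as uniform-intensity disks with a Gaussian-CDF
  edge (softness 0.75 px) — the simplest shape that exercises
  segmentation and ring quantification. Nuclear radius is uniform on
  8–12 px (conventional for a 10× acquisition); marker/exclusion/
  biomarker signal extends over the cell body, `cellMargin` = 8 px
  beyond the nucleus. The margin must exceed the ring width (4 px) plus
  the segmentation's boundary uncertainty (≈ 2 px) plus the edge
  softness, so that the nucleus-anchored measurement ring samples the
  marker plateau; this geometric consistency is what makes unbiased
  recovery a fair requirement on the pipeline.
* **Intensity laws** are log-normal per channel (fluorescence is
  non-negative and right-skewed), parametrised by arithmetic mean/SD:
  strong signal 500 ± 100 on expressed markers, weak normal non-specific
  staining 20 ± 10 otherwise, nuclear 800 ± 120 in every cell. The
  biomarker is a two-component normal mixture (negative 30 ± 20,
  positive 400 ± 80) whose component separation is a named parameter so
  cutoff-recovery tests can sweep it. Default positive fractions follow
  the subpopulation heterogeneity pattern of a representative patient:
  84% (CK S+), 50% (DP — the bimodal population), 33% (CAXII S+).
* **Fields** add a linear left-to-right background ramp plus i.i.d.
  Gaussian noise, left unclipped (floating-point detector convention):
  clipping at zero would bias the background mean upward by an amount
  growing with noise/background, which is a property of a detector, not
  of the assay. Placement enforces a minimum centre separation with
  bounded retries; an infeasible density is an explicit error.
* **Cohorts** draw each sample's true density from its response group's
  log-normal law and the observed count as Poisson(density × volume).
  Group density means are anchored to the published clinical scale —
  19.8 CTCs/mL near radiographic progression versus 2.3 CTCs/mL under
  response, 11 vs 9 samples. The log-scale SDs (1.2 and 1.0) are chosen
  once so that the implied per-sample ranges match the published ranges
  (≈ 0.5–163 and ≈ 0.1–6.5 CTCs/mL respectively); per-sample raw counts
  were never published, so these are scale-anchored, not fitted.
  Phenotype mixing (40/30/30 CAXII S+/DP/CK S+) and the 2 mL default
  blood volume are conventional choices in the realistic range for
  rare-cell assays. Hidden truth columns carry the `truth_` prefix and
  are stripped by the table writers unless explicitly requested.

**What the generator does not emulate:** optics (no PSF), cell doublets
and debris, overlapping cells, autofocus or registration errors,
spatially correlated noise, and biological correlation between marker
intensity and biomarker state within a cell. Passing tests therefore
demonstrate correctness of the measurement and statistical machinery
under the stated model — not robustness to every real-microscopy
artifact, which is what the QC flags and configurable thresholds are
for.

## Validation design and problem sizes

The test suite checks each stage against an independent oracle: a naive
min/max-filter opening for the rolling ball, a nearest-centroid
partition for measurement regions, exhaustive split search for the
cutoff, full permutation enumeration for the exact Mann–Whitney p, an
independently computed U (and pROC) for the AUC, and exhaustive cutoff
search for the LR optimum. End-to-end recovery runs on 20 seeded
512 × 512 fields of 10 non-overlapping cells at signal-to-noise 5
(recall/precision ≥ 0.95; ≥ 99% of per-cell background-subtracted means
within 3 noise standard errors of truth — the 3-SE band's nominal
coverage is 99.7%, so a fraction is asserted rather than every single
cell), 200 seeded cohorts at the clinical density scales (one-sided
Mann–Whitney p < 0.05 in ≥ 80% of seeds, median AUC ≥ 0.75), and 200
bimodal mixtures 4 SDs apart for cutoff recovery. These sizes keep the
full suite under a minute of compute while leaving the stochastic bands
comfortable margins.

## Known limitations

* Segmentation is single-channel and threshold-based; touching nuclei
  are not split (the generator's minimum-separation default sidesteps
  this; real crowded fields would need a watershed).
* One exclusion cutoff for the pooled exclusion dye; marker-specific
  exclusion is out of scope by panel design.
* The LR-optimal cutoff is a point estimate; no confidence interval is
  reported for it (none is defined in the source analysis), only the
  ROC-level p-value against chance.
* PD-L1/HLA-I co-expression on the same cell is out of scope: the panel
  carries one biomarker channel per slide.
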