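# Sample enumeration, group tests, ROC/likelihood-ratio cutoff selection
# and longitudinal crossing detection.

mkCalls <- function(labels, countable = TRUE) {
  data.frame(label = factor(labels, levels = allLabels()),
             countable = countable & labels %in% ctcLabels())
}

test_that("enumeration divides countable counts by volume and is additive", {
  calls <- mkCalls(rep("CK_S", 10))
  expect_equal(enumerateSample(calls, volume = 2)$density_ALL_CTC, 5)
  # zero CTCs is a valid sample (healthy-donor case), not an error
  none <- enumerateSample(mkCalls(c("EXCLUDED", "TRIPLE_NEG")), volume = 2)
  expect_equal(none$density_ALL_CTC, 0)
  mix <- enumerateSample(mkCalls(c(rep("CAXII_S", 4), rep("CK_S", 6))),
                         volume = 2)
  expect_equal(mix$density_ALL_CTC, 5)
  expect_equal(mix$density_CAXII_S, 2)
  expect_equal(mix$density_CK_S, 3)
  expect_equal(mix$density_ALL_CTC,
               mix$density_CAXII_S + mix$density_DP + mix$density_CK_S)
  # QC-flagged and excluded cells never contribute
  flagged <- mkCalls(rep("CK_S", 4), countable = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(enumerateSample(flagged, volume = 1)$n_ALL_CTC, 2)
  expect_error(enumerateSample(calls, volume = 0), "> 0")
})

test_that("group comparison matches exact enumeration on small samples", {
  expect_gte(compareGroups(c(1, 2, 3), c(1, 2, 3))$p.value, 0.99)
  g <- compareGroups(c(1, 2, 3), c(10, 20, 30), alternative = "less")
  expect_equal(g$statistic, 0)
  expect_equal(g$p.value, 1 / choose(6, 3))
  expect_error(compareGroups(numeric(0), 1:3), "non-empty")
  expect_error(compareGroups(1, 1:3, test = "t"), "at least 2")
})

test_that("exact Mann-Whitney p equals brute-force permutation enumeration", {
  set.seed(21)
  for (i in 1:40) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    a <- round(runif(n1, 0, 50), 3)
    b <- round(runif(n2, 0, 50) + runif(1, -5, 5), 3)
    if (anyDuplicated(c(a, b))) next
    for (alt in c("two.sided", "less", "greater")) {
      expect_equal(compareGroups(a, b, alternative = alt)$p.value,
                   oracleMWp(a, b, alt), tolerance = 1e-12)
    }
  }
})

test_that("ROC handles separation, chance and the U-statistic identity", {
  r <- rocCurve(c(5, 6, 7, 1, 2, 3),
                rep(c("progressing", "responding"), each = 3))
  expect_equal(auc(r), 1)
  # curve is monotone: sensitivity non-increasing in the cutoff
  expect_true(all(diff(rocPoints(r)$sensitivity) <= 0))
  expect_error(rocCurve(1:5, rep("responding", 5)), "must be present")

  # permuted labels: mean AUC ~ 0.5
  set.seed(5)
  scores <- rlnorm(20, 1, 1)
  aucs <- vapply(1:1000, function(i) {
    auc(rocCurve(scores, sample(rep(c("progressing", "responding"),
                                    c(11, 9)))))
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)

  # AUC = U / (n1 n2), U computed independently (ties included)
  set.seed(31)
  for (i in 1:50) {
    n1 <- sample(3:25, 1); n2 <- sample(3:25, 1)
    sc <- c(rnorm(n1, 1), rnorm(n2))
    if (runif(1) < 0.5) sc <- round(sc)  # induce ties half the time
    lab <- rep(c("progressing", "responding"), c(n1, n2))
    U <- suppressWarnings(
      wilcox.test(sc[lab == "progressing"],
                  sc[lab == "responding"])$statistic)
    expect_equal(auc(rocCurve(sc, lab)), unname(U) / (n1 * n2),
                 tolerance = 1e-12)
  }
})

test_that("ROC AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  sc <- c(rnorm(12, 1.2), rnorm(10))
  lab <- rep(c("progressing", "responding"), c(12, 10))
  ref <- as.numeric(pROC::auc(pROC::roc(response = lab, predictor = sc,
                                        levels = c("responding",
                                                   "progressing"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(auc(rocCurve(sc, lab)), ref, tolerance = 1e-12)
})

test_that("likelihood-ratio cutoff selection obeys the stated rules", {
  # perfect separation: perfect-specificity rule with flagged infinite LR
  r <- rocCurve(c(5, 6, 7, 1, 2, 3),
                rep(c("progressing", "responding"), each = 3))
  opt <- optimalCutoff(r)
  expect_true(opt$perfectSpecificity)
  expect_gt(opt$cutoff, 3); expect_lt(opt$cutoff, 5)
  expect_equal(opt$sensitivity, 1)
  # LR formula: sensitivity 0.55, specificity 0.89 gives LR 5.0
  expect_equal(0.55 / (1 - 0.89), 5, tolerance = 1e-9)
  curve <- data.frame(cutoff = c(1, 2), sensitivity = c(0.8, 0.55),
                      specificity = c(0.6, 0.89))
  opt2 <- optimalCutoff(curve)
  expect_equal(opt2$lr, 0.55 / (1 - 0.89), tolerance = 1e-9)
  expect_equal(opt2$cutoff, 2)
  expect_error(optimalCutoff(data.frame(cutoff = 1, sensitivity = 0,
                                        specificity = 1)),
               "sensitivity > 0")
  # requireFinite skips the perfect-specificity extremum
  curve3 <- data.frame(cutoff = c(1, 2), sensitivity = c(0.9, 0.3),
                       specificity = c(0.8, 1))
  expect_true(optimalCutoff(curve3)$perfectSpecificity)
  optF <- optimalCutoff(curve3, requireFinite = TRUE)
  expect_false(optF$perfectSpecificity)
  expect_equal(optF$lr, 0.9 / 0.2, tolerance = 1e-12)
})

test_that("optimal cutoff equals exhaustive search on random instances", {
  set.seed(77)
  for (i in 1:100) {
    n1 <- sample(3:25, 1); n2 <- sample(3:25, 1)
    sc <- c(rnorm(n1, runif(1, 0, 2)), rnorm(n2))
    if (runif(1) < 0.3) sc <- round(sc, 1)
    lab <- rep(c("progressing", "responding"), c(n1, n2))
    opt <- optimalCutoff(rocCurve(sc, lab))
    ora <- oracleOptimalCutoff(sc, lab == "progressing")
    expect_equal(opt$cutoff, ora$cutoff)
    expect_equal(opt$lr, ora$lr)
  }
})

test_that("densities, tests and cutoff classification are volume-scale equivariant", {
  coh <- simulateCohort(nProgressing = 8, nResponding = 8, seed = 13)
  for (cmul in c(2, 5)) {
    dens2 <- coh$n_ALL_CTC / (coh$volume * cmul)
    expect_equal(dens2, coh$density_ALL_CTC / cmul)
    r1 <- rocCurve(coh$density_ALL_CTC, coh$group)
    r2 <- rocCurve(dens2, coh$group)
    expect_equal(auc(r2), auc(r1))
    expect_equal(r2@pvalue, r1@pvalue)
    expect_equal(optimalCutoff(r2)$cutoff, optimalCutoff(r1)$cutoff / cmul)
    split1 <- coh$density_ALL_CTC > optimalCutoff(r1)$cutoff
    split2 <- dens2 > optimalCutoff(r1)$cutoff / cmul
    expect_equal(split1, split2)
  }
})

test_that("longitudinal crossings are detected with the at-cutoff-is-below rule", {
  up <- longitudinalReport(data.frame(week = c(5, 11),
                                      density_CK_PLUS = c(0.4, 5.6)), 2.6)
  expect_equal(nrow(up$events), 1)
  expect_equal(up$events$direction, "up")
  expect_equal(up$events$week, 11)
  flat <- longitudinalReport(data.frame(week = 0:3,
                                        density_CK_PLUS = rep(1, 4)), 2.6)
  expect_equal(nrow(flat$events), 0)
  # exactly at the cutoff counts as below, so at-cutoff -> above is one up
  tie <- longitudinalReport(data.frame(week = c(0, 4),
                                       density_CK_PLUS = c(2.6, 3.0)), 2.6)
  expect_equal(nrow(tie$events), 1)
  expect_equal(tie$events$direction, "up")
  expect_error(longitudinalReport(data.frame(week = c(4, 0),
                                             density_CK_PLUS = c(1, 2)),
                                  2.6),
               "strictly increasing")
})
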