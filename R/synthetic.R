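## Ground-truthed synthetic data: imaging fields, per-cell tables, cohorts
## and longitudinal series with the statistical structure the analysis
## assumes, so every downstream stage is testable without patient data.

#' Construct a PhenotypeSpec
#'
#' @param label Phenotype label (CAXII_S, DP, CK_S, WBC or TRIPLE_NEG).
#' @param channels Named list of per-role signal laws
#'   `list(dist, mean, sd)`; mean is signal added above background.
#' @param biomarker List `posFraction`, `posMean`, `posSd`, `negMean`,
#'   `negSd` describing the bimodal biomarker mixture; may be empty.
#' @return A [PhenotypeSpec-class].
#' @export
phenotypeSpec <- function(label, channels, biomarker = list()) {
  new("PhenotypeSpec", label = label, channels = channels,
      biomarker = biomarker)
}

law <- function(mean, sd, dist = "lnorm") list(dist = dist, mean = mean, sd = sd)

#' Default phenotype panel for the simulator
#'
#' Returns the five phenotypes the assay distinguishes, with well-separated
#' default intensity laws: every phenotype is nuclear-positive; marker
#' channels carry a strong log-normal signal when the phenotype expresses
#' the marker and weak normal non-specific staining otherwise; white blood
#' cells (WBC) are the only exclusion-positive phenotype; TRIPLE_NEG cells
#' have CAXII, CK and exclusion at background level. Default biomarker
#' positive fractions follow the heterogeneity pattern seen across CTC
#' subpopulations in a representative patient: CK single-positives mostly
#' biomarker-positive (84%), double-positives split 50/50 into a positive
#' and a negative population, CAXII single-positives mostly negative (33%).
#'
#' @param signalMean,signalSd Arithmetic mean/SD of the log-normal signal
#'   on marker-positive channels (arbitrary fluorescence units).
#' @param negMean,negSd Mean/SD of the weak normal non-specific signal on
#'   marker-negative channels.
#' @param nuclearMean,nuclearSd Nuclear stain law (positive in all cells).
#' @param biomarkerPos,biomarkerNeg Length-2 vectors c(mean, sd) for the
#'   positive and negative biomarker mixture components; their separation
#'   controls how bimodal the biomarker distribution is.
#' @param posFractions Named vector of biomarker positive fractions per
#'   phenotype.
#' @return Named list of [PhenotypeSpec-class] objects.
#' @examples
#' names(ctcPhenotypes())
#' @export
ctcPhenotypes <- function(signalMean = 500, signalSd = 100,
                          negMean = 20, negSd = 10,
                          nuclearMean = 800, nuclearSd = 120,
                          biomarkerPos = c(mean = 400, sd = 80),
                          biomarkerNeg = c(mean = 30, sd = 20),
                          posFractions = c(CAXII_S = 0.33, DP = 0.50,
                                           CK_S = 0.84, WBC = 0,
                                           TRIPLE_NEG = 0)) {
  pos <- law(signalMean, signalSd, "lnorm")
  neg <- law(negMean, negSd, "norm")
  nuc <- law(nuclearMean, nuclearSd, "lnorm")
  bm <- function(p) list(posFraction = unname(p),
                         posMean = unname(biomarkerPos["mean"]),
                         posSd = unname(biomarkerPos["sd"]),
                         negMean = unname(biomarkerNeg["mean"]),
                         negSd = unname(biomarkerNeg["sd"]))
  mk <- function(lab, caxii, ck, excl) {
    phenotypeSpec(lab,
      channels = list(NUCLEAR = nuc,
                      CAXII = if (caxii) pos else neg,
                      CK = if (ck) pos else neg,
                      EXCLUSION = if (excl) pos else neg),
      biomarker = bm(posFractions[[lab]]))
  }
  list(CAXII_S = mk("CAXII_S", TRUE, FALSE, FALSE),
       DP = mk("DP", TRUE, TRUE, FALSE),
       CK_S = mk("CK_S", FALSE, TRUE, FALSE),
       WBC = mk("WBC", FALSE, FALSE, TRUE),
       TRIPLE_NEG = mk("TRIPLE_NEG", FALSE, FALSE, FALSE))
}

## draw n values from a signal law; negative draws from normal laws are
## clipped at 0 (intensities are non-negative)
drawLaw <- function(n, law) {
  if (law$mean <= 0) return(rep(0, n))
  if (identical(law$dist, "lnorm")) {
    sdlog <- sqrt(log(1 + (law$sd / law$mean)^2))
    meanlog <- log(law$mean) - sdlog^2 / 2
    stats::rlnorm(n, meanlog, sdlog)
  } else {
    pmax(stats::rnorm(n, law$mean, law$sd), 0)
  }
}

drawBiomarker <- function(n, bm) {
  if (!length(bm)) {
    return(data.frame(value = rep(0, n), positive = rep(FALSE, n)))
  }
  positive <- stats::runif(n) < bm$posFraction
  value <- ifelse(positive,
                  stats::rnorm(n, bm$posMean, bm$posSd),
                  stats::rnorm(n, bm$negMean, bm$negSd))
  data.frame(value = pmax(value, 0), positive = positive)
}

resolveMix <- function(counts, phenotypes) {
  if (length(counts) == 0L) stop("phenotype mix is empty")
  if (is.null(names(counts))) stop("phenotype mix must be named by label")
  missing <- setdiff(names(counts), names(phenotypes))
  if (length(missing)) {
    stop(sprintf("no PhenotypeSpec for: %s", paste(missing, collapse = ", ")))
  }
  counts
}

#' Simulate one multichannel imaging field with ground truth
#'
#' Renders each cell as a uniform-intensity disk with a smooth (Gaussian
#' CDF) edge on every channel, on top of a linear background gradient plus
#' i.i.d. Gaussian noise. The nuclear disk has radius `radius`; marker,
#' exclusion and biomarker signal extends over the larger cell body
#' (radius + `cellMargin`), mimicking membrane/cytoplasmic staining around
#' the nucleus, so that a nucleus-anchored measurement ring samples the
#' marker plateau. Placement enforces a minimum centre separation; if the
#' requested density cannot be placed within bounded retries an error
#' reports the density.
#'
#' @param counts Named integer vector: cells per phenotype label.
#' @param phenotypes Named list of [PhenotypeSpec-class] (defaults to
#'   [ctcPhenotypes()]).
#' @param fieldShape Field dimensions c(rows, cols) in pixels.
#' @param background c(level, gradient): baseline intensity plus a linear
#'   left-to-right ramp spanning `gradient` intensity units.
#' @param noiseSd SD of the additive Gaussian pixel noise.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param radiusRange Nuclear radius range in pixels (uniform draw).
#' @param cellMargin Extra cell-body radius beyond the nucleus, pixels.
#'   Must exceed the measurement ring width plus the segmentation's
#'   boundary uncertainty and the edge softness, so that a
#'   nucleus-anchored measurement ring samples the marker plateau.
#' @param edgeSd Gaussian edge softness of the rendered disks, pixels.
#' @param minSeparation Minimum centre-to-centre distance; `NULL` =
#'   non-overlapping cell bodies (2 * (max radius + cellMargin) + 2).
#' @param maxPlacementTries Rejection-sampling budget per field.
#' @return List with `stack` ([ChannelStack-class]) and `truth`
#'   (data.frame: cell_id, label, row, col, radius, true_<ROLE> plateau
#'   signal per channel, truth_biomarker_pos).
#' @examples
#' fld <- simulateField(c(CAXII_S = 3, WBC = 2), fieldShape = c(256, 256),
#'                      seed = 1)
#' fld$truth$label
#' @export
simulateField <- function(counts, phenotypes = ctcPhenotypes(),
                          fieldShape = c(1024, 1024),
                          background = c(level = 100, gradient = 0),
                          noiseSd = 20, seed,
                          radiusRange = c(8, 12), cellMargin = 8,
                          edgeSd = 0.75, minSeparation = NULL,
                          maxPlacementTries = 5000) {
  if (missing(seed)) stop("a seed is required")
  counts <- resolveMix(counts, phenotypes)
  nCells <- sum(counts)
  rMax <- max(radiusRange)
  if (is.null(minSeparation)) minSeparation <- 2 * (rMax + cellMargin) + 2
  pad <- rMax + cellMargin + ceiling(3 * edgeSd) + 1
  if (any(fieldShape <= 2 * pad)) {
    stop("field too small to place cells without clipping")
  }
  withr::with_seed(seed, {
    labels <- rep(names(counts), times = counts)
    radius <- stats::runif(nCells, radiusRange[1], radiusRange[2])
    ## rejection-sample centres under the min-separation constraint
    rows <- cols <- numeric(nCells)
    placed <- 0L
    tries <- 0L
    while (placed < nCells) {
      if (tries >= maxPlacementTries) {
        stop(sprintf(
          "could not place %d cells in a %dx%d field at min separation %.1f px (density %.2g cells/px^2): reduce the density or the separation",
          nCells, fieldShape[1], fieldShape[2], minSeparation,
          nCells / prod(fieldShape)))
      }
      tries <- tries + 1L
      r0 <- stats::runif(1, pad, fieldShape[1] - pad)
      c0 <- stats::runif(1, pad, fieldShape[2] - pad)
      if (placed > 0L) {
        d2 <- (rows[seq_len(placed)] - r0)^2 + (cols[seq_len(placed)] - c0)^2
        if (min(d2) < minSeparation^2) next
      }
      placed <- placed + 1L
      rows[placed] <- r0
      cols[placed] <- c0
    }

    roles <- channelRoles()
    ## per-cell plateau signal per channel
    plateau <- matrix(0, nCells, length(roles), dimnames = list(NULL, roles))
    bmPos <- logical(nCells)
    for (lab in unique(labels)) {
      idx <- which(labels == lab)
      ph <- phenotypes[[lab]]
      for (role in setdiff(roles, "BIOMARKER")) {
        plateau[idx, role] <- drawLaw(length(idx), ph@channels[[role]])
      }
      bmDraw <- drawBiomarker(length(idx), ph@biomarker)
      plateau[idx, "BIOMARKER"] <- bmDraw$value
      bmPos[idx] <- bmDraw$positive
    }

    chans <- vector("list", length(roles))
    names(chans) <- roles
    gradRamp <- matrix(rep(seq(0, 1, length.out = fieldShape[2]),
                           each = fieldShape[1]),
                       fieldShape[1], fieldShape[2])
    bgField <- background[[1]] + background[[2]] * gradRamp
    for (role in roles) {
      img <- bgField
      for (i in seq_len(nCells)) {
        rSig <- if (role == "NUCLEAR") radius[i] else radius[i] + cellMargin
        ext <- ceiling(rSig + 3 * edgeSd)
        rr <- max(1, floor(rows[i] - ext)):min(fieldShape[1], ceiling(rows[i] + ext))
        cc <- max(1, floor(cols[i] - ext)):min(fieldShape[2], ceiling(cols[i] + ext))
        d <- sqrt(outer((rr - rows[i])^2, (cc - cols[i])^2, "+"))
        img[rr, cc] <- img[rr, cc] +
          plateau[i, role] * stats::pnorm((rSig - d) / edgeSd)
      }
      if (noiseSd > 0) {
        ## noise is left unclipped (floating-point detector convention):
        ## clipping at 0 would bias the background mean upward by an
        ## amount that grows with noiseSd / background level
        img <- img + matrix(stats::rnorm(length(img), 0, noiseSd),
                            nrow(img), ncol(img))
      }
      chans[[role]] <- img
    }

    truth <- data.frame(cell_id = seq_len(nCells), label = labels,
                        row = rows, col = cols, radius = radius,
                        stringsAsFactors = FALSE)
    for (role in roles) truth[[paste0("true_", role)]] <- plateau[, role]
    truth$truth_biomarker_pos <- bmPos
    list(stack = ChannelStack(chans,
                              metadata = list(background = background,
                                              noiseSd = noiseSd, seed = seed)),
         truth = truth)
  })
}

cellTableSchema <- function() {
  c("cell_id", "row", "col", "area", "solidity",
    paste0("raw_", channelRoles()), paste0("bgsub_", channelRoles()),
    "flag_saturated", "flag_border", "flag_size", "flag_solidity", "qc_pass")
}

#' Simulate a per-cell measurement table with hidden truth labels
#'
#' Tabular shortcut that bypasses imaging: per-cell background-subtracted
#' intensities are drawn directly from each phenotype's signal laws into
#' the same column schema that [measureCells()] produces. Ground-truth
#' columns carry the `truth_` prefix; [stripTruth()] (applied by the table
#' writers by default) removes them from anything the analysis consumes.
#'
#' @param mix Named numeric vector of phenotype mixing weights (need not
#'   sum to 1).
#' @param nCells Total number of cells to draw (>= 0).
#' @param phenotypes Named list of [PhenotypeSpec-class].
#' @param backgroundLevel Raw-scale background added to form raw_* columns.
#' @param seed Integer seed.
#' @return data.frame in the CellTable schema plus truth_label and
#'   truth_biomarker_pos.
#' @examples
#' tab <- simulateCellTable(c(DP = 1), nCells = 5, seed = 1)
#' tab$truth_label
#' @export
simulateCellTable <- function(mix, nCells, phenotypes = ctcPhenotypes(),
                              backgroundLevel = 100, seed) {
  if (missing(seed)) stop("a seed is required")
  if (nCells < 0) stop("nCells must be >= 0")
  if (nCells > 0) mix <- resolveMix(mix, phenotypes)
  roles <- channelRoles()
  withr::with_seed(seed, {
    if (nCells == 0L) {
      tab <- as.data.frame(matrix(numeric(0), 0, length(cellTableSchema()),
                                  dimnames = list(NULL, cellTableSchema())))
      tab$truth_label <- character(0)
      tab$truth_biomarker_pos <- logical(0)
      return(tab)
    }
    labels <- sample(names(mix), nCells, replace = TRUE,
                     prob = mix / sum(mix))
    radius <- stats::runif(nCells, 8, 12)
    tab <- data.frame(cell_id = seq_len(nCells),
                      row = stats::runif(nCells, 1, 1024),
                      col = stats::runif(nCells, 1, 1024),
                      area = round(pi * radius^2),
                      solidity = 1,
                      stringsAsFactors = FALSE)
    vals <- matrix(0, nCells, length(roles), dimnames = list(NULL, roles))
    bmPos <- logical(nCells)
    for (lab in unique(labels)) {
      idx <- which(labels == lab)
      ph <- phenotypes[[lab]]
      for (role in setdiff(roles, "BIOMARKER")) {
        vals[idx, role] <- drawLaw(length(idx), ph@channels[[role]])
      }
      bmDraw <- drawBiomarker(length(idx), ph@biomarker)
      vals[idx, "BIOMARKER"] <- bmDraw$value
      bmPos[idx] <- bmDraw$positive
    }
    for (role in roles) {
      tab[[paste0("raw_", role)]] <- vals[, role] + backgroundLevel
      tab[[paste0("bgsub_", role)]] <- vals[, role]
    }
    tab$flag_saturated <- FALSE
    tab$flag_border <- FALSE
    tab$flag_size <- FALSE
    tab$flag_solidity <- FALSE
    tab$qc_pass <- TRUE
    tab$truth_label <- labels
    tab$truth_biomarker_pos <- bmPos
    tab
  })
}

#' Simulate a patient cohort of CTC samples
#'
#' Each sample's true CTC density (cells per mL of blood) is drawn from its
#' group's log-normal law; the observed total CTC count is
#' Poisson(density x volume) and is split across the three CTC phenotypes
#' by a multinomial draw. Per-cell biomarker values are drawn from each
#' phenotype's bimodal mixture and returned as a list column. Default group
#' density means are anchored to the clinical scale of the assay: samples
#' taken near radiographic progression averaged 19.8 CTCs/mL versus 2.3
#' CTCs/mL for samples from responding patients.
#'
#' @param nProgressing,nResponding Samples per response group.
#' @param densityMeans c(progressing =, responding =) mean CTC density,
#'   cells/mL.
#' @param densitySdlog c(progressing =, responding =) log-scale SD of the
#'   density law (controls the right-skew of per-sample densities).
#' @param proportions Named phenotype mixing proportions (must sum to 1).
#' @param volume Blood volume per sample, mL (> 0).
#' @param phenotypes Named list of [PhenotypeSpec-class] (biomarker laws).
#' @param seed Integer seed.
#' @return data.frame, one row per sample: sample_id, group, volume,
#'   true_density, counts and densities per phenotype (plus ALL_CTC and
#'   CK_PLUS), and a `biomarker` list column of per-cell draws.
#' @examples
#' coh <- simulateCohort(nProgressing = 3, nResponding = 3, seed = 1)
#' coh$density_ALL_CTC
#' @export
simulateCohort <- function(nProgressing = 11, nResponding = 9,
                           densityMeans = c(progressing = 19.8,
                                            responding = 2.3),
                           densitySdlog = c(progressing = 1.2,
                                            responding = 1.0),
                           proportions = c(CAXII_S = 0.4, DP = 0.3,
                                           CK_S = 0.3),
                           volume = 2, phenotypes = ctcPhenotypes(), seed) {
  if (missing(seed)) stop("a seed is required")
  if (nProgressing < 0 || nResponding < 0) stop("group sizes must be >= 0")
  if (volume <= 0) stop("volume must be > 0")
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-8) {
    stop("phenotype proportions must be non-negative and sum to 1")
  }
  phs <- names(proportions)
  if (!all(phs %in% ctcLabels())) stop("proportions must cover CTC phenotypes")
  withr::with_seed(seed, {
    group <- rep(c("progressing", "responding"),
                 c(nProgressing, nResponding))
    n <- length(group)
    dens <- numeric(n)
    for (g in c("progressing", "responding")) {
      idx <- which(group == g)
      if (!length(idx)) next
      sdlog <- densitySdlog[[g]]
      meanlog <- log(densityMeans[[g]]) - sdlog^2 / 2
      dens[idx] <- stats::rlnorm(length(idx), meanlog, sdlog)
    }
    total <- stats::rpois(n, dens * volume)
    countMat <- matrix(0L, n, length(phs), dimnames = list(NULL, phs))
    biomarker <- vector("list", n)
    for (i in seq_len(n)) {
      if (total[i] > 0) {
        countMat[i, ] <- as.integer(stats::rmultinom(1, total[i], proportions))
      }
      draws <- lapply(phs, function(ph) {
        drawBiomarker(countMat[i, ph], phenotypes[[ph]]@biomarker)$value
      })
      biomarker[[i]] <- unlist(draws)
    }
    out <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                      group = group, volume = volume, true_density = dens,
                      stringsAsFactors = FALSE)
    for (ph in phs) {
      out[[paste0("n_", ph)]] <- countMat[, ph]
      out[[paste0("density_", ph)]] <- countMat[, ph] / volume
    }
    out$n_ALL_CTC <- as.integer(rowSums(countMat))
    out$density_ALL_CTC <- out$n_ALL_CTC / volume
    ckp <- intersect(c("CK_S", "DP"), phs)
    out$n_CK_PLUS <- as.integer(rowSums(countMat[, ckp, drop = FALSE]))
    out$density_CK_PLUS <- out$n_CK_PLUS / volume
    out$biomarker <- I(biomarker)
    out
  })
}

#' Simulate a longitudinal series of CTC samples for one patient
#'
#' One sample per timepoint; counts are Poisson(density x volume) exactly
#' as in [simulateCohort()].
#'
#' @param series data.frame with a strictly increasing `week` column and
#'   one `density_<PHENOTYPE>` column (cells/mL) per CTC phenotype.
#' @param volume Blood volume per sample, mL.
#' @param seed Integer seed.
#' @return data.frame: week, volume, counts and densities per phenotype
#'   plus ALL_CTC and CK_PLUS.
#' @examples
#' sp <- data.frame(week = c(0, 5, 11),
#'                  density_CK_S = c(0.4, 0.4, 5.6),
#'                  density_CAXII_S = c(0.1, 0.07, 106.4))
#' simulateLongitudinal(sp, volume = 2, seed = 1)
#' @export
simulateLongitudinal <- function(series, volume = 2, seed) {
  if (missing(seed)) stop("a seed is required")
  if (anyDuplicated(series$week)) stop("duplicate weeks in series")
  if (is.unsorted(series$week, strictly = TRUE)) {
    stop("weeks must be strictly increasing")
  }
  if (volume <= 0) stop("volume must be > 0")
  densCols <- grep("^density_", names(series), value = TRUE)
  if (!length(densCols)) stop("series needs density_<PHENOTYPE> columns")
  phs <- sub("^density_", "", densCols)
  withr::with_seed(seed, {
    out <- data.frame(week = series$week, volume = volume)
    counts <- sapply(densCols, function(cl) {
      stats::rpois(nrow(series), series[[cl]] * volume)
    })
    counts <- matrix(counts, nrow = nrow(series),
                     dimnames = list(NULL, phs))
    for (ph in phs) {
      out[[paste0("n_", ph)]] <- counts[, ph]
      out[[paste0("density_", ph)]] <- counts[, ph] / volume
    }
    out$n_ALL_CTC <- as.integer(rowSums(counts))
    out$density_ALL_CTC <- out$n_ALL_CTC / volume
    ckp <- intersect(c("CK_S", "DP"), phs)
    out$n_CK_PLUS <- as.integer(rowSums(counts[, ckp, drop = FALSE]))
    out$density_CK_PLUS <- out$n_CK_PLUS / volume
    out
  })
}

#' Truth-column helpers
#'
#' Generator outputs carry ground-truth columns prefixed `truth_` for test
#' use only. `truthColumns()` lists them; `stripTruth()` removes them, and
#' is applied by [writeCellTable()] unless truth is explicitly requested,
#' so hidden truth never leaks into the schemas the analysis consumes.
#'
#' @param x A data.frame.
#' @return `truthColumns()`: character vector; `stripTruth()`: the
#'   data.frame without truth columns.
#' @export
truthColumns <- function(x) grep("^truth_", names(x), value = TRUE)

#' @rdname truthColumns
#' @export
stripTruth <- function(x) x[, setdiff(names(x), truthColumns(x)), drop = FALSE]
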