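## Image-stage pipeline: rolling-ball background subtraction,
## nucleus-anchored segmentation, measurement-region partition, background
## estimation from non-cell pixels, and per-cell quantification with QC
## flags in place of manual review.

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background of a fluorescence image as its
#' morphological grey-opening with a disc structuring element of the given
#' radius and subtracts it, clipping at zero. Features smaller than the
#' ball (cells) survive; smooth illumination and offsets are removed, so
#' the result is invariant to adding a constant to the whole image. A flat
#' image maps to all zeros.
#'
#' @param image 2-D numeric matrix of intensities.
#' @param radius Ball (disc) radius in pixels; >= 1 and less than half the
#'   image's short side.
#' @return Matrix of the same shape, background-subtracted and >= 0.
#' @examples
#' img <- matrix(100, 32, 32); img[10:14, 10:14] <- 600
#' out <- rollingBallSubtract(img, 10)
#' range(out)
#' @export
rollingBallSubtract <- function(image, radius) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a 2-D numeric matrix")
  }
  if (radius < 1) stop("radius must be >= 1")
  if (2 * radius + 1 > min(dim(image))) {
    stop("radius must be smaller than the image's short side")
  }
  rng <- range(image)
  if (rng[1] == rng[2]) return(matrix(0, nrow(image), ncol(image)))
  ## EBImage grey morphology clamps to [0, 1]; min/max filters commute with
  ## increasing affine maps, so normalise, open, and map back exactly
  norm <- (image - rng[1]) / (rng[2] - rng[1])
  brush <- EBImage::makeBrush(2 * as.integer(radius) + 1, shape = "disc")
  bg <- EBImage::opening(norm, brush) * (rng[2] - rng[1]) + rng[1]
  pmax(image - bg, 0)
}

#' Segmentation configuration
#'
#' @param thresholdMethod "otsu" (default; Otsu's method on the
#'   background-subtracted nuclear channel), "fixed" (use
#'   `thresholdValue`), or "quantile" (use the `thresholdQuantile` image
#'   quantile).
#' @param thresholdValue Fixed nuclear threshold (method "fixed").
#' @param thresholdQuantile Quantile for method "quantile".
#' @param minArea,maxArea Nuclear area bounds in pixels; objects outside
#'   the range are discarded (logged), the automatable proxy for an intact
#'   nucleus together with `minSolidity`.
#' @param minSolidity Minimum nuclear solidity (area / convex hull area);
#'   less solid objects are kept but QC-flagged.
#' @param ringWidth Dilation of the nuclear mask, in pixels, defining the
#'   measurement region that captures peri-nuclear membrane/cytoplasmic
#'   marker signal.
#' @param maskSmoothRadius Radius of the binary morphological opening
#'   applied to the thresholded nuclear mask before labelling; removes
#'   isolated noise pixels and ragged boundary stragglers that would
#'   otherwise inflate the measurement regions. 0 disables smoothing.
#' @param rollingBallRadius Radius for nuclear background subtraction.
#' @param saturationLevel Intensity treated as detector saturation
#'   (NA disables the check).
#' @param saturationFraction Fraction of region pixels at/above
#'   `saturationLevel` that triggers the saturation QC flag.
#' @return List of class `segmentationConfig`.
#' @export
segmentationConfig <- function(thresholdMethod = c("otsu", "fixed",
                                                   "quantile"),
                               thresholdValue = NA_real_,
                               thresholdQuantile = 0.99,
                               minArea = 50, maxArea = 2000,
                               minSolidity = 0.8, ringWidth = 4,
                               maskSmoothRadius = 2,
                               rollingBallRadius = 50,
                               saturationLevel = NA_real_,
                               saturationFraction = 0.005) {
  structure(list(thresholdMethod = match.arg(thresholdMethod),
                 thresholdValue = thresholdValue,
                 thresholdQuantile = thresholdQuantile,
                 minArea = minArea, maxArea = maxArea,
                 minSolidity = minSolidity, ringWidth = ringWidth,
                 maskSmoothRadius = maskSmoothRadius,
                 rollingBallRadius = rollingBallRadius,
                 saturationLevel = saturationLevel,
                 saturationFraction = saturationFraction),
            class = "segmentationConfig")
}

## solidity = pixel count / convex hull area of the pixel centres,
## capped at 1 (hulls of pixel centres slightly under-cover the raster)
objectSolidity <- function(rr, cc) {
  n <- length(rr)
  if (n < 4L) return(1)
  pts <- cbind(rr, cc)
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]
  m <- nrow(hp)
  if (m < 3L) return(1)
  nxt <- c(2:m, 1)
  hullArea <- abs(sum(hp[, 1] * hp[nxt, 2] - hp[nxt, 1] * hp[, 2])) / 2
  ## pad: pixel centres shrink the hull by ~half a pixel along the boundary
  perim <- sum(sqrt(rowSums((hp - hp[nxt, , drop = FALSE])^2)))
  hullArea <- hullArea + perim / 2 + 1
  min(n / hullArea, 1)
}

#' Segment nuclei and build measurement regions
#'
#' Thresholds the background-subtracted nuclear channel (binary cell
#' boundary), labels connected components, filters them by nuclear area,
#' and builds one measurement region per retained cell: the nuclear mask
#' dilated by `ringWidth` pixels. Pixels claimed by more than one cell's
#' dilation are assigned to the nearer centroid, so measurement regions
#' partition the field (each pixel belongs to at most one region). Cells
#' touching the field border are QC-flagged.
#'
#' @param stack A [ChannelStack-class] containing a NUCLEAR channel.
#' @param config A [segmentationConfig()].
#' @return List of class `cellSegmentation`: `labels` (nuclear label
#'   matrix), `regions` (measurement-region label matrix), `cells`
#'   (skeleton data.frame: cell_id, row, col, area, solidity, flag_border,
#'   flag_size, flag_solidity), `discarded` (area-filtered objects),
#'   `threshold`, and the config.
#' @export
segmentCells <- function(stack, config = segmentationConfig()) {
  stopifnot(is(stack, "ChannelStack"))
  if (!"NUCLEAR" %in% stackRoles(stack)) {
    stop("segmentation requires a NUCLEAR channel")
  }
  nuc <- rollingBallSubtract(getChannel(stack, "NUCLEAR"),
                             config$rollingBallRadius)
  thr <- switch(config$thresholdMethod,
    otsu = {
      mx <- max(nuc)
      if (mx == 0) Inf
      else EBImage::otsu(EBImage::Image(nuc / mx), range = c(0, 1)) * mx
    },
    fixed = {
      if (!is.finite(config$thresholdValue)) {
        stop("thresholdValue must be set for method 'fixed'")
      }
      config$thresholdValue
    },
    quantile = stats::quantile(nuc, config$thresholdQuantile, names = FALSE)
  )
  bw <- nuc > thr
  if (config$maskSmoothRadius > 0) {
    bw <- EBImage::opening(
      bw, EBImage::makeBrush(2 * as.integer(config$maskSmoothRadius) + 1,
                             shape = "disc")) > 0.5
  }
  labels <- EBImage::bwlabel(bw)
  nObj <- max(labels)
  empty <- data.frame(cell_id = integer(0), row = numeric(0),
                      col = numeric(0), area = integer(0),
                      solidity = numeric(0), flag_border = logical(0),
                      flag_size = logical(0), flag_solidity = logical(0))
  if (nObj == 0L) {
    return(structure(list(labels = labels, regions = labels, cells = empty,
                          discarded = empty, threshold = thr,
                          config = config),
                     class = "cellSegmentation"))
  }
  idx <- which(labels > 0)
  lab <- labels[idx]
  rr <- ((idx - 1L) %% nrow(labels)) + 1L
  cc <- ((idx - 1L) %/% nrow(labels)) + 1L
  area <- tabulate(lab, nObj)
  cenR <- rowsum(rr, lab)[, 1] / area
  cenC <- rowsum(cc, lab)[, 1] / area
  border <- tabulate(lab[rr == 1L | rr == nrow(labels) |
                           cc == 1L | cc == ncol(labels)], nObj) > 0
  solidity <- vapply(seq_len(nObj), function(k) {
    sel <- lab == k
    objectSolidity(rr[sel], cc[sel])
  }, numeric(1))
  cells <- data.frame(cell_id = seq_len(nObj), row = cenR, col = cenC,
                      area = area, solidity = solidity,
                      flag_border = border,
                      flag_size = area < config$minArea |
                                  area > config$maxArea,
                      flag_solidity = solidity < config$minSolidity)
  keep <- !cells$flag_size
  discarded <- cells[!keep, , drop = FALSE]
  cells <- cells[keep, , drop = FALSE]
  ## drop filtered objects from the mask and renumber contiguously
  remap <- integer(nObj)
  remap[cells$cell_id] <- seq_len(nrow(cells))
  labels[idx] <- remap[lab]
  cells$cell_id <- seq_len(nrow(cells))
  rownames(cells) <- NULL

  ## measurement regions: dilate the nuclear mask, assign contested or new
  ## pixels to the nearest retained centroid
  regions <- labels
  if (nrow(cells) > 0L && config$ringWidth > 0) {
    brush <- EBImage::makeBrush(2 * as.integer(config$ringWidth) + 1,
                                shape = "disc")
    dil <- EBImage::dilate(labels > 0, brush)
    newIdx <- which(dil & labels == 0L)
    if (length(newIdx)) {
      nr <- ((newIdx - 1L) %% nrow(labels)) + 1L
      nc <- ((newIdx - 1L) %/% nrow(labels)) + 1L
      d2 <- outer(nr, cells$row, "-")^2 + outer(nc, cells$col, "-")^2
      regions[newIdx] <- max.col(-d2, ties.method = "first")
    }
  }
  structure(list(labels = labels, regions = regions, cells = cells,
                 discarded = discarded, threshold = thr, config = config),
            class = "cellSegmentation")
}

#' Estimate per-channel background from non-cell pixels
#'
#' The average background fluorescence of each channel, computed over
#' pixels outside every measurement region dilated by `exclusionDilation`
#' pixels (a guard band against residual cell signal). Accounts for
#' sample-to-sample variability in washing efficiency. If fewer than 1% of
#' field pixels remain, the estimate is flagged unreliable.
#'
#' @param stack A [ChannelStack-class].
#' @param regions Measurement-region label matrix from [segmentCells()]
#'   (or a `cellSegmentation` object).
#' @param exclusionDilation Guard-band width in pixels.
#' @return List of class `backgroundEstimate`: `estimate` (named numeric,
#'   per role), `nPixels`, `fraction` of field pixels used, `reliable`.
#' @export
estimateBackground <- function(stack, regions, exclusionDilation = 8) {
  stopifnot(is(stack, "ChannelStack"))
  if (inherits(regions, "cellSegmentation")) regions <- regions$regions
  if (!all(dim(regions) == dim(stack))) {
    stop("regions and stack must share dimensions")
  }
  mask <- regions > 0
  if (any(mask) && exclusionDilation > 0) {
    brush <- EBImage::makeBrush(2 * as.integer(exclusionDilation) + 1,
                                shape = "disc")
    mask <- EBImage::dilate(mask, brush)
  }
  bgPix <- which(!mask)
  frac <- length(bgPix) / length(mask)
  est <- vapply(stackRoles(stack),
                function(role) mean(getChannel(stack, role)[bgPix]),
                numeric(1))
  if (frac < 0.01) {
    warning("background estimated from < 1% of field pixels; flagged unreliable")
  }
  structure(list(estimate = est, nPixels = length(bgPix), fraction = frac,
                 reliable = frac >= 0.01),
            class = "backgroundEstimate")
}

#' Quantify cells over their measurement regions
#'
#' For every cell and channel role: the raw mean intensity over the cell's
#' measurement region and the background-subtracted mean (raw minus the
#' per-channel background estimate). Subtracted means may be negative and
#' are deliberately not clipped: downstream cutoff fitting needs the full
#' (negative-tail-inclusive) distribution. Adds the saturation QC flag and
#' assembles `qc_pass` (no border, saturation or solidity flag).
#'
#' @param seg A `cellSegmentation` from [segmentCells()].
#' @param stack The [ChannelStack-class] that was segmented.
#' @param background A `backgroundEstimate` from [estimateBackground()]
#'   covering every role in the stack.
#' @return data.frame (CellTable): cell_id, row, col, area, solidity,
#'   raw_<ROLE> and bgsub_<ROLE> per role, QC flags, qc_pass.
#' @export
measureCells <- function(seg, stack, background) {
  stopifnot(inherits(seg, "cellSegmentation"), is(stack, "ChannelStack"),
            inherits(background, "backgroundEstimate"))
  if (!all(dim(seg$regions) == dim(stack))) {
    stop("segmentation and stack must share dimensions")
  }
  roles <- stackRoles(stack)
  missingBg <- setdiff(roles, names(background$estimate))
  if (length(missingBg)) {
    stop(sprintf("background estimate missing role(s): %s",
                 paste(missingBg, collapse = ", ")))
  }
  cells <- seg$cells
  n <- nrow(cells)
  cfg <- seg$config
  if (n == 0L) {
    for (role in roles) {
      cells[[paste0("raw_", role)]] <- numeric(0)
      cells[[paste0("bgsub_", role)]] <- numeric(0)
    }
    cells$flag_saturated <- logical(0)
    cells$qc_pass <- logical(0)
    return(cells)
  }
  idx <- which(seg$regions > 0)
  reg <- seg$regions[idx]
  regArea <- tabulate(reg, n)
  satAny <- rep(FALSE, n)
  for (role in roles) {
    v <- getChannel(stack, role)[idx]
    rawMean <- rowsum(v, reg)[, 1] / regArea
    cells[[paste0("raw_", role)]] <- rawMean
    cells[[paste0("bgsub_", role)]] <- rawMean -
      background$estimate[[role]]
    if (is.finite(cfg$saturationLevel)) {
      satFrac <- tabulate(reg[v >= cfg$saturationLevel], n) / regArea
      satAny <- satAny | satFrac >= cfg$saturationFraction
    }
  }
  cells$flag_saturated <- satAny
  cells$qc_pass <- !cells$flag_border & !cells$flag_saturated &
    !cells$flag_solidity
  rownames(cells) <- NULL
  cells
}

#' Full image-stage pipeline for one field
#'
#' Convenience wrapper: segment, estimate background, measure.
#'
#' @param stack A [ChannelStack-class].
#' @param config A [segmentationConfig()].
#' @param exclusionDilation Guard band for [estimateBackground()].
#' @return List: `cells` (CellTable data.frame), `segmentation`,
#'   `background`.
#' @examples
#' fld <- simulateField(c(CAXII_S = 3), fieldShape = c(256, 256), seed = 7)
#' res <- quantifyField(fld$stack)
#' nrow(res$cells)
#' @export
quantifyField <- function(stack, config = segmentationConfig(),
                          exclusionDilation = 8) {
  seg <- segmentCells(stack, config)
  bg <- estimateBackground(stack, seg, exclusionDilation)
  cells <- measureCells(seg, stack, bg)
  list(cells = cells, segmentation = seg, background = bg)
}
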