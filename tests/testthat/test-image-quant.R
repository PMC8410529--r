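# Image stage: rolling-ball subtraction, segmentation, measurement-region
# partition, background estimation and per-cell quantification.

test_that("rolling-ball subtraction removes flat fields and constant offsets", {
  expect_equal(rollingBallSubtract(matrix(100, 64, 64), 10),
               matrix(0, 64, 64))
  img <- matrix(0, 96, 96)
  img[40:50, 40:50] <- 600
  out <- rollingBallSubtract(img, 25)
  # the disk is smaller than the ball, so it survives intact
  expect_equal(max(abs(out - img)), 0)
  # offset invariance
  expect_equal(rollingBallSubtract(img + 37, 25), out)
  expect_error(rollingBallSubtract(array(0, c(4, 4, 2)), 2), "2-D")
  expect_error(rollingBallSubtract(matrix(0, 16, 16), 20), "short side")
})

test_that("rolling-ball subtraction agrees with a direct grey-opening oracle", {
  set.seed(4)
  img <- matrix(runif(64 * 64, 0, 80), 64, 64)
  img[20:26, 30:36] <- img[20:26, 30:36] + 900
  radius <- 12
  # oracle: brute-force min-then-max filter over the same disc offsets
  brush <- EBImage::makeBrush(2 * radius + 1, "disc")
  off <- which(brush == 1, arr.ind = TRUE) - (radius + 1)
  n <- 64
  filt <- function(m, fun) {
    out <- matrix(NA_real_, n, n)
    for (r in 1:n) for (cc in 1:n) {
      rr <- r + off[, 1]; c2 <- cc + off[, 2]
      ok <- rr >= 1 & rr <= n & c2 >= 1 & c2 <= n
      out[r, cc] <- fun(m[cbind(rr[ok], c2[ok])])
    }
    out
  }
  openf <- filt(filt(img, min), max)
  expect_equal(rollingBallSubtract(img, radius), pmax(img - openf, 0),
               tolerance = 1e-8)
})

test_that("segmentation finds exactly the constructed nuclei and filters by area", {
  img <- matrix(0, 200, 200)
  centers <- cbind(c(40, 40, 120, 120, 170), c(40, 120, 40, 120, 170))
  for (i in seq_len(nrow(centers))) {
    rr <- outer((1:200 - centers[i, 1])^2, (1:200 - centers[i, 2])^2, "+")
    img[rr <= 81] <- 500
  }
  img[10, 10] <- 500  # single-pixel speck, below min area
  stack <- ChannelStack(list(NUCLEAR = img))
  # smoothing off so the sub-minArea object reaches the discard log
  seg <- segmentCells(stack, segmentationConfig(minArea = 30,
                                                maskSmoothRadius = 0))
  expect_equal(nrow(seg$cells), 5)
  expect_equal(nrow(seg$discarded), 1)
  expect_equal(seg$discarded$area, 1L)
  expect_error(segmentCells(ChannelStack(list(CK = img))), "NUCLEAR")
  # empty field: empty table, not an error
  seg0 <- segmentCells(ChannelStack(list(NUCLEAR = matrix(0, 64, 64))),
                       segmentationConfig(rollingBallRadius = 20))
  expect_equal(nrow(seg0$cells), 0)
})

test_that("contested measurement pixels go to the nearer centroid and regions partition the field", {
  img <- matrix(0, 120, 120)
  for (ctr in list(c(60, 50), c(60, 72))) {
    rr <- outer((1:120 - ctr[1])^2, (1:120 - ctr[2])^2, "+")
    img[rr <= 64] <- 400
  }
  stack <- ChannelStack(list(NUCLEAR = img))
  seg <- segmentCells(stack, segmentationConfig(minArea = 30, ringWidth = 6))
  expect_equal(nrow(seg$cells), 2)
  # every pixel belongs to at most one region, and nuclear pixels keep
  # their own label
  expect_true(all(seg$regions[seg$labels > 0] == seg$labels[seg$labels > 0]))
  # ring pixels obey the nearest-centroid oracle
  ring <- which(seg$regions > 0 & seg$labels == 0)
  rr <- ((ring - 1) %% 120) + 1
  cc <- ((ring - 1) %/% 120) + 1
  d1 <- (rr - seg$cells$row[1])^2 + (cc - seg$cells$col[1])^2
  d2 <- (rr - seg$cells$row[2])^2 + (cc - seg$cells$col[2])^2
  oracle <- ifelse(d1 <= d2, 1L, 2L)
  expect_equal(as.integer(seg$regions[ring]), oracle)
})

test_that("per-cell means follow the stated arithmetic and sign convention", {
  img <- matrix(20, 100, 100)  # uniform background 20
  rr <- outer((1:100 - 50)^2, (1:100 - 50)^2, "+")
  nuc <- matrix(0, 100, 100)
  nuc[rr <= 81] <- 500
  bright <- img; bright[rr <= 196] <- 50   # raw 50 over the whole region
  dim_ch <- matrix(10, 100, 100)           # raw 10 < background 20
  stack <- ChannelStack(list(NUCLEAR = nuc, CAXII = bright, CK = dim_ch))
  seg <- segmentCells(stack, segmentationConfig(minArea = 30, ringWidth = 4,
                                                rollingBallRadius = 20))
  bg <- structure(list(estimate = c(NUCLEAR = 0, CAXII = 20, CK = 20),
                       nPixels = 5000L, fraction = 0.5, reliable = TRUE),
                  class = "backgroundEstimate")
  cells <- measureCells(seg, stack, bg)
  expect_equal(cells$bgsub_CAXII, 30, tolerance = 1e-12)
  # dimmer than background: negative, retained, not clipped
  expect_equal(cells$bgsub_CK, -10, tolerance = 1e-12)
  expect_error(measureCells(seg, stack,
                            structure(list(estimate = c(NUCLEAR = 0),
                                           nPixels = 1L, fraction = 0.5,
                                           reliable = TRUE),
                                      class = "backgroundEstimate")),
               "missing role")
})

test_that("background estimation averages non-cell pixels and reacts to masking", {
  flat <- ChannelStack(list(NUCLEAR = matrix(7, 80, 80),
                            CK = matrix(7, 80, 80)))
  est <- estimateBackground(flat, matrix(0L, 80, 80))
  expect_equal(unname(est$estimate), c(7, 7))
  # linear gradient 0 -> 10 with no cells: mean ~ 5
  grad <- matrix(rep(seq(0, 10, length.out = 80), each = 80), 80, 80)
  est2 <- estimateBackground(ChannelStack(list(CK = grad)),
                             matrix(0L, 80, 80))
  expect_equal(unname(est2$estimate), 5, tolerance = 1e-6)
  # masking a bright cell lowers the estimate
  bright <- matrix(10, 80, 80)
  bright[30:40, 30:40] <- 1000
  regions <- matrix(0L, 80, 80)
  regions[30:40, 30:40] <- 1L
  stk <- ChannelStack(list(CK = bright))
  masked <- estimateBackground(stk, regions, exclusionDilation = 2)
  unmasked <- estimateBackground(stk, matrix(0L, 80, 80))
  expect_lt(masked$estimate[["CK"]], unmasked$estimate[["CK"]])
  # too few remaining pixels: flagged unreliable
  expect_warning(
    big <- estimateBackground(stk, matrix(1L, 80, 80),
                              exclusionDilation = 0),
    "unreliable")
  expect_false(big$reliable)
})

test_that("quantification is invariant to adding a constant to all channels", {
  fld <- simulateField(c(CAXII_S = 4, CK_S = 3), fieldShape = c(384, 384),
                       seed = 77, noiseSd = 15)
  res1 <- quantifyField(fld$stack)
  shifted <- ChannelStack(lapply(fld$stack@channels, function(m) m + 250))
  res2 <- quantifyField(shifted)
  expect_equal(nrow(res1$cells), nrow(res2$cells))
  for (role in channelRoles()) {
    expect_equal(res2$cells[[paste0("bgsub_", role)]],
                 res1$cells[[paste0("bgsub_", role)]], tolerance = 1e-6)
  }
})

test_that("border-touching and saturated cells are QC-flagged, not dropped", {
  img <- matrix(0, 128, 128)
  rr <- outer((1:128 - 8)^2, (1:128 - 64)^2, "+")   # touches top border
  img[rr <= 100] <- 400
  rr2 <- outer((1:128 - 80)^2, (1:128 - 64)^2, "+")
  img[rr2 <= 100] <- 400
  sat <- matrix(0, 128, 128)
  sat[rr2 <= 100] <- 65535                           # saturated cell body
  stack <- ChannelStack(list(NUCLEAR = img, CAXII = sat))
  cfg <- segmentationConfig(minArea = 30, saturationLevel = 65535)
  seg <- segmentCells(stack, cfg)
  bg <- estimateBackground(stack, seg)
  cells <- measureCells(seg, stack, bg)
  expect_equal(nrow(cells), 2)
  expect_equal(sum(cells$flag_border), 1)
  expect_equal(sum(cells$flag_saturated), 1)
  expect_true(all(!cells$qc_pass))
})

test_that("measured intensities recover generator truth within noise error", {
  fld <- simulateField(c(CAXII_S = 3, DP = 3, CK_S = 3),
                       fieldShape = c(448, 448), seed = 101, noiseSd = 50)
  res <- quantifyField(fld$stack)
  expect_equal(nrow(res$cells), nrow(fld$truth))
  regArea <- tabulate(res$segmentation$regions[res$segmentation$regions > 0])
  # pair measured cells with truth by centroid
  d <- sqrt(outer(fld$truth$row, res$cells$row, "-")^2 +
            outer(fld$truth$col, res$cells$col, "-")^2)
  pair <- apply(d, 1, which.min)
  nOK <- 0L; nTot <- 0L
  for (role in c("CAXII", "CK", "EXCLUSION", "BIOMARKER")) {
    err <- abs(res$cells[[paste0("bgsub_", role)]][pair] -
               fld$truth[[paste0("true_", role)]])
    se <- 50 / sqrt(regArea[pair])
    nOK <- nOK + sum(err <= 3 * se)
    nTot <- nTot + length(err)
  }
  expect_gte(nOK / nTot, 0.95)
})
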