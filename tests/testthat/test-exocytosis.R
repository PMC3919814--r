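test_that("segmentation: blank images, true centroids, touching cells", {
  p <- PatchSimParams(nCells = 10L, timepoints = 0, noiseSd = 0,
                      basePrevalence = 0, foldPeak = 1, seed = 19)
  blank <- matrix(0, 200, 200)
  seg0 <- segmentCells(blank, expectedRingAreaPx(p))
  expect_equal(nrow(seg0$centroids), 0L)

  pis <- renderPatchImages(p)
  seg <- segmentCells(images(pis)[[1]], expectedRingAreaPx(p),
                      pixelSize = p@pixelSize)
  tt <- truthTable(pis)
  expect_equal(nrow(seg$centroids), 10L)
  # each truth centroid has a segmented centroid within one pixel
  for (i in seq_len(10)) {
    d <- sqrt((seg$centroids$x_um - tt$x_um[i])^2 +
                (seg$centroids$y_um - tt$y_um[i])^2)
    expect_lt(min(d), p@pixelSize)
  }

  # two touching rings merge into one oversized component and are dropped
  # by the size filter: a documented limitation of global thresholding
  img <- matrix(0, 120, 120)
  tile <- rheotax:::drawRing(120L, 20, 24, p)
  img[tile$ii, tile$jj] <- img[tile$ii, tile$jj] + tile$val
  tile <- rheotax:::drawRing(120L, 20 + 2 * p@cellRadius, 24, p)
  img[tile$ii, tile$jj] <- img[tile$ii, tile$jj] + tile$val
  segT <- segmentCells(img, expectedRingAreaPx(p), pixelSize = p@pixelSize,
                       sizeRange = c(0.25, 1.5))
  expect_equal(nrow(segT$centroids), 0L)
  segT2 <- segmentCells(img, expectedRingAreaPx(p), pixelSize = p@pixelSize)
  expect_equal(nrow(segT2$centroids), 1L)
})

test_that("membrane profiles are flat on uniform rings and hot on arcs", {
  p <- PatchSimParams(nCells = 1L, timepoints = 0, noiseSd = 0,
                      basePrevalence = 0, foldPeak = 1, seed = 20)
  pis <- renderPatchImages(p)
  img <- images(pis)[[1]]
  seg <- segmentCells(img, expectedRingAreaPx(p), pixelSize = p@pixelSize)
  prof <- membraneProfile(img, seg$pixels[[1]],
                          c(seg$centroids$x_px[1], seg$centroids$y_px[1]))
  expect_length(prof, 72L)
  expect_lte(max(prof, na.rm = TRUE) / min(prof, na.rm = TRUE), 1.05)

  # constructed 45-degree arc at triple gain: 9 hot bins at ~3x baseline
  p45 <- PatchSimParams(nCells = 1L, timepoints = 0, noiseSd = 0,
                        basePrevalence = 0.999, patchArc = 45, patchGain = 3,
                        foldPeak = 1, seed = 20)
  img45 <- images(renderPatchImages(p45))[[1]]
  seg45 <- segmentCells(img45, expectedRingAreaPx(p45),
                        pixelSize = p45@pixelSize)
  prof45 <- membraneProfile(img45, seg45$pixels[[1]],
                            c(seg45$centroids$x_px[1],
                              seg45$centroids$y_px[1]))
  rel <- prof45 / median(prof45, na.rm = TRUE)
  hot <- sum(rel >= 2, na.rm = TRUE)
  expect_gte(hot, 8L)   # 45 deg = 9 bins, boundary bins may split
  expect_lte(hot, 10L)
  expect_gt(max(rel, na.rm = TRUE), 2.5)

  call <- detectPatch(prof45)
  expect_true(call$patch_present)
  expect_gte(call$arc_extent, 40)
  expect_lte(call$arc_extent, 55)

  # degenerate mask skipped with a warning
  expect_warning(out <- membraneProfile(img, cbind(1:5, 1:5), c(3, 3)),
                 "degenerate")
  expect_null(out)
})

test_that("profile integral matches a direct pixel-sum oracle", {
  p <- PatchSimParams(nCells = 1L, timepoints = 0, noiseSd = 0,
                      basePrevalence = 0, foldPeak = 1, seed = 22)
  img <- images(renderPatchImages(p))[[1]]
  seg <- segmentCells(img, expectedRingAreaPx(p), pixelSize = p@pixelSize)
  prof <- membraneProfile(img, seg$pixels[[1]],
                          c(seg$centroids$x_px[1], seg$centroids$y_px[1]))
  # uniform ring: sum of bin means = mean ring intensity x bin count
  ringMean <- mean(img[img > 0])
  expect_equal(sum(prof, na.rm = TRUE), ringMean * sum(!is.na(prof)),
               tolerance = 0.05)
})

test_that("patch calls: flat profiles negative, wrap-around arcs positive", {
  expect_false(detectPatch(rep(1, 72))$patch_present)

  prof <- rep(1, 72)
  prof[10:18] <- 3
  call <- detectPatch(prof)
  expect_true(call$patch_present)
  expect_equal(call$arc_extent, 45)
  expect_equal(call$arc_contrast, 3)

  # run wrapping across 0 degrees
  wrap <- rep(1, 72)
  wrap[c(69:72, 1:5)] <- 2.5
  callW <- detectPatch(wrap)
  expect_true(callW$patch_present)
  expect_equal(callW$arc_extent, 45)
})

test_that("raising min contrast never creates new positives", {
  p <- PatchSimParams(nCells = 60L, timepoints = 0, basePrevalence = 0.5,
                      foldPeak = 1, seed = 26)
  pis <- renderPatchImages(p)
  nPos <- vapply(c(1.5, 2, 2.5, 3.5), function(mc) {
    sum(scorePatchImages(pis, minContrast = mc)$patch_present)
  }, numeric(1))
  expect_true(all(diff(nPos) <= 0))
})

test_that("detection is insensitive to the patch angle", {
  base <- PatchSimParams(nCells = 1L, timepoints = 0, noiseSd = 0,
                         basePrevalence = 0.999, foldPeak = 1, seed = 28)
  centre <- c(30, 30)
  # draw the same cell with the patch at 8 explicit angles
  for (ang in seq(0, 315, by = 45)) {
    img <- matrix(0, 300, 300)
    tile <- rheotax:::drawRing(300L, centre[1], centre[2], base,
                               patchStart = ang)
    img[tile$ii, tile$jj] <- img[tile$ii, tile$jj] + tile$val
    segA <- segmentCells(img, expectedRingAreaPx(base),
                         pixelSize = base@pixelSize)
    prof <- membraneProfile(img, segA$pixels[[1]],
                            c(segA$centroids$x_px[1], segA$centroids$y_px[1]))
    expect_true(detectPatch(prof)$patch_present)
  }
})

test_that("scoring reaches high sensitivity and specificity on rendered truth", {
  p <- PatchSimParams(nCells = 300L, timepoints = 0, basePrevalence = 0.5,
                      foldPeak = 1, patchGain = 3, noiseSd = 0.03, seed = 7)
  pis <- renderPatchImages(p)
  calls <- scorePatchImages(pis)
  tt <- truthTable(pis)
  idx <- apply(outer(calls$x_um, tt$x_um, "-")^2 +
                 outer(calls$y_um, tt$y_um, "-")^2, 1, which.min)
  truth <- tt$has_patch[idx]
  sens <- mean(calls$patch_present[truth])
  spec <- mean(!calls$patch_present[!truth])
  expect_gte(sens, 0.95)
  expect_gte(spec, 0.95)
})

test_that("time-course table recovers truth prevalences with Wilson CIs", {
  p <- PatchSimParams(nCells = 400L, timepoints = c(0, 2), seed = 33)
  tt <- simulatePatchTruth(p, nReplicates = 3)
  tc <- prevalenceTimeCourse(tt)
  for (i in seq_len(nrow(tc))) {
    sub <- tt[tt$time_min == tc$time_min[i], ]
    expect_equal(tc$prevalence[i], mean(sub$has_patch))
    expect_equal(tc$n_cells[i], nrow(sub))
  }
  expect_true(all(tc$ci_lo <= tc$prevalence & tc$prevalence <= tc$ci_hi))
  expect_true(is.na(tc$p_vs_t0[tc$time_min == 0]))
  expect_false(any(is.na(tc$p_vs_t0[tc$time_min != 0])))

  expect_error(prevalenceTimeCourse(tt[tt$time_min > 0, ]), "time 0")
})
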