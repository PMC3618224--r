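## Graded two-bump statistic map on a 3-mm grid.
twoBumpMap <- function(d = c(15L, 15L, 5L), c1 = c(4, 8, 3), c2 = c(14, 8, 3),
                       h1 = 50, h2 = 40) {
  stat <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    stat[i, j, k] <- h1 * exp(-sum((c(i, j, k) - c1)^2) / 6) +
      h2 * exp(-sum((c(i, j, k) - c2)^2) / 6)
  new("StatMap", statistic = as.numeric(stat), dof = c(5, 100),
      p = pmin(exp(-as.numeric(stat)), 1), dim = d, thresholdMeta = list())
}

test_that("peak-based ROIs respect the 8-mm rule and nearest assignment", {
  map <- twoBumpMap()
  mask <- array(map@statistic > 1, dim = map@dim)
  rois <- defineROIsFromPeaks(map, mask, radius = 8, voxelSize = c(3, 3, 3))
  expect_length(rois, 2)

  ## brute-force oracle: exhaustive distances from every masked voxel
  aff <- cbind(diag(c(3, 3, 3)), -(map@dim - 1) / 2 * 3)
  aff <- rbind(aff, c(0, 0, 0, 1))
  world <- function(v) t(aff %*% t(cbind(v - 1L, 1)))[, 1:3, drop = FALSE]
  for (roi in rois) {
    dmm <- sqrt(rowSums((world(roiVoxels(roi)) -
                         matrix(roiPeak(roi), roiSize(roi), 3,
                                byrow = TRUE))^2))
    expect_true(all(dmm <= 8 + 1e-9))
  }
  ## two peaks 30 mm apart give disjoint ROIs
  lin <- lapply(rois, function(r) {
    v <- roiVoxels(r); v[, 1] + 15L * (v[, 2] - 1L) + 225L * (v[, 3] - 1L)
  })
  expect_length(intersect(lin[[1]], lin[[2]]), 0)
  ## every masked voxel within 8 mm of some peak is claimed by nearest
  stat <- array(map@statistic, map@dim)
  peaks <- t(vapply(rois, roiPeak, numeric(3)))
  mw <- world(which(mask, arr.ind = TRUE))
  D <- sqrt(outer(rowSums(mw^2), rep(1, 2)) - 2 * mw %*% t(peaks) +
            outer(rep(1, nrow(mw)), rowSums(peaks^2)))
  claimed <- rowSums(D <= 8 + 1e-9) > 0
  expect_equal(sum(claimed), sum(vapply(rois, roiSize, integer(1))))

  ## flat plateau: no strict maxima, hence no ROIs
  flat <- new("StatMap", statistic = rep(2, prod(map@dim)), dof = c(5, 100),
              p = rep(0.001, prod(map@dim)), dim = map@dim,
              thresholdMeta = list())
  expect_length(defineROIsFromPeaks(flat, mask), 0)
  ## empty mask: empty list, not an error
  expect_length(defineROIsFromPeaks(map, mask & FALSE), 0)
})

test_that("single compact blob collapses to one ROI containing it", {
  d <- c(9L, 9L, 9L)
  stat <- array(0, d)
  for (i in 1:9) for (j in 1:9) for (k in 1:9)
    stat[i, j, k] <- exp(-sum((c(i, j, k) - 5)^2) / 8)
  map <- new("StatMap", statistic = as.numeric(stat), dof = c(5, 100),
             p = pmin(exp(-3 * as.numeric(stat)), 1), dim = d,
             thresholdMeta = list())
  mask <- array(FALSE, d)
  ## 2-voxel-radius spherical blob on a 3-mm grid: all within 6 mm of peak
  for (i in 1:9) for (j in 1:9) for (k in 1:9)
    mask[i, j, k] <- sum((c(i, j, k) - 5)^2) <= 4
  rois <- defineROIsFromPeaks(map, mask, radius = 8)
  expect_length(rois, 1)
  expect_equal(roiSize(rois[[1]]), sum(mask))
})

test_that("the MT/MST+ split follows the ipsilateral and trim rules", {
  ## hand-enumerable toy: a 4-voxel-wide slab, ipsi subset at the anterior
  ## end (world y grows with index j)
  d <- c(4L, 10L, 1L)
  contra <- array(TRUE, d)
  ipsi <- array(FALSE, d)
  ipsi[, 7:10, ] <- TRUE
  sp <- splitMtMst(contra, ipsi, voxelSize = c(3, 3, 3), hemisphere = "left")
  expect_equal(roiSize(sp$MST), 16)              # the planted ipsi subset
  ## MT = contra minus ipsi (24 voxels at j = 1..6), none beyond the MST+
  ## median (j in 7..10 -> all MT voxels are posterior): nothing trimmed
  expect_equal(roiSize(sp$MT), 24)
  expect_equal(sp$MST@hemisphere, "left")

  ## ipsi == contra: MT is empty, MST+ is the full component
  sp2 <- splitMtMst(contra, contra)
  expect_equal(roiSize(sp2$MST), prod(d))
  expect_equal(roiSize(sp2$MT), 0)

  ## anterior trim: an MT arm reaching past the MST+ median is cut
  contra3 <- array(FALSE, d)
  contra3[1, , ] <- TRUE                         # full-depth column
  ipsi3 <- array(FALSE, d)
  ipsi3[4, 5:8, ] <- TRUE                        # separate ipsi component
  sp3 <- splitMtMst(contra3, ipsi3)
  ## MST+ median anterior coordinate = median of j = 5..8 -> 6.5 ->
  ## MT keeps j <= 6 only
  expect_equal(sort(roiVoxels(sp3$MT)[, 2]), 1:6)

  expect_error(splitMtMst(contra, array(FALSE, d)), "MST undefined")
  expect_error(splitMtMst(contra, array(FALSE, c(2L, 2L, 2L))), "grid")

  ## invariants: disjoint, subset relations
  lin <- function(v) v[, 1] + d[1] * (v[, 2] - 1L) + prod(d[1:2]) * (v[, 3] - 1L)
  expect_length(intersect(lin(roiVoxels(sp$MT)), lin(roiVoxels(sp$MST))), 0)
  expect_true(all(lin(roiVoxels(sp$MST)) %in% which(ipsi)))
  expect_true(all(lin(roiVoxels(sp$MT)) %in% which(contra & !ipsi)))
})

test_that("the localizer pipeline recovers planted MT/MST+ exactly", {
  hrf <- fixHRF()
  amps <- ampVec(tra = 1, cir = 1, rad = 1, spi = 1, rand = 1)
  mtLike <- makeROISpec("MT", hemisphere = "left", amplitudes = amps,
                        ipsilateralResponsive = FALSE,
                        center = c(-12, -6, 0), radius = 5)
  mstLike <- makeROISpec("MST", hemisphere = "left", amplitudes = amps,
                         ipsilateralResponsive = TRUE,
                         center = c(-12, 6, 0), radius = 5)
  nm <- makeNoiseModel(sigma = 0, driftAmplitude = 0)
  dims <- c(14L, 14L, 8L)
  volL <- simulateVolume(buildLocalizerDesign("mtmst_left"),
                         list(mtLike, mstLike), nm, hrf, dims = dims, seed = 3)
  volR <- simulateVolume(buildLocalizerDesign("mtmst_right"),
                         list(mtLike, mstLike), nm, hrf, dims = dims, seed = 4)
  act <- function(vol, design) {
    fit <- fitGLM(vol, buildDesignMatrix(design, fixHRF()))
    map <- fContrast(fit, contrastRows(fit, list(on = c(on = 1))))
    array(map@statistic > 100, dim = fitDim(fit))
  }
  ipsi <- act(volL, buildLocalizerDesign("mtmst_left"))
  contra <- act(volR, buildLocalizerDesign("mtmst_right"))
  gt <- groundTruthMasks(volL)
  expect_identical(which(ipsi), which(gt$MST))
  expect_identical(which(contra), which(gt$MT | gt$MST))
  sp <- splitMtMst(contra, ipsi, affine = volL@affine, hemisphere = "left")
  lin <- function(v) as.integer(sort(v[, 1] + dims[1] * (v[, 2] - 1L) +
                                     prod(dims[1:2]) * (v[, 3] - 1L)))
  expect_identical(lin(roiVoxels(sp$MST)), which(gt$MST))
  ## MT equals planted MT minus ipsi voxels, after the anterior trim
  plantedMT <- which(gt$MT & !gt$MST)
  w <- t(volL@affine %*% t(cbind(arrayInd(plantedMT, dims) - 1L, 1)))[, 2]
  medAnt <- median(t(volL@affine %*%
                     t(cbind(arrayInd(which(gt$MST), dims) - 1L, 1)))[, 2])
  expect_identical(lin(roiVoxels(sp$MT)), sort(plantedMT[w <= medAnt + 1e-9]))
})

test_that("regional profiles equal voxelwise fits on average", {
  des <- fixFF3D()
  hrf <- fixHRF()
  amps <- ampVec(tra = 1, cir = 1, rad = 1, spi = 1, rand = 0.5, sta = 0)
  spec <- makeROISpec("r", amplitudes = amps, center = c(0, 0, 0), radius = 4)
  nm <- makeNoiseModel(sigma = 0.3)
  vol <- simulateVolume(des, list(spec), nm, hrf, dims = c(8L, 8L, 6L),
                        seed = 2)
  mask <- groundTruthMasks(vol)$r
  roi <- new("ROI", name = "r", hemisphere = "left",
             voxels = which(mask, arr.ind = TRUE), peak = rep(NA_real_, 3),
             centroid = c(0, 0, 0))
  prof <- regionalProfile(vol, roi, des, hrf)

  ## average-then-fit equals fit-then-average for the linear estimator
  X <- buildDesignMatrix(des, hrf)
  fitAll <- fitGLM(vol, X, whiten = FALSE)
  lin <- which(mask)
  meanBetas <- rowMeans(fitAll@coefficients[X@taskLabels, lin])
  profNoW <- {
    d4 <- dim(vol@data)
    series <- colMeans(matrix(vol@data, ncol = d4[4])[lin, ])
    f <- fitGLM(series, X, whiten = FALSE)
    f@coefficients[X@taskLabels, 1]
  }
  expect_equal(profNoW, meanBetas, tolerance = 1e-9)

  ## a 1-voxel ROI profiles that voxel alone
  one <- new("ROI", name = "v", hemisphere = "left",
             voxels = matrix(roi@voxels[1, ], 1), peak = rep(NA_real_, 3),
             centroid = c(0, 0, 0))
  p1 <- regionalProfile(vol, one, des, hrf)
  v1 <- vol@data[roi@voxels[1, 1], roi@voxels[1, 2], roi@voxels[1, 3], ]
  f1 <- fitGLM(v1, X)
  expect_equal(p1@betas, f1@coefficients[X@taskLabels, 1])

  ## noiseless profile recovery
  vol0 <- simulateVolume(des, list(spec),
                         makeNoiseModel(sigma = 0, driftAmplitude = 0),
                         hrf, dims = c(8L, 8L, 6L), seed = 2)
  p0 <- regionalProfile(vol0, roi, des, hrf)
  expect_lt(max(abs(p0@betas - amps)), 1e-6)

  empty <- new("ROI", name = "e", hemisphere = "",
               voxels = matrix(integer(0), ncol = 3),
               peak = rep(NA_real_, 3), centroid = rep(NA_real_, 3))
  expect_error(regionalProfile(vol, empty, des, hrf), "empty ROI")
})
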