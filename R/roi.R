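## ROI definition from statistical maps: 8-mm local-maximum regions, the
## MT/MST+ ipsilateral split with anterior trim, and regional condition
## profiling.

.worldCoords <- function(voxels, affine) {
  t(affine %*% t(cbind(voxels - 1L, 1)))[, 1:3, drop = FALSE]
}

#' Define ROIs around local maxima of a statistical map
#'
#' Local maxima are masked voxels whose statistic strictly exceeds all of
#' their (26-neighborhood) neighbors; a flat plateau therefore yields no
#' maxima.  Each region collects the masked voxels within \code{radius}
#' mm (Euclidean, world coordinates) of its maximum; a voxel within range
#' of several maxima joins the nearest one, ties going to the maximum with
#' the larger statistic.
#'
#' @param map a \code{\link{StatMap}} with a spatial grid.
#' @param mask logical array of voxels eligible for inclusion.
#' @param radius inclusion radius in mm (default 8).
#' @param voxelSize voxel edge lengths (mm) used when no affine is given.
#' @param affine optional 4x4 voxel-to-world affine.
#' @return List of \code{\link{ROI}} (empty for an empty mask).
#' @export
defineROIsFromPeaks <- function(map, mask, radius = 8, voxelSize = c(3, 3, 3),
                                affine = NULL) {
  d <- map@dim
  if (length(d) != 3) stop("map must carry a 3-D grid")
  if (is.null(affine)) affine <- .defaultAffine(d, voxelSize)
  stat <- array(map@statistic, dim = d)
  idx <- which(mask)
  if (length(idx) == 0) return(list())

  offsets <- .neighborOffsets(26)
  isMax <- vapply(idx, function(lin) {
    ci <- arrayInd(lin, d)
    nb <- sweep(offsets, 2, as.integer(ci), "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    lin2 <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
    all(stat[lin] > stat[lin2])
  }, logical(1))
  peaks <- idx[isMax]
  if (length(peaks) == 0) return(list())

  maskVox <- arrayInd(idx, d)
  maskWorld <- .worldCoords(maskVox, affine)
  peakVox <- arrayInd(peaks, d)
  peakWorld <- .worldCoords(peakVox, affine)
  peakStat <- stat[peaks]

  ## distance of every masked voxel to every peak
  D <- outer(rowSums(maskWorld^2), rep(1, length(peaks))) -
    2 * maskWorld %*% t(peakWorld) +
    outer(rep(1, nrow(maskWorld)), rowSums(peakWorld^2))
  D <- sqrt(pmax(D, 0))
  within <- D <= radius + 1e-9
  ## nearest peak; ties broken toward the larger-statistic peak
  assign <- vapply(seq_len(nrow(D)), function(i) {
    cand <- which(within[i, ])
    if (length(cand) == 0) return(NA_integer_)
    dm <- min(D[i, cand])
    best <- cand[D[i, cand] <= dm + 1e-9]
    as.integer(best[which.max(peakStat[best])])
  }, integer(1))

  lapply(seq_along(peaks), function(j) {
    rows <- which(assign == j)
    vox <- maskVox[rows, , drop = FALSE]
    new("ROI", name = sprintf("roi%02d", j), hemisphere = "",
        voxels = vox, peak = as.numeric(peakWorld[j, ]),
        centroid = colMeans(.worldCoords(vox, affine)))
  })
}

#' ROI accessors
#'
#' @param roi an \code{ROI}.
#' @return \code{roiVoxels}: the n-by-3 voxel index matrix;
#'   \code{roiSize}: the voxel count; \code{roiPeak}/\code{roiCentroid}:
#'   world-mm coordinates.
#' @export
roiVoxels <- function(roi) roi@voxels

#' @rdname roiVoxels
#' @export
roiSize <- function(roi) nrow(roi@voxels)

#' @rdname roiVoxels
#' @export
roiPeak <- function(roi) roi@peak

#' @rdname roiVoxels
#' @export
roiCentroid <- function(roi) roi@centroid

.largestComponent <- function(mask, connectivity = 6) {
  lab <- .labelComponents(mask, connectivity)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

#' Split the MT+ complex into MT and MST+
#'
#' MST+ is the largest connected component of the voxels significantly
#' active under ipsilateral stimulation.  MT is the largest connected
#' component of the voxels active under contralateral but not ipsilateral
#' stimulation, with any voxel lying further anterior than the median
#' anterior-axis coordinate of MST+ removed (MST+ sits anterior to MT, so
#' the trim guards MT against MST+ spillover).  The anterior axis is the
#' world y coordinate by default.
#'
#' @param contraMask,ipsiMask logical arrays on the same grid: voxels
#'   active under contralateral / ipsilateral stimulation.
#' @param voxelSize,affine grid geometry (as in
#'   \code{\link{defineROIsFromPeaks}}).
#' @param anteriorAxis world axis pointing anterior (1 = x, 2 = y, 3 = z;
#'   default 2).
#' @param connectivity neighborhood for contiguity (default 6).
#' @param hemisphere label attached to the returned regions.
#' @return List with elements \code{MT} and \code{MST} (both \code{ROI}).
#'   An empty ipsilateral mask is an error: the absence of an ipsilateral
#'   response means MST+ cannot be defined in that hemisphere (a
#'   legitimate outcome to signal, not to silently absorb).
#' @export
splitMtMst <- function(contraMask, ipsiMask, voxelSize = c(3, 3, 3),
                       affine = NULL, anteriorAxis = 2, connectivity = 6,
                       hemisphere = "") {
  if (!all(dim(contraMask) == dim(ipsiMask)))
    stop("masks must share a grid")
  if (!any(ipsiMask))
    stop("MST undefined: no ipsilateral response in this hemisphere")
  d <- dim(contraMask)
  if (is.null(affine)) affine <- .defaultAffine(d, voxelSize)

  mst <- .largestComponent(ipsiMask, connectivity)
  mtMask <- contraMask & !ipsiMask
  mt <- if (any(mtMask)) .largestComponent(mtMask, connectivity) else mtMask

  mstVox <- arrayInd(which(mst), d)
  mstWorld <- .worldCoords(mstVox, affine)
  medAnt <- stats::median(mstWorld[, anteriorAxis])

  if (any(mt)) {
    mtVox <- arrayInd(which(mt), d)
    mtWorld <- .worldCoords(mtVox, affine)
    keep <- mtWorld[, anteriorAxis] <= medAnt + 1e-9
    mtVox <- mtVox[keep, , drop = FALSE]
  } else {
    mtVox <- matrix(integer(0), ncol = 3)
  }

  mkRoi <- function(name, vox) {
    cen <- if (nrow(vox) > 0) colMeans(.worldCoords(vox, affine))
           else rep(NA_real_, 3)
    new("ROI", name = name, hemisphere = hemisphere, voxels = vox,
        peak = rep(NA_real_, 3), centroid = cen)
  }
  list(MT = mkRoi("MT", mtVox), MST = mkRoi("MST+", mstVox))
}

#' Regional condition profile
#'
#' Spatially averages the time series over the region's voxels, fits the
#' first-level GLM to the averaged series (average-then-fit; for a linear
#' model this equals fitting voxelwise and averaging the estimates) and
#' returns the per-condition amplitude estimates and percent signal
#' change.
#'
#' @param volume a \code{SyntheticVolume} or 4-D array.
#' @param roi an \code{\link{ROI}}.
#' @param design the \code{TrialSequence} the volume was acquired under.
#' @param hrf an \code{HRFModel}.
#' @param highpass high-pass cutoff (s).
#' @return A \code{\link{RegionalProfile}}.
#' @export
regionalProfile <- function(volume, roi, design, hrf = makeHRF(design@TR),
                            highpass = 128) {
  dat <- if (is(volume, "SyntheticVolume")) volume@data else volume
  if (roiSize(roi) == 0) stop("empty ROI")
  d <- dim(dat)
  vox <- roi@voxels
  if (any(vox[, 1] > d[1] | vox[, 2] > d[2] | vox[, 3] > d[3] | vox < 1))
    stop("ROI lies outside the volume grid")
  lin <- vox[, 1] + d[1] * (vox[, 2] - 1L) + d[1] * d[2] * (vox[, 3] - 1L)
  mat <- matrix(dat, nrow = prod(d[1:3]), ncol = d[4])
  series <- colMeans(mat[lin, , drop = FALSE])
  X <- buildDesignMatrix(design, hrf, nVolumes = d[4], highpass = highpass)
  fit <- fitGLM(series, X)
  betas <- fit@coefficients[fit@taskLabels, 1]
  psc <- vapply(fit@taskLabels, function(cc)
    percentSignalChange(fit, cc), numeric(1))
  new("RegionalProfile", roiName = roi@name, hemisphere = roi@hemisphere,
      betas = betas, psc = psc, runMean = fit@runMean)
}
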