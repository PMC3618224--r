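## Synthetic BOLD generation: ROI time series and 4-D volumes with known
## ground truth, AR(1) noise, slow drift and NIfTI round-tripping.

#' Construct ground-truth region and noise specifications
#'
#' \code{makeROISpec} defines a spherical region with known per-condition
#' amplitudes; \code{makeNoiseModel} the AR(1)-plus-drift noise process.
#'
#' @param name region label.
#' @param hemisphere "left" or "right".
#' @param amplitudes named numeric over the six task conditions (signal
#'   units); missing conditions default to 0.
#' @param ipsilateralResponsive does the region respond to stimulation of
#'   its own hemifield? (TRUE for MST-like regions.)
#' @param center sphere center, world mm.
#' @param radius sphere radius, mm.
#' @return \code{makeROISpec}: an \code{\link{ROISpec}};
#'   \code{makeNoiseModel}: a \code{\link{NoiseModel}}.
#' @export
makeROISpec <- function(name, hemisphere = "left", amplitudes = numeric(),
                        ipsilateralResponsive = TRUE,
                        center = c(0, 0, 0), radius = 6) {
  amp <- stats::setNames(numeric(length(.TASK_CONDITIONS)), .TASK_CONDITIONS)
  amp[names(amplitudes)] <- amplitudes
  new("ROISpec", name = name, hemisphere = hemisphere, amplitudes = amp,
      ipsilateralResponsive = ipsilateralResponsive,
      center = center, radius = radius)
}

#' @rdname makeROISpec
#' @param sigma marginal noise standard deviation (signal units).
#' @param rho lag-1 autocorrelation.
#' @param driftAmplitude,driftPeriod,driftPhase cosine drift (signal
#'   units, s, rad).
#' @param baseline constant signal level.
#' @export
makeNoiseModel <- function(sigma = 1, rho = 0.3, driftAmplitude = 2,
                           driftPeriod = 200, driftPhase = 0,
                           baseline = 100) {
  new("NoiseModel", sigma = sigma, rho = rho,
      driftAmplitude = driftAmplitude, driftPeriod = driftPeriod,
      driftPhase = driftPhase, baseline = baseline)
}

## Stationary AR(1) noise with marginal sd sigma, via recursive filtering
## of scaled innovations with a burn-in.
.ar1Noise <- function(n, sigma, rho, burn = 200L) {
  if (sigma == 0) return(numeric(n))
  e <- rnorm(n + burn, sd = sigma * sqrt(1 - rho^2))
  as.numeric(stats::filter(e, rho, method = "recursive"))[burn + seq_len(n)]
}

## Deterministic (noise-free) part of a region's signal.
.cleanSignal <- function(design, spec, noise, hrf, nVolumes) {
  R <- .designRegressors(design, hrf, nVolumes)
  amp <- .effectiveAmplitudes(spec, design)
  tVol <- (seq_len(nVolumes) - 1L) * design@TR
  drift <- noise@driftAmplitude *
    cos(2 * pi * tVol / noise@driftPeriod + noise@driftPhase)
  noise@baseline + drift + as.numeric(R %*% amp[colnames(R)])
}

## Map a region's per-condition amplitudes onto the design's regressors.
## For a block localizer the ON response is the mean of the five motion
## amplitudes, gated to zero when the stimulated hemifield is ipsilateral
## to a region that lacks ipsilateral responses (the MT/MST+ rule).
.effectiveAmplitudes <- function(spec, design) {
  if (is(design, "TrialSequence")) return(spec@amplitudes)
  amp <- mean(spec@amplitudes[.MOTION_CONDITIONS])
  ap <- design@aperture
  if (length(ap) > 0 && identical(ap$hemifield, spec@hemisphere) &&
      !spec@ipsilateralResponsive)
    amp <- 0
  c(on = amp)
}

#' Simulate one region-average BOLD time series
#'
#' Generates \code{baseline + drift + sum_c amplitude_c (onsets_c * HRF) +
#' AR(1) noise} at the design's volume times.  With \code{sigma = 0} and
#' zero drift the series equals the convolved regressors exactly, so GLM
#' fitting recovers the planted amplitudes to machine precision.
#'
#' @param design a \code{TrialSequence} or \code{BlockDesign}.
#' @param spec an \code{\link{ROISpec}} (planted amplitudes).
#' @param noise a \code{\link{NoiseModel}}.
#' @param hrf an \code{\link{HRFModel}}; must share the design's TR.
#' @param seed integer seed.
#' @param nVolumes optional override of the design's volume count.
#' @return Numeric time series of length \code{nVolumes}.
#' @export
simulateROITimeseries <- function(design, spec, noise, hrf = makeHRF(design@TR),
                                  seed = 1L, nVolumes = design@nVolumes) {
  if (abs(hrf@TR - design@TR) > 1e-9)
    stop("design and HRF must share the same TR")
  clean <- .cleanSignal(design, spec, noise, hrf, nVolumes)
  set.seed(as.integer(seed))
  clean + .ar1Noise(nVolumes, noise@sigma, noise@rho)
}

## ---------------------------------------------------------------------------
## Volumes
## ---------------------------------------------------------------------------

## Voxel-center world coordinates (mm) for a grid under an affine mapping
## 0-based indices -> mm.
.voxelWorld <- function(dims, affine) {
  idx <- as.matrix(expand.grid(i = seq_len(dims[1]) - 1L,
                               j = seq_len(dims[2]) - 1L,
                               k = seq_len(dims[3]) - 1L))
  t(affine %*% t(cbind(idx, 1)))[, 1:3, drop = FALSE]
}

.defaultAffine <- function(dims, voxelSize) {
  origin <- -(dims[1:3] - 1) / 2 * voxelSize
  a <- diag(c(voxelSize, 1))
  a[1:3, 4] <- origin
  a
}

## Logical in-sphere mask for one ROISpec.
.roiMask <- function(spec, dims, affine) {
  w <- .voxelWorld(dims, affine)
  d2 <- (w[, 1] - spec@center[1])^2 + (w[, 2] - spec@center[2])^2 +
        (w[, 3] - spec@center[3])^2
  array(d2 <= spec@radius^2 + 1e-9, dim = dims[1:3])
}

#' Simulate a 4-D synthetic BOLD volume
#'
#' Voxels inside each planted spherical region receive that region's clean
#' signal plus independent AR(1) noise; background voxels receive baseline,
#' drift and noise only.  Under a lateralized localizer design, regions
#' without ipsilateral responsiveness stay silent when the stimulated
#' hemifield matches their hemisphere.
#'
#' @inheritParams simulateROITimeseries
#' @param layout list of \code{\link{ROISpec}}.
#' @param dims integer 3-vector, spatial grid size.
#' @param voxelSize voxel edge lengths (mm, default 3).
#' @param affine optional 4x4 affine (default: grid centered on the
#'   world origin).
#' @return A \code{\link{SyntheticVolume}}.
#' @export
simulateVolume <- function(design, layout, noise, hrf = makeHRF(design@TR),
                           dims = c(20L, 20L, 12L), voxelSize = c(3, 3, 3),
                           affine = NULL, seed = 1L) {
  if (is.null(affine)) affine <- .defaultAffine(dims, voxelSize)
  nVol <- design@nVolumes
  masks <- lapply(layout, .roiMask, dims = dims, affine = affine)
  w <- .voxelWorld(dims, affine)
  for (i in seq_along(layout)) {
    if (!any(masks[[i]]))
      stop(sprintf("layout error: ROI '%s' lies outside the grid",
                   layout[[i]]@name))
  }
  nVox <- prod(dims[1:3])
  tVol <- (seq_len(nVol) - 1L) * design@TR
  drift <- noise@driftAmplitude *
    cos(2 * pi * tVol / noise@driftPeriod + noise@driftPhase)
  base <- noise@baseline + drift

  set.seed(as.integer(seed))
  dat <- matrix(0, nrow = nVol, ncol = nVox)
  for (v in seq_len(nVox))
    dat[, v] <- .ar1Noise(nVol, noise@sigma, noise@rho)
  dat <- dat + base
  for (i in seq_along(layout)) {
    clean <- .cleanSignal(design, layout[[i]], noise, hrf, nVol) -
      base   # avoid double-counting baseline + drift
    vox <- which(as.vector(masks[[i]]))
    dat[, vox] <- dat[, vox] + clean
  }
  arr <- array(t(dat), dim = c(dims[1:3], nVol))
  new("SyntheticVolume", data = arr, voxelSize = voxelSize, affine = affine,
      groundTruth = layout, seed = as.integer(seed))
}

#' Ground-truth ROI masks of a synthetic volume
#'
#' @param volume a \code{SyntheticVolume}.
#' @return Named list of logical 3-D arrays, one per planted region.
#' @export
groundTruthMasks <- function(volume) {
  dims <- dim(volume@data)
  m <- lapply(volume@groundTruth, .roiMask, dims = dims, affine = volume@affine)
  names(m) <- vapply(volume@groundTruth, function(s) s@name, character(1))
  m
}

#' Write and read synthetic volumes as NIfTI
#'
#' The 4-D data are stored as 64-bit floats so a write/read round trip is
#' bit-identical; the affine is stored in the sform.  The ground-truth
#' layout can be written alongside as a JSON sidecar.
#'
#' @param volume a \code{SyntheticVolume}.
#' @param path output path (.nii or .nii.gz).
#' @param sidecar optional JSON path for the ground-truth layout.
#' @return \code{writeSyntheticVolume}: \code{path}, invisibly;
#'   \code{readVolumeData}: the 4-D array with the affine as attribute
#'   "affine".
#' @export
writeSyntheticVolume <- function(volume, path, sidecar = NULL) {
  img <- RNifti::asNifti(volume@data)
  img <- RNifti::`sform<-`(img, structure(volume@affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  if (!is.null(sidecar)) {
    layout <- lapply(volume@groundTruth, function(s)
      list(name = s@name, hemisphere = s@hemisphere,
           amplitudes = as.list(s@amplitudes),
           ipsilateral_responsive = s@ipsilateralResponsive,
           center = s@center, radius = s@radius))
    jsonlite::write_json(layout, sidecar, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname writeSyntheticVolume
#' @export
readVolumeData <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attr(arr, "affine") <- unclass(RNifti::xform(img))
  arr
}
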