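#' @import methods
#' @importFrom stats fft pf rnorm runif sd uniroot p.adjust pt convolve
NULL

## Condition vocabulary used throughout the package.  The five motion
## conditions plus the static control are modeled in the GLM; "null"
## (fixation) periods form the implicit baseline and are never modeled.
.MOTION_CONDITIONS <- c("translational", "circular", "radial", "spiral", "random")
.TASK_CONDITIONS   <- c(.MOTION_CONDITIONS, "static")
.ALL_CONDITIONS    <- c(.TASK_CONDITIONS, "null")
.SPEED_TIERS       <- c("low", "mid", "high")

#' Condition labels
#'
#' Vocabulary helpers for the seven trial types of the event-related
#' flow-field experiment: five motion conditions (translational, circular,
#' radial, spiral, random), the static control, and the null (fixation)
#' baseline.
#'
#' @return Character vectors of condition labels.
#' @export
motionConditions <- function() .MOTION_CONDITIONS

#' @rdname motionConditions
#' @export
taskConditions <- function() .TASK_CONDITIONS

#' @rdname motionConditions
#' @export
allConditions <- function() .ALL_CONDITIONS

## ---------------------------------------------------------------------------
## Stimulus geometry and dot-field classes
## ---------------------------------------------------------------------------

#' FieldGeometry: wide-field flat-screen stimulus geometry
#'
#' Describes the projection geometry of a wide-field stimulation setup: a
#' flat screen viewed at short distance.  Angular half-extents are derived
#' from the screen half-sizes by flat-screen trigonometry
#' (\code{atan(size/distance)}); the oblique half-extent is the angle to a
#' screen corner, \code{atan(sqrt(tan^2(h) + tan^2(v)))}.
#'
#' @slot viewingDistance viewing distance in cm.
#' @slot halfWidthCm,halfHeightCm screen half-extents in cm.
#' @slot halfAngles named numeric: \code{horizontal}, \code{vertical},
#'   \code{oblique} half-extents in degrees of visual angle.
#' @export
setClass("FieldGeometry",
  representation(viewingDistance = "numeric",
                 halfWidthCm = "numeric",
                 halfHeightCm = "numeric",
                 halfAngles = "numeric"),
  validity = function(object) {
    if (object@viewingDistance <= 0 || object@halfWidthCm <= 0 ||
        object@halfHeightCm <= 0)
      return("all lengths must be positive")
    ha <- object@halfAngles
    if (!all(c("horizontal", "vertical", "oblique") %in% names(ha)))
      return("halfAngles must be named horizontal/vertical/oblique")
    if (ha["oblique"] < max(ha["horizontal"], ha["vertical"]) - 1e-9)
      return("oblique half-angle must be >= the horizontal and vertical ones")
    TRUE
  })

#' SpeedProfile: logarithmic eccentricity scaling of dot speed
#'
#' Dot speed grows logarithmically with eccentricity from \code{vMin} at the
#' screen center to \code{vMax} at the maximum (oblique) eccentricity:
#' \deqn{v(e) = v_{min} + (v_{max}-v_{min})
#'   \frac{\log(1 + e/e_0)}{\log(1 + e_{max}/e_0)}}
#' The scale parameter \eqn{e_0} is calibrated so that the number-weighted
#' mean speed over a uniformly dense rectangular field equals
#' \code{vMeanTarget}.
#'
#' @slot vMin,vMax,vMeanTarget angular speeds in deg/s.
#' @slot scaleParam calibrated logarithmic scale \eqn{e_0} (deg).
#' @slot maxEccentricity the oblique half-extent the profile was calibrated
#'   for (deg).
#' @export
setClass("SpeedProfile",
  representation(vMin = "numeric", vMax = "numeric", vMeanTarget = "numeric",
                 scaleParam = "numeric", maxEccentricity = "numeric"),
  validity = function(object) {
    if (!(object@vMin > 0 && object@vMin < object@vMeanTarget &&
          object@vMeanTarget < object@vMax))
      return("need 0 < vMin < vMeanTarget < vMax")
    if (object@scaleParam <= 0) return("scaleParam must be positive")
    TRUE
  })

#' DotFieldState: instantaneous state of a limited-lifetime dot field
#'
#' One frame of a flow-field stimulus: dot positions (deg, screen-centered,
#' x rightward, y upward), velocities (deg/s), angular sizes (deg) and ages
#' (s), together with the condition, global direction sign and simulation
#' clock.  Dots live for 350 ms and are respawned at uniform-random
#' positions, keeping the dot count (hence density) constant.
#'
#' @slot dots data.frame with columns x, y, vx, vy, size, age, birthEcc.
#' @slot condition one of the seven condition labels (no "null").
#' @slot directionSign +1 or -1, the base direction before 500-ms reversals.
#' @slot simTime current stimulus clock (s).
#' @slot frame integer frame counter (simTime = frame * dt).
#' @slot dt frame duration (s), default 1/60.
#' @slot densityTarget target density (dots/deg^2).
#' @slot rngSeed integer seed; each frame derives its own stream.
#' @slot geometry a \code{FieldGeometry}.
#' @slot profile a \code{SpeedProfile}.
#' @export
setClass("DotFieldState",
  representation(dots = "data.frame", condition = "character",
                 directionSign = "numeric", simTime = "numeric",
                 frame = "integer", dt = "numeric",
                 densityTarget = "numeric", rngSeed = "integer",
                 geometry = "FieldGeometry", profile = "SpeedProfile"),
  validity = function(object) {
    if (!object@condition %in% .TASK_CONDITIONS)
      return("unknown condition")
    if (!object@directionSign %in% c(-1, 1))
      return("directionSign must be +1 or -1")
    need <- c("x", "y", "vx", "vy", "size", "age", "birthEcc")
    if (!all(need %in% names(object@dots)))
      return("dots table misses required columns")
    if (nrow(object@dots) > 0) {
      if (any(object@dots$age < -1e-12 | object@dots$age > 0.35 + 1e-9))
        return("dot ages must lie in [0, 0.35] s")
      if (object@condition == "static" &&
          any(object@dots$vx != 0 | object@dots$vy != 0))
        return("static condition must have zero velocities")
    }
    TRUE
  })

## ---------------------------------------------------------------------------
## Experimental designs
## ---------------------------------------------------------------------------

#' TrialSequence: timed trials of the event-related flow-field run
#'
#' 105 contiguous 3-s trials (15 per condition; 5 per speed tier for each
#' motion condition; nulls as consecutive triplets after every 18 non-null
#' trials), starting at the beginning of the fifth acquired volume (t = 8 s
#' at TR = 2 s).
#'
#' @slot trials data.frame with columns onset, duration, condition,
#'   speed_tier (s, s, label, label or NA).
#' @slot TR repetition time (s).
#' @slot nVolumes number of acquired volumes.
#' @slot discardedLeadIn lead-in discarded before task onset (s).
#' @export
setClass("TrialSequence",
  representation(trials = "data.frame", TR = "numeric",
                 nVolumes = "integer", discardedLeadIn = "numeric"),
  validity = function(object) {
    tr <- object@trials
    need <- c("onset", "duration", "condition", "speed_tier")
    if (!all(need %in% names(tr))) return("trials table misses columns")
    if (nrow(tr) > 1) {
      d <- diff(tr$onset)
      if (any(abs(d - tr$duration[-nrow(tr)]) > 1e-9))
        return("trials must be contiguous (zero inter-trial interval)")
    }
    if (!all(tr$condition %in% .ALL_CONDITIONS)) return("unknown condition")
    TRUE
  })

#' BlockDesign: periodic block design (localizers and retinotopy)
#'
#' Alternating ON/OFF blocks: 8 cycles of 16 s ON + 16 s OFF (256 s) for the
#' V6 and MT/MST+ localizers, or 8 cycles of 64 s (512 s) for phase-encoded
#' retinotopy.  MT/MST+ localizers carry an aperture record (center offset,
#' diameter, hemifield) and a 2-s in/out motion reversal period.
#'
#' @slot kind one of "v6", "mtmst_left", "mtmst_right", "retinotopy".
#' @slot cycleLength full ON+OFF cycle length (s).
#' @slot nCycles number of cycles.
#' @slot onCondition,offCondition condition labels for the two block types.
#' @slot TR repetition time (s).
#' @slot nVolumes number of acquired volumes.
#' @slot aperture list(center = c(x, y) deg, diameter deg, hemifield) or
#'   empty list.
#' @slot reversalPeriod within-block motion reversal period (s; NA if none).
#' @export
setClass("BlockDesign",
  representation(kind = "character", cycleLength = "numeric",
                 nCycles = "integer", onCondition = "character",
                 offCondition = "character", TR = "numeric",
                 nVolumes = "integer", aperture = "list",
                 reversalPeriod = "numeric"),
  validity = function(object) {
    if (object@cycleLength <= 0 || object@nCycles < 1)
      return("cycle length and count must be positive")
    TRUE
  })

## ---------------------------------------------------------------------------
## Synthetic BOLD generation
## ---------------------------------------------------------------------------

#' HRFModel: canonical double-gamma hemodynamic response
#'
#' The canonical difference-of-gammas impulse response: a positive gamma
#' peaking near 5 s minus a scaled undershoot gamma peaking near 15 s,
#' normalized to unit peak.
#'
#' @slot TR sampling interval (s).
#' @slot peakDelay,undershootDelay gamma delays (s; defaults 6 and 16).
#' @slot peakDispersion,undershootDispersion gamma dispersions (defaults 1).
#' @slot undershootRatio peak/undershoot amplitude ratio (default 6).
#' @slot lengthS kernel length (s, default 32).
#' @export
setClass("HRFModel",
  representation(TR = "numeric", peakDelay = "numeric",
                 undershootDelay = "numeric", peakDispersion = "numeric",
                 undershootDispersion = "numeric", undershootRatio = "numeric",
                 lengthS = "numeric"),
  validity = function(object) {
    if (object@TR <= 0) return("TR must be positive")
    if (object@lengthS <= 0) return("kernel length must be positive")
    TRUE
  })

#' ROISpec: ground-truth region specification for synthetic volumes
#'
#' A spherical region with known per-condition response amplitudes, used as
#' planted ground truth by the synthetic BOLD generator.
#'
#' @slot name region label.
#' @slot hemisphere "left" or "right".
#' @slot amplitudes named numeric over the six task conditions (signal
#'   units; baseline 0).
#' @slot ipsilateralResponsive whether the region responds to stimulation of
#'   its own hemifield (TRUE for MST-like, FALSE for MT-like regions).
#' @slot center sphere center in world mm.
#' @slot radius sphere radius in mm.
#' @export
setClass("ROISpec",
  representation(name = "character", hemisphere = "character",
                 amplitudes = "numeric", ipsilateralResponsive = "logical",
                 center = "numeric", radius = "numeric"),
  validity = function(object) {
    if (!object@hemisphere %in% c("left", "right"))
      return("hemisphere must be left or right")
    if (!all(.TASK_CONDITIONS %in% names(object@amplitudes)))
      return("amplitudes must cover all six task conditions")
    if (object@radius <= 0) return("radius must be positive")
    if (length(object@center) != 3) return("center must be a 3-vector (mm)")
    TRUE
  })

#' NoiseModel: AR(1) noise plus slow drift
#'
#' Additive noise for synthetic BOLD series: stationary AR(1) noise with
#' marginal standard deviation \code{sigma} and lag-1 autocorrelation
#' \code{rho}, a low-frequency cosine drift, and a constant baseline.
#'
#' @slot sigma marginal noise s.d. (signal units).
#' @slot rho lag-1 autocorrelation, |rho| < 1.
#' @slot driftAmplitude cosine drift amplitude (signal units).
#' @slot driftPeriod drift period (s); chosen above the 128-s high-pass
#'   cutoff so the filter should remove it.
#' @slot driftPhase drift phase offset (rad); varies between sessions.
#' @slot baseline constant signal level.
#' @export
setClass("NoiseModel",
  representation(sigma = "numeric", rho = "numeric",
                 driftAmplitude = "numeric", driftPeriod = "numeric",
                 driftPhase = "numeric", baseline = "numeric"),
  validity = function(object) {
    if (abs(object@rho) >= 1) return("|rho| must be < 1")
    if (object@sigma < 0) return("sigma must be >= 0")
    if (object@driftPeriod <= 0) return("drift period must be positive")
    TRUE
  })

#' SyntheticVolume: 4-D synthetic BOLD volume with ground truth
#'
#' @slot data 4-D array (x, y, z, t).
#' @slot voxelSize voxel edge lengths in mm (default 3, 3, 3).
#' @slot affine 4x4 voxel-index (0-based) to world-mm mapping.
#' @slot groundTruth list of \code{ROISpec} planted in the volume.
#' @slot seed integer seed the volume was generated with.
#' @export
setClass("SyntheticVolume",
  representation(data = "array", voxelSize = "numeric", affine = "matrix",
                 groundTruth = "list", seed = "integer"),
  validity = function(object) {
    if (length(dim(object@data)) != 4) return("data must be 4-D")
    if (!all(dim(object@affine) == c(4, 4))) return("affine must be 4x4")
    TRUE
  })

## ---------------------------------------------------------------------------
## GLM estimation
## ---------------------------------------------------------------------------

#' DesignMatrix: first-level GLM design
#'
#' Task regressors (onset boxcars convolved with the canonical HRF, sampled
#' at volume times), an orthonormal discrete-cosine high-pass basis with
#' periods above the cutoff, and a constant column.
#'
#' @slot values time-by-regressor matrix.
#' @slot labels column labels.
#' @slot taskLabels labels of the task (condition) columns.
#' @slot TR repetition time (s).
#' @slot highpassCutoff high-pass period cutoff (s).
#' @slot unitPeak peak of a unit-amplitude single-trial regressor (used as
#'   the percent-signal-change scaling).
#' @export
setClass("DesignMatrix",
  representation(values = "matrix", labels = "character",
                 taskLabels = "character", TR = "numeric",
                 highpassCutoff = "numeric", unitPeak = "numeric"),
  validity = function(object) {
    if (ncol(object@values) != length(object@labels))
      return("labels must match columns")
    if (qr(object@values)$rank < ncol(object@values))
      return("design matrix is rank deficient")
    TRUE
  })

#' GLMFit: per-voxel GLM estimates after AR(1) prewhitening
#'
#' @slot coefficients regressor-by-voxel matrix of estimates.
#' @slot residVar per-voxel residual variance (whitened scale).
#' @slot dof effective residual degrees of freedom.
#' @slot rhoHat pooled lag-1 autocorrelation estimate used for whitening.
#' @slot whitened whether AR(1) whitening was applied.
#' @slot labels regressor labels.
#' @slot taskLabels task-regressor labels.
#' @slot xtxInv inverse cross-product of the whitened design (for contrasts).
#' @slot runMean per-voxel mean of the raw series (PSC denominator).
#' @slot unitPeak peak of the unit single-trial regressor, inherited from
#'   the design matrix.
#' @export
setClass("GLMFit",
  representation(coefficients = "matrix", residVar = "numeric",
                 dof = "numeric", rhoHat = "numeric", whitened = "logical",
                 labels = "character", taskLabels = "character",
                 xtxInv = "matrix", runMean = "numeric",
                 unitPeak = "numeric"),
  validity = function(object) {
    if (any(object@residVar < -1e-12)) return("residual variance must be >= 0")
    if (abs(object@rhoHat) >= 1) return("|rhoHat| must be < 1")
    TRUE
  })

#' StatMap: voxelwise F statistics and p-values
#'
#' @slot statistic numeric vector or array of F values.
#' @slot dof numerator/denominator degrees of freedom.
#' @slot p p-values, same shape as statistic.
#' @slot dim spatial grid dimensions (integer(0) for per-voxel vectors
#'   without geometry).
#' @slot thresholdMeta list recording any thresholding applied (q, extent).
#' @export
setClass("StatMap",
  representation(statistic = "numeric", dof = "numeric", p = "numeric",
                 dim = "integer", thresholdMeta = "list"),
  validity = function(object) {
    if (any(object@p < -1e-12 | object@p > 1 + 1e-12, na.rm = TRUE))
      return("p-values must lie in [0, 1]")
    if (any(object@statistic < -1e-9, na.rm = TRUE))
      return("F statistics must be >= 0")
    TRUE
  })

## ---------------------------------------------------------------------------
## ROI analysis
## ---------------------------------------------------------------------------

#' ROI: a region of interest on the voxel grid
#'
#' @slot name region label.
#' @slot hemisphere "left", "right" or "".
#' @slot voxels n-by-3 integer matrix of 1-based voxel indices.
#' @slot peak world-mm coordinate of the defining peak (NA if not
#'   peak-defined).
#' @slot centroid world-mm centroid of the voxel set.
#' @export
setClass("ROI",
  representation(name = "character", hemisphere = "character",
                 voxels = "matrix", peak = "numeric", centroid = "numeric"),
  validity = function(object) {
    if (ncol(object@voxels) != 3) return("voxels must be an n-by-3 matrix")
    TRUE
  })

#' RegionalProfile: per-condition response estimates for one region
#'
#' Obtained by spatially averaging the region's time series and fitting the
#' first-level GLM to the average.
#'
#' @slot roiName,hemisphere identifiers.
#' @slot betas named per-condition amplitude estimates (signal units).
#' @slot psc named per-condition percent signal change.
#' @slot runMean mean of the averaged raw series.
#' @export
setClass("RegionalProfile",
  representation(roiName = "character", hemisphere = "character",
                 betas = "numeric", psc = "numeric", runMean = "numeric"),
  validity = function(object) {
    if (!all(.TASK_CONDITIONS %in% names(object@betas)))
      return("betas must cover the six task conditions")
    TRUE
  })

## ---------------------------------------------------------------------------
## Motion-coherence coefficient and ANOVA
## ---------------------------------------------------------------------------

#' CoherenceProfile: the MC/MI motion-coherence coefficient
#'
#' Per hemisphere, MC is the mean amplitude over the four coherent motion
#' conditions (translational, circular, radial, spiral), MI the random
#' (incoherent) amplitude, and the coefficient their ratio MC/MI; the
#' summary is the mean and SEM of the per-hemisphere ratios.
#'
#' @slot hemispheres data.frame with columns hemisphere, mc, mi, ratio.
#' @slot meanRatio across-hemisphere mean of the ratios.
#' @slot semRatio standard error of the mean (0 for a single hemisphere).
#' @slot unstable TRUE when any |MI| < 0.05 |MC| (ratio numerically
#'   unstable); the ratio is still reported, never clamped.
#' @export
setClass("CoherenceProfile",
  representation(hemispheres = "data.frame", meanRatio = "numeric",
                 semRatio = "numeric", unstable = "logical"),
  validity = function(object) {
    h <- object@hemispheres
    if (!all(c("hemisphere", "mc", "mi", "ratio") %in% names(h)))
      return("hemisphere table misses columns")
    if (object@semRatio < 0) return("SEM must be >= 0")
    if (nrow(h) > 0 &&
        any(abs(h$ratio * h$mi - h$mc) > 1e-6 * pmax(1, abs(h$mc))))
      return("ratio * MI must equal MC")
    TRUE
  })

#' AnovaResult: a repeated-measures ANOVA effect
#'
#' @slot effect effect label.
#' @slot F F value.
#' @slot df numerator and denominator degrees of freedom.
#' @slot p p-value.
#' @slot cellMeans named per-cell means.
#' @export
setClass("AnovaResult",
  representation(effect = "character", F = "numeric", df = "numeric",
                 p = "numeric", cellMeans = "numeric"),
  validity = function(object) {
    if (object@F < -1e-12) return("F must be >= 0")
    if (length(object@df) != 2 || any(object@df < 1))
      return("df must be two positive integers")
    TRUE
  })

## ---------------------------------------------------------------------------
## Retinotopy
## ---------------------------------------------------------------------------

#' PeriodicResponse: Fourier description of a periodic BOLD response
#'
#' @slot amplitude,phase per-frequency-bin amplitude and phase (bins 0 to
#'   floor(n/2), in cycles per scan).
#' @slot n number of time points.
#' @slot stimulusBin stimulus frequency in cycles per scan (default 8).
#' @slot noiseBins bins entering the noise estimate.
#' @slot excludedBins bins excluded from both signal and noise (DC,
#'   stimulus-adjacent bins, 2nd and 3rd harmonics).
#' @export
setClass("PeriodicResponse",
  representation(amplitude = "numeric", phase = "numeric", n = "integer",
                 stimulusBin = "integer", noiseBins = "integer",
                 excludedBins = "integer"),
  validity = function(object) {
    if (object@stimulusBin >= object@n / 2)
      return("stimulus bin must be below the Nyquist bin")
    TRUE
  })

#' FieldSignMap: visual field sign from polar-angle and eccentricity maps
#'
#' @slot polar,ecc input 2-D grids (rad, deg).
#' @slot sign field-sign grid: +1 (non-mirror), -1 (mirror), NA where a
#'   gradient vanishes.
#' @export
setClass("FieldSignMap",
  representation(polar = "matrix", ecc = "matrix", sign = "matrix"),
  validity = function(object) {
    if (!all(dim(object@polar) == dim(object@ecc)) ||
        !all(dim(object@polar) == dim(object@sign)))
      return("grids must share a shape")
    TRUE
  })
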