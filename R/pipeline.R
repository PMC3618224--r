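## End-to-end orchestration: parameter-recovery studies for the MC/MI
## coefficient and the full synthetic "study run".

#' Planted amplitude table for the acceptance study
#'
#' The per-area planted amplitudes used by the coherence recovery study.
#' Each area's coherent and random amplitudes are in the exact ratio the
#' region's MC/MI coefficient should recover (V6 0.70/0.25 = 2.8 over 26
#' hemispheres; MST+ 0.715/0.50 = 1.43 over 20; CSv 0.345/-1.50 = -0.23
#' over 26), at amplitudes giving roughly 1 percent signal change on a
#' baseline of 100.
#'
#' @return data.frame with columns area, coherent, random, nHemispheres.
#' @export
plantedCoherenceTable <- function() {
  data.frame(area = c("V6", "MST+", "CSv"),
             coherent = c(0.70, 0.715, 0.345),
             random = c(0.25, 0.50, -1.50),
             nHemispheres = c(26L, 20L, 26L))
}

## Average of nVoxels independent AR(1) noise series added to a clean
## regional signal; one hemisphere of the recovery study.
.simulateHemisphereSeries <- function(clean, noise, nVoxels, nVol, seed) {
  set.seed(as.integer(seed))
  noiseMat <- matrix(0, nVol, nVoxels)
  for (v in seq_len(nVoxels))
    noiseMat[, v] <- .ar1Noise(nVol, noise@sigma, noise@rho)
  clean + rowMeans(noiseMat)
}

#' Recover the MC/MI coefficient from simulated hemispheres
#'
#' Parameter-recovery study: for each hemisphere, simulates a spherical
#' region's voxel time series under the event-related flow-field design
#' (known coherent and random amplitudes, AR(1) noise, session-specific
#' drift phase), spatially averages the voxels, fits the prewhitened GLM,
#' extracts the regional condition profile and computes the MC/MI
#' coefficient across hemispheres.
#'
#' @param coherentAmp amplitude planted for each of the four coherent
#'   conditions (signal units).
#' @param randomAmp amplitude planted for the random condition.
#' @param nHemispheres number of simulated hemispheres.
#' @param nVoxels voxels averaged per region (default 33, a 6-mm-radius
#'   sphere on the 3-mm grid).
#' @param noise a \code{NoiseModel} (default: sigma 1 on baseline 100,
#'   rho 0.3).
#' @param staticAmp amplitude planted for the static condition.
#' @param nRuns scans per hemisphere (default 6, as in the study protocol:
#'   each run has its own trial order and drift phase; per-condition
#'   estimates are averaged across runs before the ratio is taken).
#' @param designs optional list of \code{TrialSequence}, one per run;
#'   defaults to seed-derived flow-field designs (fixed across
#'   hemispheres, different between runs).
#' @param hrf an \code{HRFModel}.
#' @param seed integer seed for the whole study.
#' @return A \code{\link{CoherenceProfile}}.
#' @export
recoverCoherence <- function(coherentAmp, randomAmp, nHemispheres = 26L,
                             nVoxels = 33L, noise = makeNoiseModel(),
                             staticAmp = 0.1, nRuns = 6L, designs = NULL,
                             hrf = NULL, seed = 1L) {
  seed <- as.integer(seed)
  if (is.null(designs))
    designs <- lapply(seq_len(nRuns), function(r) buildFF3DDesign(seed + r))
  nRuns <- length(designs)
  if (is.null(hrf)) hrf <- makeHRF(designs[[1]]@TR)
  spec <- makeROISpec("region", amplitudes = c(
    translational = coherentAmp, circular = coherentAmp,
    radial = coherentAmp, spiral = coherentAmp,
    random = randomAmp, static = staticAmp))
  Xs <- lapply(designs, buildDesignMatrix, hrf = hrf)
  ## task responses are identical across hemispheres: precompute per run
  taskSignal <- lapply(seq_len(nRuns), function(r) {
    R <- .designRegressors(designs[[r]], hrf)
    as.numeric(R %*% spec@amplitudes[colnames(R)])
  })
  profiles <- vector("list", nHemispheres)
  for (h in seq_len(nHemispheres)) {
    betaRuns <- matrix(0, length(.TASK_CONDITIONS), nRuns,
                       dimnames = list(.TASK_CONDITIONS, NULL))
    pscRuns <- betaRuns
    for (r in seq_len(nRuns)) {
      set.seed(seed + 7000L + 31L * h + r)
      des <- designs[[r]]
      driftPhase <- runif(1, 0, 2 * pi)       # session-specific drift
      tVol <- (seq_len(des@nVolumes) - 1L) * des@TR
      clean <- noise@baseline + taskSignal[[r]] +
        noise@driftAmplitude *
          cos(2 * pi * tVol / noise@driftPeriod + driftPhase)
      series <- .simulateHemisphereSeries(clean, noise, nVoxels,
                                          des@nVolumes,
                                          seed + 997L * h + 101L * r)
      fit <- fitGLM(series, Xs[[r]])
      betaRuns[, r] <- fit@coefficients[fit@taskLabels, 1]
      pscRuns[, r] <- vapply(fit@taskLabels, function(cc)
        percentSignalChange(fit, cc), numeric(1))
    }
    profiles[[h]] <- new("RegionalProfile", roiName = spec@name,
                         hemisphere = if (h %% 2 == 1) "left" else "right",
                         betas = rowMeans(betaRuns), psc = rowMeans(pscRuns),
                         runMean = noise@baseline)
  }
  mcMiCoefficient(profiles)
}

#' Run the full synthetic study pipeline
#'
#' Chains the package end to end on synthetic inputs: simulates 3-s clips
#' of every motion condition and summarizes them (density, speed, dot
#' ages, reversal times); checks the design arithmetic of the
#' event-related run, the localizers and the retinotopy scans; runs the
#' MC/MI parameter-recovery study over the planted areas (V6, MST+, CSv)
#' plus the noiseless identity; and recovers a planted traveling-wave
#' phase map.  Deterministic given the seed.
#'
#' @param seed integer master seed.
#' @param outputDir optional directory for intermediate artifacts (event
#'   CSVs, clip CSV, report JSON).
#' @param clipDuration stimulus clip length (s, default 3).
#' @param areas planted-amplitude table as from
#'   \code{\link{plantedCoherenceTable}}.
#' @return Nested report list with elements \code{stimulus},
#'   \code{design}, \code{coherence}, \code{retinotopy}.
#' @export
runFullPipeline <- function(seed = 1L, outputDir = NULL, clipDuration = 3,
                            areas = plantedCoherenceTable()) {
  seed <- as.integer(seed)
  geom <- defaultFieldGeometry()
  profile <- speedTierProfile("low", geom)

  ## --- stimulus ------------------------------------------------------------
  stim <- list()
  for (cond in .MOTION_CONDITIONS) {
    frames <- simulateFlowClip(cond, duration = clipDuration,
                               profile = profile, geometry = geom,
                               seed = seed + match(cond, .MOTION_CONDITIONS))
    stim[[cond]] <- summarizeStimulus(frames)
    if (!is.null(outputDir) && cond == "translational")
      writeFrameTable(frames[1:10],
                      file.path(outputDir, "clip_translational.csv"))
  }
  stimulus <- list(
    perCondition = stim,
    maxAgeMs = 1000 * max(vapply(stim, `[[`, numeric(1), "maxAge")),
    reversalIntervalMs = 1000 * stim$radial$reversalInterval,
    meanSpeedLow = stim$radial$meanSpeed,
    meanDensity = mean(vapply(stim, `[[`, numeric(1), "meanDensity")))

  ## --- design --------------------------------------------------------------
  ff3d <- buildFF3DDesign(seed)
  loc <- buildLocalizerDesign("v6")
  ret <- buildRetinotopyDesign()
  design <- list(
    nTrials = nrow(trials(ff3d)),
    nVolumesFF3D = nVolumes(ff3d),
    scanSecondsFF3D = scanDuration(ff3d),
    scanSecondsLocalizer = scanDuration(loc),
    nVolumesRetinotopy = nVolumes(ret),
    obliqueExtentDeg = unname(fieldExtents(geom)["oblique"]))
  if (!is.null(outputDir))
    writeEventTable(ff3d, file.path(outputDir, "events_ff3d.csv"))

  ## --- coherence recovery --------------------------------------------------
  noiseless <- recoverCoherence(0.5, 0.5, nHemispheres = 2L, nVoxels = 1L,
                                noise = makeNoiseModel(sigma = 0,
                                                       driftAmplitude = 0),
                                designs = list(ff3d), seed = seed)
  designs6 <- lapply(seq_len(6L), function(r) buildFF3DDesign(seed + r))
  recov <- lapply(seq_len(nrow(areas)), function(i) {
    recoverCoherence(areas$coherent[i], areas$random[i],
                     nHemispheres = areas$nHemispheres[i],
                     designs = designs6, seed = seed + 13L * i)
  })
  names(recov) <- areas$area
  coherence <- list(
    noiselessEqualRatio = coherenceRatio(noiseless),
    areas = data.frame(
      area = areas$area,
      planted = areas$coherent / areas$random,
      recovered = vapply(recov, coherenceRatio, numeric(1)),
      sem = vapply(recov, coherenceSEM, numeric(1)),
      nHemispheres = areas$nHemispheres))

  ## --- retinotopy ----------------------------------------------------------
  wave <- simulateTravelingWave(nrow = 8, ncol = 16, nTime = 256,
                                stimulusBin = 8, phaseSlope = 0.1,
                                noiseSd = 0.05, seed = seed + 99L)
  pm <- phaseMap(wave, stimulusBin = 8, hemodynamicDelay = 0, TR = 2)
  slope <- mean(apply(pm$phase, 1, circularSlope))
  retino <- list(phaseSlope = slope, plantedSlope = 0.1,
                 minF = min(pm$F))

  report <- list(stimulus = stimulus, design = design,
                 coherence = coherence, retinotopy = retino)
  if (!is.null(outputDir)) {
    jsonlite::write_json(
      list(design = design,
           stimulus = stimulus[c("maxAgeMs", "reversalIntervalMs",
                                 "meanSpeedLow", "meanDensity")],
           coherence = coherence$areas,
           retinotopy = retino),
      file.path(outputDir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}
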