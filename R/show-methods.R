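## show() methods for the main containers.

setMethod("show", "FieldGeometry", function(object) {
  ha <- object@halfAngles
  cat(sprintf(
    "FieldGeometry: %.4g cm distance; extents %.3g x %.3g deg (oblique %.3g)\n",
    object@viewingDistance, 2 * ha["horizontal"], 2 * ha["vertical"],
    2 * ha["oblique"]))
})

setMethod("show", "SpeedProfile", function(object) {
  cat(sprintf(
    "SpeedProfile: %.3g-%.3g deg/s (target mean %.3g), log scale e0 = %.4g deg\n",
    object@vMin, object@vMax, object@vMeanTarget, object@scaleParam))
})

setMethod("show", "DotFieldState", function(object) {
  cat(sprintf(
    "DotFieldState: %s, %d dots, t = %.3f s (frame %d), density target %.3g/deg^2\n",
    object@condition, nrow(object@dots), object@simTime, object@frame,
    object@densityTarget))
})

setMethod("show", "TrialSequence", function(object) {
  tb <- table(object@trials$condition)
  cat(sprintf("TrialSequence: %d trials, %d volumes at TR %.3g s\n",
              nrow(object@trials), object@nVolumes, object@TR))
  cat("  ", paste(names(tb), tb, sep = ":", collapse = " "), "\n")
})

setMethod("show", "BlockDesign", function(object) {
  cat(sprintf("BlockDesign '%s': %d x %.3g-s cycles, %d volumes at TR %.3g s\n",
              object@kind, object@nCycles, object@cycleLength,
              object@nVolumes, object@TR))
  if (length(object@aperture) > 0)
    cat(sprintf("  aperture: %.3g deg diameter at (%.3g, %.3g), %s hemifield\n",
                object@aperture$diameter, object@aperture$center[1],
                object@aperture$center[2], object@aperture$hemifield))
})

setMethod("show", "SyntheticVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("SyntheticVolume: %d x %d x %d grid, %d volumes, %d planted ROIs\n",
              d[1], d[2], d[3], d[4], length(object@groundTruth)))
})

setMethod("show", "GLMFit", function(object) {
  cat(sprintf(
    "GLMFit: %d regressors x %d voxels, dof %.0f, rho_hat %.3f%s\n",
    nrow(object@coefficients), ncol(object@coefficients), object@dof,
    object@rhoHat, if (object@whitened) " (whitened)" else ""))
})

setMethod("show", "StatMap", function(object) {
  cat(sprintf("StatMap: F(%g, %g) over %d voxels; min p = %.3g\n",
              object@dof[1], object@dof[2], length(object@statistic),
              suppressWarnings(min(object@p, na.rm = TRUE))))
})

setMethod("show", "ROI", function(object) {
  cat(sprintf("ROI '%s'%s: %d voxels, centroid (%.1f, %.1f, %.1f) mm\n",
              object@name,
              if (nzchar(object@hemisphere))
                paste0(" [", object@hemisphere, "]") else "",
              nrow(object@voxels), object@centroid[1], object@centroid[2],
              object@centroid[3]))
})

setMethod("show", "RegionalProfile", function(object) {
  cat(sprintf("RegionalProfile '%s' [%s]:\n", object@roiName,
              object@hemisphere))
  print(round(rbind(beta = object@betas, psc = object@psc), 4))
})

setMethod("show", "CoherenceProfile", function(object) {
  cat(sprintf("CoherenceProfile: MC/MI = %.3f +/- %.3f over %d hemispheres%s\n",
              object@meanRatio, object@semRatio, nrow(object@hemispheres),
              if (object@unstable) " [unstable: |MI| near zero]" else ""))
})

setMethod("show", "AnovaResult", function(object) {
  cat(sprintf("rm-ANOVA %s: F(%g, %g) = %.3f, p = %.4g\n", object@effect,
              object@df[1], object@df[2], object@F, object@p))
})

setMethod("show", "FieldSignMap", function(object) {
  s <- object@sign
  cat(sprintf("FieldSignMap %d x %d: %d positive, %d negative, %d undefined\n",
              nrow(s), ncol(s), sum(s == 1, na.rm = TRUE),
              sum(s == -1, na.rm = TRUE), sum(is.na(s))))
})
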