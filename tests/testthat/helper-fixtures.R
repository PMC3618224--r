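## Shared fixtures, built once per test run.

fix <- new.env()

fixGeometry <- function() {
  if (is.null(fix$geom)) fix$geom <- defaultFieldGeometry()
  fix$geom
}

fixLowProfile <- function() {
  if (is.null(fix$low)) fix$low <- speedTierProfile("low", fixGeometry())
  fix$low
}

fixHRF <- function() {
  if (is.null(fix$hrf)) fix$hrf <- makeHRF(2)
  fix$hrf
}

fixFF3D <- function() {
  if (is.null(fix$ff3d)) fix$ff3d <- buildFF3DDesign(42L)
  fix$ff3d
}

fixClip <- function(condition = "radial", seed = 7L) {
  key <- paste0("clip_", condition, "_", seed)
  if (is.null(fix[[key]]))
    fix[[key]] <- simulateFlowClip(condition, duration = 3,
                                   profile = fixLowProfile(),
                                   geometry = fixGeometry(), seed = seed)
  fix[[key]]
}

## per-condition amplitudes helper (each condition defaults to zero)
ampVec <- function(tra = 0, cir = 0, rad = 0, spi = 0, rand = 0, sta = 0) {
  c(translational = tra, circular = cir, radial = rad, spiral = spi,
    random = rand, static = sta)
}

quietNoise <- function() makeNoiseModel(sigma = 0, driftAmplitude = 0)
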