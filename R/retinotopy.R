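## Phase-encoded retinotopy: stimulus-frequency F ratio, response phase,
## and visual field sign from polar-angle and eccentricity gradients.

#' Fourier F ratio at the stimulus frequency
#'
#' Decomposes a periodic time series into frequency bins (cycles per
#' scan) and forms the ratio of the power at the stimulus frequency to
#' the mean power over the noise bins.  Excluded from the noise band are
#' the DC bin, the bins adjacent to the stimulus bin (leakage guard), and
#' the 2nd and 3rd harmonics; for the default 8-cycle design on 256
#' volumes the excluded bins are therefore 0, 7, 8, 9, 16 and 24.  The
#' degrees of freedom are (2, 2 * number of noise bins).
#'
#' @param series numeric time series (length at least 4x the stimulus
#'   bin).
#' @param stimulusBin stimulus frequency in cycles per scan (default 8).
#' @return List with \code{F}, \code{df}, and the
#'   \code{\link{PeriodicResponse}} as \code{response}.
#' @export
periodicFRatio <- function(series, stimulusBin = 8L) {
  n <- length(series)
  stimulusBin <- as.integer(stimulusBin)
  if (n < 4 * stimulusBin)
    stop("insufficient data: need at least 4 time points per stimulus cycle")
  sp <- fft(series)
  nb <- floor(n / 2)
  bins <- 0:nb
  amp <- Mod(sp[bins + 1]) / n
  ph <- Arg(sp[bins + 1])
  excluded <- unique(c(0L, stimulusBin - 1L, stimulusBin + 1L,
                       2L * stimulusBin, 3L * stimulusBin))
  excluded <- excluded[excluded >= 0L & excluded <= nb]
  noise <- setdiff(bins, c(excluded, stimulusBin))
  pw <- amp^2
  Fv <- pw[stimulusBin + 1] / mean(pw[noise + 1])
  resp <- new("PeriodicResponse", amplitude = amp, phase = ph,
              n = as.integer(n), stimulusBin = stimulusBin,
              noiseBins = as.integer(noise), excludedBins = as.integer(excluded))
  list(F = Fv, df = c(2, 2 * length(noise)), response = resp)
}

#' Response phase at the stimulus frequency
#'
#' The phase of the stimulus-frequency component, corrected for a fixed
#' hemodynamic delay and wrapped to [0, 2*pi).  The sign convention makes
#' the phase equal the stimulus lag: a response shifted later by a
#' quarter cycle has phase pi/2.
#'
#' @param resp a \code{\link{PeriodicResponse}}.
#' @param hemodynamicDelay delay subtracted from the phase (s, default 5).
#' @param TR repetition time (s, default 2).
#' @return Phase in radians, in [0, 2*pi).
#' @export
responsePhase <- function(resp, hemodynamicDelay = 5, TR = 2) {
  k <- resp@stimulusBin
  if (resp@amplitude[k + 1] <= 0)
    stop("undefined phase: no power at the stimulus frequency")
  period <- resp@n * TR / k
  ph <- -resp@phase[k + 1] - 2 * pi * hemodynamicDelay / period
  ph %% (2 * pi)
}

#' Phase map of a gridded time-series array
#'
#' Convenience wrapper applying \code{\link{periodicFRatio}} and
#' \code{\link{responsePhase}} to every node of a 2-D grid of time
#' series.
#'
#' @param series 3-D array (rows, cols, time).
#' @inheritParams responsePhase
#' @param stimulusBin cycles per scan.
#' @return List of 2-D matrices \code{phase} and \code{F}.
#' @export
phaseMap <- function(series, stimulusBin = 8L, hemodynamicDelay = 5, TR = 2) {
  d <- dim(series)
  ph <- matrix(NA_real_, d[1], d[2])
  Fv <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    r <- periodicFRatio(series[i, j, ], stimulusBin)
    Fv[i, j] <- r$F
    ph[i, j] <- responsePhase(r$response, hemodynamicDelay, TR)
  }
  list(phase = ph, F = Fv)
}

#' Mean circular phase increment along a vector
#'
#' Average wrapped difference between consecutive phases (rad); the slope
#' estimator for linear phase progressions that may cross the 0/2*pi
#' boundary.
#'
#' @param phases numeric vector of phases (rad).
#' @return Mean increment in (-pi, pi].
#' @export
circularSlope <- function(phases) {
  d <- diff(phases)
  mean(atan2(sin(d), cos(d)))
}

## Central-difference gradients (one-sided at the borders) of a 2-D grid;
## x runs along columns, y along rows.
.grad2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gx <- matrix(0, nr, nc)
  gy <- matrix(0, nr, nc)
  if (nc >= 3) gx[, 2:(nc - 1)] <- (m[, 3:nc] - m[, 1:(nc - 2)]) / 2
  gx[, 1] <- m[, 2] - m[, 1]
  gx[, nc] <- m[, nc] - m[, nc - 1]
  if (nr >= 3) gy[2:(nr - 1), ] <- (m[3:nr, ] - m[1:(nr - 2), ]) / 2
  gy[1, ] <- m[2, ] - m[1, ]
  gy[nr, ] <- m[nr, ] - m[nr - 1, ]
  list(gx = gx, gy = gy)
}

#' Visual field sign from polar-angle and eccentricity maps
#'
#' Computes, at every grid node, the orientation of the local mapping
#' from cortex to visual field: the sign of the z component of the cross
#' product of the polar-angle and eccentricity gradients (central
#' differences; one-sided at borders).  The sign convention is chosen so
#' the identity (non-mirror) visual-field map gets +1 and its mirror
#' image -1.  Nodes where either gradient vanishes are undefined (NA).
#'
#' @param polar 2-D grid of polar angle (rad).
#' @param ecc 2-D grid of eccentricity (deg), same shape.
#' @return A \code{\link{FieldSignMap}}.
#' @export
fieldSign <- function(polar, ecc) {
  if (!all(dim(polar) == dim(ecc))) stop("shape mismatch between grids")
  if (nrow(polar) < 3 || ncol(polar) < 3) stop("grids must be at least 3x3")
  gp <- .grad2(polar)
  ge <- .grad2(ecc)
  cross <- gp$gx * ge$gy - gp$gy * ge$gx
  s <- -sign(cross)          # identity map (polar = atan2, ecc = r) -> +1
  zero <- (gp$gx == 0 & gp$gy == 0) | (ge$gx == 0 & ge$gy == 0)
  s[zero | cross == 0] <- NA_real_
  new("FieldSignMap", polar = polar, ecc = ecc, sign = s)
}

#' Field-sign accessor
#'
#' @param x a \code{FieldSignMap}.
#' @return The sign grid (+1, -1, NA).
#' @export
fieldSignGrid <- function(x) x@sign

#' Simulate a traveling-wave response grid
#'
#' Synthetic phase-encoded data: each node of a 2-D grid responds
#' sinusoidally at the stimulus frequency with a phase that advances
#' linearly along x (a traveling wave), plus white noise.  Used to
#' exercise phase recovery.
#'
#' @param nrow,ncol grid size.
#' @param nTime time points.
#' @param stimulusBin cycles per scan.
#' @param phaseSlope phase advance per column (rad).
#' @param amplitude,noiseSd response amplitude and noise s.d.
#' @param seed integer seed.
#' @return 3-D array (rows, cols, time).
#' @export
simulateTravelingWave <- function(nrow = 32, ncol = 32, nTime = 256,
                                  stimulusBin = 8, phaseSlope = 0.1,
                                  amplitude = 1, noiseSd = 0, seed = 1L) {
  set.seed(as.integer(seed))
  tIdx <- seq_len(nTime) - 1L
  arr <- array(0, c(nrow, ncol, nTime))
  for (j in seq_len(ncol)) {
    ph <- phaseSlope * (j - 1)
    sig <- amplitude * cos(2 * pi * stimulusBin * tIdx / nTime - ph)
    for (i in seq_len(nrow))
      arr[i, j, ] <- sig + if (noiseSd > 0) rnorm(nTime, sd = noiseSd) else 0
  }
  arr
}
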