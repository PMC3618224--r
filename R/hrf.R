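## Canonical hemodynamic response function and regressor construction.

#' Construct a canonical HRF model
#'
#' The canonical difference-of-gammas impulse response with the standard
#' parameterization: peak delay 6 s, undershoot delay 16 s, unit
#' dispersions, peak/undershoot ratio 6, 32-s kernel, normalized to unit
#' peak.  With these defaults the kernel peaks close to 5 s.
#'
#' @param TR sampling interval (s).
#' @param peakDelay,undershootDelay,peakDispersion,undershootDispersion,undershootRatio,lengthS
#'   double-gamma parameters.
#' @return An \code{\link{HRFModel}}.
#' @export
makeHRF <- function(TR = 2, peakDelay = 6, undershootDelay = 16,
                    peakDispersion = 1, undershootDispersion = 1,
                    undershootRatio = 6, lengthS = 32) {
  new("HRFModel", TR = TR, peakDelay = peakDelay,
      undershootDelay = undershootDelay, peakDispersion = peakDispersion,
      undershootDispersion = undershootDispersion,
      undershootRatio = undershootRatio, lengthS = lengthS)
}

## Continuous (un-normalized) double gamma; shape = delay / dispersion,
## scale = dispersion, following the conventional parameterization.
.hrfRaw <- function(model, t) {
  stats::dgamma(t, shape = model@peakDelay / model@peakDispersion,
                scale = model@peakDispersion) -
    stats::dgamma(t, shape = model@undershootDelay / model@undershootDispersion,
                  scale = model@undershootDispersion) / model@undershootRatio
}

## Peak of the continuous kernel, evaluated on a fine internal grid so the
## normalization does not depend on TR.
.hrfPeak <- function(model, dt = 0.01) {
  max(.hrfRaw(model, seq(0, model@lengthS, by = dt)))
}

#' Evaluate the peak-normalized canonical HRF
#'
#' \code{canonicalHRF} samples the kernel at the model's TR;
#' \code{hrfAtTimes} evaluates the same continuous kernel at arbitrary
#' times (used for fine-grid oracles and micro-time convolution).
#'
#' @param model an \code{HRFModel}.
#' @param t times (s) at which to evaluate.
#' @return Numeric kernel values (unit peak).
#' @export
canonicalHRF <- function(model = makeHRF()) {
  hrfAtTimes(model, seq(0, model@lengthS, by = model@TR))
}

#' @rdname canonicalHRF
#' @export
hrfAtTimes <- function(model, t) {
  .hrfRaw(model, t) / .hrfPeak(model)
}

## ---------------------------------------------------------------------------
## Regressor construction (shared by the simulator and the GLM so that
## noiseless parameter recovery is exact)
## ---------------------------------------------------------------------------

## Linear convolution via zero-padded FFTs (padded to a highly composite
## length so micro-time grids stay fast).
.fftConvolve <- function(u, h) {
  n <- length(u) + length(h) - 1L
  L <- stats::nextn(n, 2)
  x <- Re(fft(fft(c(u, numeric(L - length(u)))) *
              fft(c(h, numeric(L - length(h)))), inverse = TRUE)) / L
  x[seq_along(u)]
}

## Convolve an onset/duration train with the HRF on a micro-time grid and
## sample at volume acquisition times t = (i-1) * TR.
.convolveTrain <- function(onsets, durations, hrf, nVolumes, TR,
                           microDt = 0.01) {
  stopifnot(abs(TR / microDt - round(TR / microDt)) < 1e-9)
  nMicro <- as.integer(round(nVolumes * TR / microDt)) + 1L
  tMicro <- (seq_len(nMicro) - 1L) * microDt
  u <- numeric(nMicro)
  for (i in seq_along(onsets)) {
    on <- tMicro >= onsets[i] - 1e-9 & tMicro < onsets[i] + durations[i] - 1e-9
    u[on] <- u[on] + 1
  }
  h <- hrfAtTimes(hrf, seq(0, hrf@lengthS, by = microDt))
  x <- .fftConvolve(u, h) * microDt
  idx <- as.integer(round((seq_len(nVolumes) - 1L) * TR / microDt)) + 1L
  x[idx]
}

## Task regressors for a design: one column per modeled condition.
## TrialSequence -> the six stimulus conditions (null periods are the
## implicit baseline); BlockDesign -> one "on" regressor (16-s ON boxcars,
## or a full-cycle sinusoidal profile is NOT used -- blocks are boxcars).
.designRegressors <- function(design, hrf, nVolumes = NULL,
                              microDt = 0.01) {
  if (is(design, "TrialSequence")) {
    if (is.null(nVolumes)) nVolumes <- design@nVolumes
    tab <- design@trials
    conds <- .TASK_CONDITIONS
    X <- vapply(conds, function(cc) {
      rows <- tab$condition == cc
      if (!any(rows)) return(numeric(nVolumes))
      .convolveTrain(tab$onset[rows], tab$duration[rows], hrf, nVolumes,
                     design@TR, microDt)
    }, numeric(nVolumes))
    colnames(X) <- conds
    X
  } else if (is(design, "BlockDesign")) {
    if (is.null(nVolumes)) nVolumes <- design@nVolumes
    onsets <- (seq_len(design@nCycles) - 1L) * design@cycleLength
    X <- matrix(.convolveTrain(onsets, rep(design@cycleLength / 2,
                                           design@nCycles),
                               hrf, nVolumes, design@TR, microDt),
                ncol = 1, dimnames = list(NULL, "on"))
    X
  } else stop("unsupported design class")
}

## Peak of a unit-amplitude single-trial (or single-block) regressor on the
## micro-time grid; the percent-signal-change scaling.
.unitTrialPeak <- function(design, hrf, microDt = 0.01) {
  dur <- if (is(design, "TrialSequence")) design@trials$duration[1]
         else design@cycleLength / 2
  tMicro <- seq(0, dur + hrf@lengthS + 2, by = microDt)
  u <- as.numeric(tMicro < dur - 1e-9)
  h <- hrfAtTimes(hrf, seq(0, hrf@lengthS, by = microDt))
  max(.fftConvolve(u, h) * microDt)
}
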