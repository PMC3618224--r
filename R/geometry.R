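## Wide-field flat-screen geometry and the eccentricity scaling laws for
## dot speed and size.

#' Construct a wide-field stimulus geometry
#'
#' Converts screen half-extents (cm) at a given viewing distance into
#' angular half-extents by flat-screen trigonometry.  The study setup views
#' a back-projection screen at 20 cm, giving half-extents of 34.5 degrees
#' horizontally and 27.5 degrees vertically (69 x 55 degrees full extent,
#' 82 degrees along the oblique).
#'
#' @param viewingDistance viewing distance in cm (> 0).
#' @param halfWidthCm,halfHeightCm screen half-extents in cm (> 0).
#' @return A \code{\link{FieldGeometry}}.
#' @examples
#' g <- makeFieldGeometry(20, 20 * tanpi(34.5 / 180), 20 * tanpi(27.5 / 180))
#' fieldExtents(g)   # ~ c(69, 55, 82)
#' @export
makeFieldGeometry <- function(viewingDistance, halfWidthCm, halfHeightCm) {
  if (!all(is.finite(c(viewingDistance, halfWidthCm, halfHeightCm))) ||
      viewingDistance <= 0 || halfWidthCm <= 0 || halfHeightCm <= 0)
    stop("invalid geometry: all lengths must be positive and finite")
  h <- atan(halfWidthCm / viewingDistance)
  v <- atan(halfHeightCm / viewingDistance)
  obl <- atan(sqrt(tan(h)^2 + tan(v)^2))
  new("FieldGeometry",
      viewingDistance = viewingDistance,
      halfWidthCm = halfWidthCm, halfHeightCm = halfHeightCm,
      halfAngles = c(horizontal = h, vertical = v, oblique = obl) * 180 / pi)
}

#' Geometry accessors and angle/screen conversions
#'
#' \code{fieldHalfAngles} returns the angular half-extents (deg);
#' \code{fieldExtents} the full extents (2x);
#' \code{maxEccentricity} the oblique half-extent, the largest eccentricity
#' a dot can reach; \code{degToCm}/\code{cmToDeg} convert between an
#' eccentricity angle and the on-screen distance from center, inverse to
#' one another.
#'
#' @param geometry a \code{FieldGeometry}.
#' @param deg,cm values to convert.
#' @return Numeric.
#' @export
fieldHalfAngles <- function(geometry) geometry@halfAngles

#' @rdname fieldHalfAngles
#' @export
fieldExtents <- function(geometry) 2 * geometry@halfAngles

#' @rdname fieldHalfAngles
#' @export
maxEccentricity <- function(geometry) unname(geometry@halfAngles["oblique"])

#' @rdname fieldHalfAngles
#' @export
cornerEccentricity <- function(geometry) {
  ## Largest Euclidean eccentricity reachable in the flat 2-D angle
  ## coordinates the dots live in (the rectangle corner).  This exceeds the
  ## trigonometric oblique half-angle, which measures the true visual angle
  ## to the corner; the speed/size laws span the flat-coordinate range.
  unname(sqrt(geometry@halfAngles["horizontal"]^2 +
              geometry@halfAngles["vertical"]^2))
}

#' @rdname fieldHalfAngles
#' @export
degToCm <- function(geometry, deg) geometry@viewingDistance * tan(deg * pi / 180)

#' @rdname fieldHalfAngles
#' @export
cmToDeg <- function(geometry, cm) atan(cm / geometry@viewingDistance) * 180 / pi

#' The study's wide-field geometry
#'
#' The default geometry: 20-cm viewing distance with screen half-sizes
#' chosen to subtend 34.5 degrees horizontally and 27.5 degrees vertically,
#' reproducing the printed 69/55/82-degree extents.
#'
#' @return A \code{FieldGeometry}.
#' @export
defaultFieldGeometry <- function() {
  d <- 20
  makeFieldGeometry(d, d * tan(34.5 * pi / 180), d * tan(27.5 * pi / 180))
}

.inField <- function(geometry, x, y, tol = 1e-9) {
  abs(x) <= geometry@halfAngles["horizontal"] + tol &
    abs(y) <= geometry@halfAngles["vertical"] + tol
}

## Mean of the speed law over a uniformly dense rectangular field, by
## midpoint quadrature on the eccentricity e(x, y) = sqrt(x^2 + y^2).
.meanSpeedUniform <- function(vMin, vMax, e0, geometry, nGrid = 256) {
  h <- geometry@halfAngles["horizontal"]
  v <- geometry@halfAngles["vertical"]
  eMax <- cornerEccentricity(geometry)
  xs <- (seq_len(nGrid) - 0.5) / nGrid * h   # one quadrant suffices
  ys <- (seq_len(nGrid) - 0.5) / nGrid * v
  e <- sqrt(outer(xs^2, ys^2, "+"))
  mean(vMin + (vMax - vMin) * log1p(e / e0) / log1p(eMax / e0))
}

#' Construct and calibrate a speed profile
#'
#' Builds the logarithmic speed law for one of the study's three speed
#' tiers.  The scale parameter is found by a one-dimensional root search so
#' that the number-weighted mean speed over a uniformly dense field equals
#' \code{vMeanTarget}.  The study's tiers are 1-20 deg/s (mean 18), 5-50
#' (mean 30) and 10-70 (mean 50).
#'
#' @param vMin,vMax,vMeanTarget angular speeds (deg/s),
#'   0 < vMin < vMeanTarget < vMax.
#' @param geometry a \code{FieldGeometry} (defines the maximum
#'   eccentricity and the field over which the mean is taken).
#' @return A calibrated \code{\link{SpeedProfile}}.
#' @export
makeSpeedProfile <- function(vMin, vMax, vMeanTarget,
                             geometry = defaultFieldGeometry()) {
  if (!(vMin > 0 && vMin < vMeanTarget && vMeanTarget < vMax))
    stop("need 0 < vMin < vMeanTarget < vMax")
  f <- function(loge0)
    .meanSpeedUniform(vMin, vMax, exp(loge0), geometry) - vMeanTarget
  ## Small e0 saturates the law toward vMax; large e0 tends to the linear
  ## law.  The root is bracketed over a wide log range.
  root <- uniroot(f, lower = log(1e-9), upper = log(1e4), tol = 1e-12)
  new("SpeedProfile", vMin = vMin, vMax = vMax, vMeanTarget = vMeanTarget,
      scaleParam = exp(root$root),
      maxEccentricity = cornerEccentricity(geometry))
}

#' The study's three speed tiers
#'
#' @param tier "low" (1-20 deg/s, mean 18), "mid" (5-50, mean 30) or
#'   "high" (10-70, mean 50).
#' @param geometry a \code{FieldGeometry}.
#' @return A calibrated \code{SpeedProfile}.
#' @export
speedTierProfile <- function(tier = c("low", "mid", "high"),
                             geometry = defaultFieldGeometry()) {
  tier <- match.arg(tier)
  p <- switch(tier,
              low  = c(1, 20, 18),
              mid  = c(5, 50, 30),
              high = c(10, 70, 50))
  makeSpeedProfile(p[1], p[2], p[3], geometry)
}

#' Dot speed at a given eccentricity
#'
#' The calibrated logarithmic speed law: \code{vMin} at the center,
#' \code{vMax} at the maximum (oblique) eccentricity, monotone increasing.
#'
#' @param eccentricity eccentricity in deg (vectorized).
#' @param profile a \code{SpeedProfile}.
#' @param geometry the \code{FieldGeometry} the profile was calibrated for.
#' @return Angular speed(s) in deg/s.
#' @export
dotSpeed <- function(eccentricity, profile, geometry = NULL) {
  eMax <- if (is.null(geometry)) profile@maxEccentricity
          else cornerEccentricity(geometry)
  if (any(eccentricity < -1e-9 | eccentricity > eMax + 1e-9))
    stop("eccentricity outside the field")
  e0 <- profile@scaleParam
  profile@vMin + (profile@vMax - profile@vMin) *
    log1p(pmin(pmax(eccentricity, 0), eMax) / e0) / log1p(eMax / e0)
}

#' Dot angular size at a given eccentricity
#'
#' Affine map of eccentricity onto the printed 0.1-4.0 degree diameter
#' range: 0.1 deg at the center, 4.0 deg at the maximum eccentricity.
#'
#' @inheritParams dotSpeed
#' @return Angular diameter(s) in deg.
#' @export
dotSize <- function(eccentricity, geometry = defaultFieldGeometry()) {
  eMax <- cornerEccentricity(geometry)
  if (any(eccentricity < -1e-9 | eccentricity > eMax + 1e-9))
    stop("eccentricity outside the field")
  0.1 + (4.0 - 0.1) * pmin(pmax(eccentricity, 0), eMax) / eMax
}
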