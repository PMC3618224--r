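## Limited-lifetime dot-field dynamics for the seven flow-field conditions.
##
## Dots live in 2-D screen-angle coordinates (deg; x rightward, y upward);
## the eccentricity-dependent speed and size laws stand in for depth.  Dots
## age in exact frames of dt seconds, die after 350 ms (21 frames at 60 Hz)
## and respawn at uniform-random positions so the dot count -- hence the
## density -- stays constant.  Coherent conditions invert their global
## direction every 500 ms; the random condition resamples each dot's
## direction and speed at the same boundaries.

.LIFETIME_S <- 0.35
.REVERSAL_S <- 0.5

## Effective direction sign at stimulus time t: the base sign flipped once
## per elapsed 500-ms interval.
.effectiveSign <- function(baseSign, t) {
  baseSign * (-1)^(floor(t / .REVERSAL_S + 1e-9))
}

.frameSeed <- function(seed, frame) {
  as.integer((as.numeric(seed) + 1103 * as.numeric(frame)) %% 2147483647)
}

#' Local velocity of a coherent flow field
#'
#' Returns the velocity a dot at \code{position} would have under one of
#' the four coherent conditions: speed from the calibrated logarithmic law
#' at the dot's eccentricity, direction horizontal (translational), tangent
#' to the circle through the position (circular), along the radius
#' (radial), or a fixed-angle mix of the two (spiral).  At the exact center
#' the circular/radial/spiral direction is the zero vector.
#'
#' @param position numeric 2-vector (deg) or n-by-2 matrix of positions.
#' @param condition "translational", "circular", "radial" or "spiral".
#' @param directionSign +1 (rightward / counterclockwise / outward) or -1.
#' @param profile a \code{SpeedProfile}.
#' @param geometry a \code{FieldGeometry}.
#' @param spiralAngle mixing angle between radial and tangential
#'   components for the spiral condition (deg, default 45).
#' @return An n-by-2 matrix of velocities (deg/s).
#' @export
velocityField <- function(position, condition, directionSign = 1,
                          profile, geometry = defaultFieldGeometry(),
                          spiralAngle = 45) {
  if (!condition %in% c("translational", "circular", "radial", "spiral"))
    stop("unsupported condition: random/static dynamics live in stepFlow()")
  pos <- if (is.matrix(position)) position else matrix(position, ncol = 2)
  if (!all(.inField(geometry, pos[, 1], pos[, 2])))
    stop("position outside the field")
  e <- sqrt(pos[, 1]^2 + pos[, 2]^2)
  spd <- dotSpeed(e, profile, geometry)
  s <- directionSign
  ctr <- e < 1e-12
  ex <- ifelse(ctr, 0, pos[, 1] / e)   # unit radial
  ey <- ifelse(ctr, 0, pos[, 2] / e)
  tx <- -ey                            # unit tangent, counterclockwise
  ty <- ex
  v <- switch(condition,
    translational = cbind(s * spd, 0 * spd),
    circular      = cbind(s * spd * tx, s * spd * ty),
    radial        = cbind(s * spd * ex, s * spd * ey),
    spiral        = {
      a <- spiralAngle * pi / 180
      cbind(s * spd * (cos(a) * ex + sin(a) * tx),
            s * spd * (cos(a) * ey + sin(a) * ty))
    })
  v[ctr & condition != "translational", ] <- 0
  unname(v)
}

## Draw n dots uniformly over the rectangular field; velocities/sizes from
## the condition's laws at the drawn positions.  Ages are supplied by the
## caller.
.spawnDots <- function(n, state, ages, tNow) {
  g <- state@geometry
  h <- g@halfAngles["horizontal"]; v <- g@halfAngles["vertical"]
  x <- runif(n, -h, h)
  y <- runif(n, -v, v)
  e <- sqrt(x^2 + y^2)
  s <- .effectiveSign(state@directionSign, tNow)
  vel <- switch(state@condition,
    static = cbind(rep(0, n), rep(0, n)),
    random = {
      ang <- runif(n, 0, 2 * pi)
      spd <- runif(n, state@profile@vMin, state@profile@vMax)
      cbind(spd * cos(ang), spd * sin(ang))
    },
    velocityField(cbind(x, y), state@condition, s, state@profile, g))
  data.frame(x = x, y = y, vx = vel[, 1], vy = vel[, 2],
             size = dotSize(e, g), age = ages, birthEcc = e)
}

#' Initialize a dot-field state
#'
#' Creates the first frame of a flow-field clip: dot count set by the
#' density target over the rectangular field, positions uniform, ages
#' staggered uniformly over the 350-ms lifetime so deaths are spread over
#' frames, velocities from the condition's flow structure (zero for
#' static; uniform random direction and speed for random).
#'
#' @param condition one of the six stimulus conditions.
#' @param profile a \code{SpeedProfile} (also used for the random
#'   condition's speed range).
#' @param geometry a \code{FieldGeometry}.
#' @param densityTarget dots per square degree (default 0.04).
#' @param directionSign +1 or -1 base direction.
#' @param dt frame duration (s, default 1/60).
#' @param seed integer seed; the whole clip is reproducible from it.
#' @return A \code{\link{DotFieldState}} at simTime 0.
#' @export
initFlowField <- function(condition, profile,
                          geometry = defaultFieldGeometry(),
                          densityTarget = 0.04, directionSign = 1,
                          dt = 1 / 60, seed = 1L) {
  condition <- match.arg(condition, .TASK_CONDITIONS)
  area <- prod(fieldExtents(geometry)[c("horizontal", "vertical")])
  n <- max(1L, round(densityTarget * area))
  state <- new("DotFieldState",
               dots = data.frame(x = numeric(0), y = numeric(0),
                                 vx = numeric(0), vy = numeric(0),
                                 size = numeric(0), age = numeric(0),
                                 birthEcc = numeric(0)),
               condition = condition, directionSign = directionSign,
               simTime = 0, frame = 0L, dt = dt,
               densityTarget = densityTarget, rngSeed = as.integer(seed),
               geometry = geometry, profile = profile)
  set.seed(.frameSeed(seed, 0L))
  lifetimeFrames <- round(.LIFETIME_S / dt)
  ages <- sample.int(lifetimeFrames, n, replace = TRUE) - 1L
  state@dots <- .spawnDots(n, state, ages * dt, tNow = 0)
  validObject(state)
  state
}

#' Advance a dot field by one frame
#'
#' Moves every dot along its trajectory for \code{dt} seconds, ages the
#' dots, respawns those that exceed the 350-ms lifetime or exit the field,
#' and applies the 500-ms global direction reversal (coherent conditions)
#' or per-dot direction/speed resampling (random condition) when the step
#' crosses a reversal boundary.  The tangential component of circular and
#' spiral motion is applied as an exact rotation (equal to the
#' forward-Euler step to first order in dt) so a dot's eccentricity is
#' conserved along circular paths.  The static condition advances only the
#' clock.
#'
#' @param state a \code{DotFieldState}.
#' @param dt frame duration (s); must subdivide the 500-ms reversal and
#'   350-ms lifetime intervals to within one-frame tolerance.
#' @return The advanced \code{DotFieldState}.
#' @export
stepFlow <- function(state, dt = state@dt) {
  if (!is.finite(dt) || dt <= 0) stop("invalid step: dt must be positive")
  if (abs(.REVERSAL_S / dt - round(.REVERSAL_S / dt)) > 1e-6 ||
      abs(.LIFETIME_S / dt - round(.LIFETIME_S / dt)) > 1e-6)
    stop("dt must subdivide the 0.5-s reversal and 0.35-s lifetime intervals")

  tOld <- state@simTime
  tNew <- tOld + dt
  newFrame <- state@frame + 1L

  if (state@condition == "static") {
    state@simTime <- tNew
    state@frame <- newFrame
    return(state)
  }

  set.seed(.frameSeed(state@rngSeed, newFrame))
  d <- state@dots
  g <- state@geometry
  p <- state@profile
  sOld <- .effectiveSign(state@directionSign, tOld)
  sNew <- .effectiveSign(state@directionSign, tNew)

  ## --- move ---------------------------------------------------------------
  if (state@condition %in% c("translational", "radial", "random")) {
    d$x <- d$x + d$vx * dt
    d$y <- d$y + d$vy * dt
  } else {                         # circular / spiral: rotation is exact
    if (state@condition == "spiral") {
      e <- sqrt(d$x^2 + d$y^2)
      vr <- sOld * dotSpeed(e, p, g) / sqrt(2)   # radial half of the mix
      sc <- ifelse(e < 1e-12, 1, (e + vr * dt) / e)
      d$x <- d$x * sc
      d$y <- d$y * sc
    }
    e <- sqrt(d$x^2 + d$y^2)
    spd <- if (state@condition == "circular") dotSpeed(d$birthEcc, p, g)
           else dotSpeed(pmin(e, cornerEccentricity(g)), p, g) / sqrt(2)
    ang <- ifelse(e < 1e-12, 0, sOld * spd * dt / e)
    ca <- cos(ang); sa <- sin(ang)
    x2 <- d$x * ca - d$y * sa
    d$y <- d$x * sa + d$y * ca
    d$x <- x2
  }
  d$age <- d$age + dt

  ## --- respawn dead and escaped dots --------------------------------------
  gone <- d$age > .LIFETIME_S + 1e-9 | !.inField(g, d$x, d$y)
  if (any(gone)) {
    fresh <- .spawnDots(sum(gone), state, ages = 0, tNow = tNew)
    d[gone, ] <- fresh
  }

  ## --- refresh velocities --------------------------------------------------
  live <- !gone
  if (any(live)) {
    if (state@condition == "random") {
      if (floor(tNew / .REVERSAL_S + 1e-9) > floor(tOld / .REVERSAL_S + 1e-9)) {
        nl <- sum(live)
        angl <- runif(nl, 0, 2 * pi)
        spdl <- runif(nl, p@vMin, p@vMax)
        d$vx[live] <- spdl * cos(angl)
        d$vy[live] <- spdl * sin(angl)
      }
    } else if (state@condition == "translational") {
      ## constant speed over the lifetime; only the sign may flip
      if (sNew != sOld) {
        d$vx[live] <- -d$vx[live]
        d$vy[live] <- -d$vy[live]
      }
    } else {
      ## circular keeps its birth-eccentricity speed (eccentricity is
      ## conserved); radial/spiral speeds follow the current eccentricity
      e <- sqrt(d$x[live]^2 + d$y[live]^2)
      eSpd <- if (state@condition == "circular") d$birthEcc[live]
              else pmin(e, cornerEccentricity(g))
      spd <- dotSpeed(eSpd, p, g)
      ctr <- e < 1e-12
      ex <- ifelse(ctr, 0, d$x[live] / e)
      ey <- ifelse(ctr, 0, d$y[live] / e)
      vel <- switch(state@condition,
        circular = cbind(-sNew * spd * ey, sNew * spd * ex),
        radial   = cbind(sNew * spd * ex, sNew * spd * ey),
        spiral   = {
          a <- pi / 4
          cbind(sNew * spd * (cos(a) * ex - sin(a) * ey),
                sNew * spd * (cos(a) * ey + sin(a) * ex))
        })
      d$vx[live] <- vel[, 1]
      d$vy[live] <- vel[, 2]
    }
  }

  state@dots <- d
  state@simTime <- tNew
  state@frame <- newFrame
  state
}

#' Simulate a flow-field clip
#'
#' Initializes a dot field and steps it for \code{duration} seconds,
#' returning every frame.
#'
#' @inheritParams initFlowField
#' @param duration clip length (s).
#' @return List of \code{DotFieldState} frames at t = 0, dt, ...,
#'   duration - dt.
#' @export
simulateFlowClip <- function(condition, duration = 3,
                             profile = speedTierProfile("low"),
                             geometry = defaultFieldGeometry(),
                             densityTarget = 0.04, directionSign = 1,
                             dt = 1 / 60, seed = 1L) {
  nFrames <- round(duration / dt)
  state <- initFlowField(condition, profile, geometry, densityTarget,
                         directionSign, dt, seed)
  frames <- vector("list", nFrames)
  frames[[1]] <- state
  for (i in seq_len(nFrames - 1)) {
    state <- stepFlow(state, dt)
    frames[[i + 1]] <- state
  }
  frames
}

## Signed global flow statistic used to detect direction reversals.
.globalFlowSign <- function(state) {
  d <- state@dots
  e <- sqrt(d$x^2 + d$y^2)
  ok <- e > 1e-9
  switch(state@condition,
    translational = mean(d$vx),
    circular = mean((d$x[ok] * d$vy[ok] - d$y[ok] * d$vx[ok]) / e[ok]),
    mean((d$x[ok] * d$vx[ok] + d$y[ok] * d$vy[ok]) / e[ok]))
}

#' Summarize a simulated stimulus clip
#'
#' Empirical statistics of a clip: mean realized dot density (dots/deg^2),
#' mean dot speed (deg/s), maximum dot age (s), and the times (s) at which
#' the global flow direction reversed, detected as sign flips of the mean
#' directional velocity component between consecutive frames.
#'
#' @param frames list of \code{DotFieldState} as returned by
#'   \code{\link{simulateFlowClip}} (at least 1 s of frames).
#' @return List with elements \code{meanDensity}, \code{meanSpeed},
#'   \code{maxAge}, \code{reversalTimes}, \code{reversalInterval}.
#' @export
summarizeStimulus <- function(frames) {
  if (length(frames) == 0) stop("empty input: no frames to summarize")
  state1 <- frames[[1]]
  dt <- state1@dt
  if (length(frames) * dt < 1 - 1e-9)
    stop("need at least 1 s of frames")
  area <- prod(fieldExtents(state1@geometry)[c("horizontal", "vertical")])
  dens <- vapply(frames, function(s) nrow(s@dots) / area, numeric(1))
  spd <- vapply(frames, function(s) mean(sqrt(s@dots$vx^2 + s@dots$vy^2)),
                numeric(1))
  maxAge <- max(vapply(frames, function(s) max(s@dots$age), numeric(1)))
  gsign <- vapply(frames, .globalFlowSign, numeric(1))
  times <- vapply(frames, function(s) s@simTime, numeric(1))
  flips <- which(sign(gsign[-1]) != sign(gsign[-length(gsign)]) &
                 sign(gsign[-1]) != 0)
  revTimes <- times[flips + 1]
  list(meanDensity = mean(dens),
       meanSpeed = mean(spd),
       maxAge = maxAge,
       reversalTimes = revTimes,
       reversalInterval = if (length(revTimes) > 1) mean(diff(revTimes))
                          else NA_real_)
}

#' Export a clip as a per-frame dot table
#'
#' Writes one row per dot per frame with columns t, x_deg, y_deg, vx, vy,
#' size_deg, age.
#'
#' @param frames list of \code{DotFieldState}.
#' @param path CSV output path.
#' @return The data.frame, invisibly.
#' @export
writeFrameTable <- function(frames, path) {
  tab <- do.call(rbind, lapply(frames, function(s) {
    d <- s@dots
    data.frame(t = s@simTime, x_deg = d$x, y_deg = d$y,
               vx = d$vx, vy = d$vy, size_deg = d$size, age = d$age)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
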