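test_that("flat-screen geometry reproduces the wide-field extents", {
  g <- fixGeometry()
  ext <- fieldExtents(g)
  expect_equal(unname(round(ext["horizontal"])), 69)
  expect_equal(unname(round(ext["vertical"])), 55)
  expect_equal(unname(round(ext["oblique"])), 82)

  ## square screen: oblique half-angle has the closed form atan(sqrt(2))
  gs <- makeFieldGeometry(10, 10, 10)
  expect_equal(unname(fieldHalfAngles(gs)["oblique"]),
               atan(sqrt(2)) * 180 / pi, tolerance = 1e-9)

  ## independent ray-projection oracle: the angle subtended by a screen
  ## point is the angle between the central ray and the ray through it
  d <- 57.3; w <- 10
  rayAngle <- acos(sum(c(0, 0, d) * c(w, 0, d)) /
                   (d * sqrt(w^2 + d^2))) * 180 / pi
  g2 <- makeFieldGeometry(d, w, 5)
  expect_equal(unname(fieldHalfAngles(g2)["horizontal"]), rayAngle,
               tolerance = 1e-9)
  expect_equal(rayAngle, 9.899, tolerance = 1e-3)

  ## degree <-> cm conversion is self-inverse
  expect_equal(cmToDeg(g, degToCm(g, 17.3)), 17.3, tolerance = 1e-9)
  expect_error(makeFieldGeometry(-1, 10, 10), "positive")
})

test_that("speed law hits its endpoints and its calibrated mean", {
  g <- fixGeometry()
  p <- fixLowProfile()
  eMax <- cornerEccentricity(g)
  expect_equal(dotSpeed(0, p), 1)
  expect_equal(dotSpeed(eMax, p), 20)
  ## monotone non-decreasing
  e <- seq(0, eMax, length.out = 200)
  expect_true(all(diff(dotSpeed(e, p)) >= 0))
  expect_error(dotSpeed(eMax + 1, p), "outside")

  ## Monte-Carlo oracle: number-weighted mean speed over uniform dots
  set.seed(11)
  x <- runif(1e5, -fieldHalfAngles(g)["horizontal"],
             fieldHalfAngles(g)["horizontal"])
  y <- runif(1e5, -fieldHalfAngles(g)["vertical"],
             fieldHalfAngles(g)["vertical"])
  expect_equal(mean(dotSpeed(sqrt(x^2 + y^2), p)), 18, tolerance = 0.5 / 18)

  ## the other printed tiers calibrate too
  for (tier in c("mid", "high")) {
    pt <- speedTierProfile(tier, g)
    expect_equal(mean(dotSpeed(sqrt(x^2 + y^2), pt)), pt@vMeanTarget,
                 tolerance = 0.01)
  }
})

test_that("dot size is the affine 0.1-4 degree map of eccentricity", {
  g <- fixGeometry()
  eMax <- cornerEccentricity(g)
  expect_equal(dotSize(0, g), 0.1)
  expect_equal(dotSize(eMax, g), 4.0)
  expect_equal(dotSize(eMax / 2, g), 2.05)
  expect_error(dotSize(eMax + 0.1, g), "outside")
})

test_that("velocity field has the right flow structure", {
  g <- fixGeometry()
  p <- fixLowProfile()

  ## translational: horizontal, speed set by eccentricity
  v <- velocityField(c(5, 7), "translational", 1, p, g)
  expect_equal(v[1, 2], 0)
  expect_equal(v[1, 1], dotSpeed(sqrt(74), p))

  set.seed(21)
  pos <- cbind(runif(1000, -30, 30), runif(1000, -25, 25))
  ## circular is orthogonal to the radius everywhere
  vc <- velocityField(pos, "circular", 1, p, g)
  expect_lt(max(abs(rowSums(vc * pos))), 1e-9)
  ## radial outward and inward are exact negatives
  vo <- velocityField(pos, "radial", 1, p, g)
  vi <- velocityField(pos, "radial", -1, p, g)
  expect_equal(vo, -vi)
  ## speeds match the law for every condition
  e <- sqrt(rowSums(pos^2))
  for (cond in c("translational", "circular", "radial", "spiral")) {
    vv <- velocityField(pos, cond, 1, p, g)
    expect_equal(sqrt(rowSums(vv^2)), dotSpeed(e, p), tolerance = 1e-9)
  }
  ## center is degenerate for rotational/radial flow
  expect_equal(velocityField(c(0, 0), "radial", 1, p, g)[1, ], c(0, 0))
  expect_error(velocityField(c(0, 0), "random", 1, p, g), "unsupported")
})

test_that("stepping enforces lifetime, reversals and density", {
  frames <- fixClip("translational")
  s <- summarizeStimulus(frames)
  expect_lte(s$maxAge, 0.35 + 1e-9)
  expect_equal(s$meanDensity, 0.04, tolerance = 0.1)
  expect_equal(s$reversalTimes, c(0.5, 1.0, 1.5, 2.0, 2.5))

  ## velocities are negated across the 0.5-s boundary
  i49 <- which(vapply(frames, function(f) abs(f@simTime - 0.4833) < 1e-6,
                      logical(1)))
  f1 <- frames[[30]]   # t just below 0.5
  f2 <- frames[[31]]   # t = 0.5
  expect_equal(f1@simTime + f1@dt, f2@simTime)
  surv <- f2@dots$age > f1@dt   # dots alive through the flip
  expect_true(all(sign(f2@dots$vx[surv]) == -sign(f1@dots$vx[surv])))

  ## any dot stepped past 350 ms is replaced by a newborn
  ages1 <- f1@dots$age
  dying <- ages1 > 0.35 - f1@dt + 1e-9
  if (any(dying)) expect_true(any(f2@dots$age < f1@dt + 1e-9))

  ## static scenes are frozen
  st0 <- initFlowField("static", fixLowProfile(), fixGeometry(), seed = 3L)
  st <- st0
  for (i in 1:100) st <- stepFlow(st)
  expect_identical(st@dots, st0@dots)
  expect_equal(st@simTime, 100 / 60)

  expect_error(stepFlow(f1, -0.01), "invalid step")
  expect_error(stepFlow(f1, 0.013), "subdivide")
})

test_that("translational dots keep constant size and speed over a lifetime", {
  frames <- fixClip("translational")
  for (idx in c(10, 40)) {
    f1 <- frames[[idx]]; f2 <- frames[[idx + 1]]
    surv <- f2@dots$age > f1@dt
    expect_equal(f2@dots$size[surv], f1@dots$size[surv])
    expect_equal(sqrt(f2@dots$vx^2 + f2@dots$vy^2)[surv],
                 sqrt(f1@dots$vx^2 + f1@dots$vy^2)[surv], tolerance = 1e-12)
  }
})

test_that("circular flow conserves eccentricity over a lifetime", {
  frames <- fixClip("circular")
  f1 <- frames[[2]]
  e1 <- sqrt(f1@dots$x^2 + f1@dots$y^2)
  st <- f1
  for (i in 1:21) st <- stepFlow(st)
  surv <- st@dots$age > 21 * st@dt - 1e-9
  ## identify survivors by matching birth eccentricity record
  e2 <- sqrt(st@dots$x^2 + st@dots$y^2)
  drift <- abs(e2[surv] - st@dots$birthEcc[surv]) /
    pmax(st@dots$birthEcc[surv], 1e-6)
  expect_lt(max(drift), 0.005)
})

test_that("clips are seed-reproducible and seeds differ", {
  a <- simulateFlowClip("radial", duration = 1, profile = fixLowProfile(),
                        seed = 5L)
  b <- simulateFlowClip("radial", duration = 1, profile = fixLowProfile(),
                        seed = 5L)
  c <- simulateFlowClip("radial", duration = 1, profile = fixLowProfile(),
                        seed = 6L)
  expect_identical(a[[60]]@dots, b[[60]]@dots)
  expect_false(identical(a[[1]]@dots$x, c[[1]]@dots$x))
})

test_that("random condition resamples at 500-ms boundaries only", {
  frames <- fixClip("random")
  f1 <- frames[[31]]; f0 <- frames[[30]]     # across t = 0.5
  surv <- f1@dots$age > f0@dt
  expect_false(isTRUE(all.equal(f0@dots$vx[surv], f1@dots$vx[surv])))
  f2 <- frames[[32]]; f3 <- frames[[33]]     # inside an interval
  surv23 <- f3@dots$age > f2@dt
  expect_equal(f2@dots$vx[surv23], f3@dots$vx[surv23])
  ## speeds lie in the profile's range
  spd <- sqrt(f1@dots$vx^2 + f1@dots$vy^2)
  expect_true(all(spd >= 1 - 1e-9 & spd <= 20 + 1e-9))
})

test_that("summarizeStimulus validates its input", {
  expect_error(summarizeStimulus(list()), "empty input")
  expect_error(summarizeStimulus(fixClip("radial")[1:10]), "at least 1 s")
})

test_that("frame tables round-trip the dot state", {
  frames <- fixClip("radial")[1:3]
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- writeFrameTable(frames, path)
  back <- read.csv(path)
  expect_equal(nrow(back), sum(vapply(frames, function(f) nrow(f@dots),
                                      integer(1))))
  expect_equal(back$x_deg, tab$x_deg)
})
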