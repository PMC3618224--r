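## Minimal design matrix for pure-noise fits.
constantDesign <- function(n) {
  new("DesignMatrix", values = cbind(constant = rep(1, n)),
      labels = "constant", taskLabels = character(0), TR = 2,
      highpassCutoff = Inf, unitPeak = 1)
}

test_that("design matrix has the documented column structure", {
  des <- fixFF3D()
  X <- buildDesignMatrix(des, fixHRF())
  ## 6 task regressors (null is the implicit baseline) + floor(2*324/128)
  ## DCT columns + constant
  expect_equal(ncol(X@values), 6 + floor(2 * 324 / 128) + 1)
  expect_setequal(X@taskLabels, taskConditions())
  ## DCT columns are orthonormal
  dct <- X@values[, grepl("^dct", X@labels)]
  expect_lt(max(abs(crossprod(dct) - diag(ncol(dct)))), 1e-9)
  ## and orthogonal to the constant
  expect_lt(max(abs(colSums(dct))), 1e-9)
})

test_that("regressors match a fine-grid convolution oracle", {
  hrf <- fixHRF()
  ## single 3-s trial at 10 s, TR 2, via an independent dt = 0.01 s
  ## convolution
  TR <- 2; nVol <- 40
  dt <- 0.01
  tFine <- seq(0, nVol * TR, by = dt)
  u <- as.numeric(tFine >= 10 - 1e-9 & tFine < 13 - 1e-9)
  h <- hrfAtTimes(hrf, seq(0, 32, by = dt))
  xFine <- stats::convolve(u, rev(h), type = "open")[seq_along(tFine)] * dt
  oracle <- xFine[round((0:(nVol - 1)) * TR / dt) + 1]

  tab <- data.frame(onset = 10, duration = 3, condition = "translational",
                    speed_tier = "low")
  des <- new("TrialSequence", trials = tab, TR = TR, nVolumes = as.integer(nVol),
             discardedLeadIn = 0)
  X <- buildDesignMatrix(des, hrf)
  expect_lt(max(abs(X@values[, "translational"] - oracle)), 1e-3)
})

test_that("noiseless fits recover amplitudes and repeated fits agree", {
  des <- fixFF3D()
  hrf <- fixHRF()
  amps <- ampVec(tra = 2, cir = 1, rad = 0.5, spi = 1.5, rand = -1, sta = 0.2)
  spec <- makeROISpec("r", amplitudes = amps)
  nm <- makeNoiseModel(sigma = 0, driftAmplitude = 0)
  y <- simulateROITimeseries(des, spec, nm, hrf, seed = 1)
  X <- buildDesignMatrix(des, hrf)
  fit1 <- fitGLM(y, X)
  fit2 <- fitGLM(y, X)
  expect_lt(max(abs(fit1@coefficients[fit1@taskLabels, 1] - amps)), 1e-6)
  expect_identical(fit1@coefficients, fit2@coefficients)  # no hidden state
  expect_error(fitGLM(y[-1], X), "shape")
})

test_that("pooled AR(1) estimate recovers the serial correlation", {
  n <- 10000L
  X <- constantDesign(n)
  set.seed(31)
  yWhite <- rnorm(n)
  expect_equal(fitGLM(yWhite, X)@rhoHat, 0, tolerance = 0.02)

  e <- rnorm(n + 200, sd = sqrt(1 - 0.3^2))
  yAr <- as.numeric(stats::filter(e, 0.3, "recursive"))[201:(n + 200)]
  fit <- fitGLM(yAr, X)
  expect_equal(fit@rhoHat, 0.3, tolerance = 0.03 / 0.3)
  ## whitened residuals are serially flat
  yw <- c(sqrt(1 - fit@rhoHat^2) * yAr[1],
          yAr[-1] - fit@rhoHat * yAr[-n])
  rw <- yw - mean(yw)
  expect_equal(cor(rw[-1], rw[-n]), 0, tolerance = 0.03)
})

test_that("whitened statistics match a GLS oracle on AR(1) data", {
  set.seed(41)
  n <- 600L
  rho <- 0.4
  tIdx <- seq_len(n)
  Xv <- cbind(task = sin(tIdx / 7) + rnorm(n, sd = 0.1), constant = 1)
  X <- new("DesignMatrix", values = Xv, labels = colnames(Xv),
           taskLabels = "task", TR = 2, highpassCutoff = Inf, unitPeak = 1)
  e <- rnorm(n + 200, sd = sqrt(1 - rho^2))
  noise <- as.numeric(stats::filter(e, rho, "recursive"))[201:(n + 200)]
  y <- 0.5 * Xv[, 1] + noise

  fit <- fitGLM(y, X)
  tPkg <- unname(fit@coefficients["task", 1] /
                   sqrt(fit@residVar * fit@xtxInv[1, 1]))

  ## GLS oracle with the true covariance: exact AR(1) whitening at rho
  W <- function(m) rbind(sqrt(1 - rho^2) * m[1, , drop = FALSE],
                         m[-1, , drop = FALSE] - rho * m[-n, , drop = FALSE])
  Xw <- W(Xv); yw <- W(matrix(y))
  bG <- solve(crossprod(Xw), crossprod(Xw, yw))
  rG <- yw - Xw %*% bG
  s2 <- sum(rG^2) / (n - 2)
  tGls <- bG[1] / sqrt(s2 * solve(crossprod(Xw))[1, 1])
  expect_equal(tPkg, tGls, tolerance = 0.02)
})

test_that("a single-row F contrast equals the squared t", {
  set.seed(51)
  n <- 120L
  Xv <- cbind(a = rnorm(n), b = rnorm(n), constant = 1)
  X <- new("DesignMatrix", values = Xv, labels = colnames(Xv),
           taskLabels = c("a", "b"), TR = 2, highpassCutoff = Inf,
           unitPeak = 1)
  y <- rnorm(n)
  fit <- fitGLM(y, X, whiten = FALSE)
  Fm <- fContrast(fit, contrastRows(fit, list(a = c(a = 1))))
  tv <- unname(fit@coefficients["a", 1] /
                 sqrt(fit@residVar * fit@xtxInv[1, 1]))
  expect_equal(Fm@statistic, tv^2, tolerance = 1e-9)
  expect_error(fContrast(fit, matrix(1, 1, 5)), "contrast")
})

test_that("the joint motion-vs-static F has a calibrated null", {
  des <- fixFF3D()
  X <- buildDesignMatrix(des, fixHRF())
  nSim <- 500
  set.seed(1)
  Y <- matrix(rnorm(nVolumes(des) * nSim), nrow = nVolumes(des))
  fit <- fitGLM(Y, X)
  map <- fContrast(fit, motionVsStaticContrast(fit))
  rate <- mean(map@p < 0.05)
  expect_equal(rate, 0.05, tolerance = 0.01 / 0.05)
  ## and infinite signal-to-noise drives p to zero
  amps <- ampVec(tra = 1)
  spec <- makeROISpec("r", amplitudes = amps)
  y0 <- simulateROITimeseries(des, spec,
                              makeNoiseModel(sigma = 0, driftAmplitude = 0),
                              fixHRF(), seed = 2)
  f0 <- fitGLM(y0, X)
  m0 <- fContrast(f0, motionVsStaticContrast(f0))
  expect_equal(m0@p, 0)
})

test_that("BH-FDR matches the brute-force oracle and extent rule works", {
  pList <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.3, 0.9, 0.95, 1.0)
  ## brute-force oracle: reject the smallest k with p(k) <= k q / m
  bhOracle <- function(p, q) {
    ps <- sort(p)
    k <- which(ps <= seq_along(ps) * q / length(ps))
    if (length(k) == 0) rep(FALSE, length(p)) else p <= ps[max(k)]
  }
  oracle <- bhOracle(pList, 0.05)
  expect_equal(sum(oracle), 2)
  map <- new("StatMap", statistic = rep(1, 10), dof = c(1, 10), p = pList,
             dim = integer(0), thresholdMeta = list())
  got <- fdrClusterThreshold(map, q = 0.05, extent = 1)
  expect_equal(got, oracle)

  ## random p-lists agree with the oracle too
  set.seed(61)
  for (i in 1:20) {
    p <- runif(50)^2
    m <- new("StatMap", statistic = rep(1, 50), dof = c(1, 10), p = p,
             dim = integer(0), thresholdMeta = list())
    expect_equal(fdrClusterThreshold(m, 0.05, extent = 1), bhOracle(p, 0.05))
  }

  ## all p = 1 -> empty mask
  m1 <- new("StatMap", statistic = rep(0, 27), dof = c(1, 10),
            p = rep(1, 27), dim = c(3L, 3L, 3L), thresholdMeta = list())
  expect_false(any(fdrClusterThreshold(m1)))

  ## extent boundary: a 9-voxel blob dies at k = 10, a 10-voxel blob lives
  d <- c(10L, 6L, 1L)
  mk <- function(nsig) {
    p <- rep(1, prod(d)); p[seq_len(nsig)] <- 1e-6
    new("StatMap", statistic = rep(1, prod(d)), dof = c(1, 10), p = p,
        dim = d, thresholdMeta = list())
  }
  expect_false(any(fdrClusterThreshold(mk(9), extent = 10)))
  expect_equal(sum(fdrClusterThreshold(mk(10), extent = 10)), 10)
})

test_that("high-pass basis removes slow drift", {
  des <- fixFF3D()
  X <- buildDesignMatrix(des, fixHRF())
  tVol <- (seq_len(nVolumes(des)) - 1) * 2
  drift <- cos(2 * pi * tVol / 200)             # period above the cutoff
  fit <- fitGLM(drift, X, whiten = FALSE)
  resid <- drift - X@values %*% fit@coefficients[, 1]
  expect_lt(sum(resid^2) / sum(drift^2), 0.01)
})

test_that("percent signal change follows its defining identity", {
  des <- fixFF3D()
  X <- buildDesignMatrix(des, fixHRF())
  spec <- makeROISpec("r", amplitudes = ampVec(tra = 1))
  nm <- makeNoiseModel(sigma = 0, driftAmplitude = 0, baseline = 100)
  y <- simulateROITimeseries(des, spec, nm, fixHRF(), seed = 1)
  fit <- fitGLM(y, X)
  psc <- percentSignalChange(fit, "translational")
  expect_equal(psc, 100 * 1 * X@unitPeak / fit@runMean, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(unname(percentSignalChange(fit, "circular")), 0,
               tolerance = 1e-6)
  expect_error(percentSignalChange(fit, "translational", runMean = -1),
               "baseline")
})

test_that("planted percent signal change is recovered under noise", {
  des <- fixFF3D()
  hrf <- fixHRF()
  X <- buildDesignMatrix(des, hrf)
  ## plant a 0.5% PSC: beta = 0.5 * baseline / (100 * unitPeak)
  beta <- 0.5 * 100 / (100 * X@unitPeak)
  spec <- makeROISpec("r", amplitudes = ampVec(tra = beta))
  nm <- makeNoiseModel(sigma = 0.15, driftAmplitude = 0)
  recovered <- vapply(1:100, function(s) {
    y <- simulateROITimeseries(des, spec, nm, hrf, seed = s)
    unname(percentSignalChange(fitGLM(y, X), "translational"))
  }, numeric(1))
  expect_equal(mean(recovered), 0.5, tolerance = 0.02 / 0.5)
})
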