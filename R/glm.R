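## First-level GLM: design matrix with canonical HRF and DCT high-pass,
## two-pass AR(1) prewhitening, F contrasts, FDR/cluster-extent
## thresholding, percent signal change.

#' Build a first-level design matrix
#'
#' One regressor per modeled trial type (onset boxcars convolved with the
#' canonical HRF and sampled at volume times; null/fixation periods are
#' the unmodeled implicit baseline), an orthonormal discrete-cosine
#' high-pass basis with \code{floor(2 * T / highpass)} columns (periods
#' above the cutoff), and a constant column.
#'
#' @param design a \code{TrialSequence} or \code{BlockDesign}.
#' @param hrf an \code{HRFModel} sharing the design's TR.
#' @param nVolumes number of volumes (defaults to the design's).
#' @param highpass high-pass period cutoff in seconds (default 128).
#' @return A \code{\link{DesignMatrix}}.
#' @export
buildDesignMatrix <- function(design, hrf = makeHRF(design@TR),
                              nVolumes = design@nVolumes, highpass = 128) {
  if (abs(hrf@TR - design@TR) > 1e-9)
    stop("design and HRF must share the same TR")
  task <- .designRegressors(design, hrf, nVolumes)
  task <- task[, colSums(abs(task)) > 0, drop = FALSE]  # absent conditions
  dct <- .dctBasis(nVolumes, design@TR, highpass)
  X <- cbind(task, dct, constant = 1)
  labels <- colnames(X)
  new("DesignMatrix", values = X, labels = labels,
      taskLabels = colnames(task), TR = design@TR,
      highpassCutoff = highpass,
      unitPeak = .unitTrialPeak(design, hrf))
}

## Orthonormal DCT-II high-pass basis: K = floor(2 * N * TR / cutoff)
## columns with periods above the cutoff (the constant term is kept as a
## separate intercept column).
.dctBasis <- function(n, TR, cutoff) {
  K <- floor(2 * n * TR / cutoff)
  if (K < 1) return(matrix(numeric(0), nrow = n, ncol = 0))
  t <- seq_len(n)
  B <- vapply(seq_len(K), function(k)
    sqrt(2 / n) * cos(pi * (2 * t - 1) * k / (2 * n)), numeric(n))
  colnames(B) <- paste0("dct", seq_len(K))
  B
}

## Coerce Y to a time-by-voxel matrix, remembering spatial dims.
.asTimeMatrix <- function(Y) {
  if (is(Y, "SyntheticVolume")) Y <- Y@data
  if (is.array(Y) && length(dim(Y)) == 4) {
    d <- dim(Y)
    list(Y = t(matrix(Y, nrow = prod(d[1:3]), ncol = d[4])), dim = d[1:3])
  } else if (is.matrix(Y)) {
    list(Y = Y, dim = integer(0))
  } else {
    list(Y = matrix(Y, ncol = 1), dim = integer(0))
  }
}

## Pooled lag-1 autocorrelation of a residual matrix (time x voxels).
.pooledLag1 <- function(E) {
  num <- sum(E[-1, , drop = FALSE] * E[-nrow(E), , drop = FALSE])
  den <- sum(E^2)
  if (den <= 0) 0 else num / den
}

## AR(1) whitening transform: first row scaled by sqrt(1 - rho^2), then
## y_t - rho * y_{t-1}.
.whiten <- function(M, rho) {
  W <- rbind(sqrt(1 - rho^2) * M[1, , drop = FALSE],
             M[-1, , drop = FALSE] - rho * M[-nrow(M), , drop = FALSE])
  dimnames(W) <- dimnames(M)
  W
}

#' Fit the GLM with AR(1) prewhitening
#'
#' Two-pass estimation: ordinary least squares, then a pooled lag-1
#' autocorrelation of the residuals across all voxels (one rho per run,
#' the same correlation structure assumed at every voxel) with a one-step
#' bias correction from the whitened residuals, then a refit of the
#' whitened data.  This is a documented approximation to full restricted
#' maximum likelihood estimation of the AR(1) parameter.
#'
#' @param Y a numeric vector, a time-by-voxel matrix, a 4-D array or a
#'   \code{SyntheticVolume}.
#' @param X a \code{\link{DesignMatrix}}.
#' @param whiten apply AR(1) prewhitening (default TRUE).
#' @return A \code{\link{GLMFit}}; \code{fitDim(fit)} is \code{integer(0)}
#'   unless Y carried a spatial grid.
#' @export
fitGLM <- function(Y, X, whiten = TRUE) {
  ym <- .asTimeMatrix(Y)
  Ymat <- ym$Y
  Xv <- X@values
  if (nrow(Ymat) != nrow(Xv))
    stop("shape error: time series length must match design rows")
  qrX <- qr(Xv)
  B <- qr.coef(qrX, Ymat)
  rho <- 0
  if (whiten) {
    E <- Ymat - Xv %*% B
    ## an (all but) perfect fit carries no serial-correlation information
    if (sum(E^2) <= 1e-12 * max(sum(Ymat^2), 1)) whiten <- FALSE
  }
  if (whiten) {
    E <- Ymat - Xv %*% B
    rho <- .pooledLag1(E)
    Xw <- .whiten(Xv, rho)
    Yw <- .whiten(Ymat, rho)
    qrW <- qr(Xw)
    Ew <- Yw - Xw %*% qr.coef(qrW, Yw)
    rho <- max(min(rho + .pooledLag1(Ew), 0.99), -0.99)  # one-step correction
  }
  Xw <- if (whiten) .whiten(Xv, rho) else Xv
  Yw <- if (whiten) .whiten(Ymat, rho) else Ymat
  qrW <- qr(Xw)
  B <- qr.coef(qrW, Yw)
  Ew <- Yw - Xw %*% B
  dof <- nrow(Xw) - ncol(Xw)
  residVar <- colSums(Ew^2) / dof
  fit <- new("GLMFit", coefficients = B, residVar = residVar, dof = dof,
             rhoHat = rho, whitened = whiten, labels = X@labels,
             taskLabels = X@taskLabels,
             xtxInv = chol2inv(qr.R(qrW)[seq_len(ncol(Xw)),
                                         seq_len(ncol(Xw)), drop = FALSE]),
             runMean = colMeans(Ymat), unitPeak = X@unitPeak)
  attr(fit, "spatialDim") <- ym$dim
  fit
}

#' Spatial grid of a fit, if any
#'
#' @param fit a \code{GLMFit}.
#' @return Integer 3-vector or \code{integer(0)}.
#' @export
fitDim <- function(fit) {
  d <- attr(fit, "spatialDim")
  if (is.null(d)) integer(0) else d
}

#' Build a contrast matrix over the fit's regressors
#'
#' \code{contrastRows} expands rows given over task-regressor names to the
#' full regressor set; \code{motionVsStaticContrast} builds the five-row
#' motion-minus-static F contrast (each motion condition minus static).
#'
#' @param fit a \code{GLMFit} (or \code{DesignMatrix}).
#' @param rows named list/matrix of task-level contrast weights.
#' @return A rows-by-regressors matrix.
#' @export
contrastRows <- function(fit, rows) {
  labels <- fit@labels
  C <- matrix(0, nrow = length(rows), ncol = length(labels),
              dimnames = list(names(rows), labels))
  for (i in seq_along(rows)) {
    w <- rows[[i]]
    if (!all(names(w) %in% labels)) stop("contrast names unknown in design")
    C[i, names(w)] <- w
  }
  C
}

#' @rdname contrastRows
#' @export
motionVsStaticContrast <- function(fit) {
  contrastRows(fit, stats::setNames(lapply(.MOTION_CONDITIONS, function(m) {
    w <- c(1, -1); names(w) <- c(m, "static"); w
  }), paste0(.MOTION_CONDITIONS, "-static")))
}

#' F contrast on a GLM fit
#'
#' Tests the joint null that all contrast rows are zero:
#' \deqn{F = (Cb)' [C (X'X)^{-1} C']^{-1} (Cb) / (r \hat\sigma^2)}
#' with degrees of freedom (rows, effective residual dof), per voxel.
#'
#' @param fit a \code{GLMFit}.
#' @param C contrast matrix (rows by regressors), e.g. from
#'   \code{\link{motionVsStaticContrast}}.
#' @return A \code{\link{StatMap}}.
#' @export
fContrast <- function(fit, C) {
  if (ncol(C) != nrow(fit@coefficients))
    stop("contrast error: width must match the number of regressors")
  r <- nrow(C)
  CB <- C %*% fit@coefficients                  # r x V
  M <- C %*% fit@xtxInv %*% t(C)
  num <- colSums(CB * solve(M, CB))
  Fv <- num / (r * fit@residVar)
  ## perfect fits: infinite F where the effect is real, 0 where it is not
  zero <- fit@residVar <= 1e-24
  Fv[zero] <- ifelse(num[zero] > 1e-18, Inf, 0)
  p <- pf(Fv, r, fit@dof, lower.tail = FALSE)
  new("StatMap", statistic = as.numeric(Fv), dof = c(r, fit@dof),
      p = as.numeric(p), dim = fitDim(fit), thresholdMeta = list())
}

## ---------------------------------------------------------------------------
## Thresholding
## ---------------------------------------------------------------------------

## Flood-fill labeling of connected components in a 3-D logical array.
.labelComponents <- function(mask, connectivity = 6) {
  d <- dim(mask)
  offsets <- .neighborOffsets(connectivity)
  labels <- array(0L, dim = d)
  nextLab <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (labels[start] != 0L) next
    nextLab <- nextLab + 1L
    queue <- start
    labels[start] <- nextLab
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ci <- arrayInd(cur, d)
      nb <- sweep(offsets, 2, as.integer(ci), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
      lin <- lin[mask[lin] & labels[lin] == 0L]
      labels[lin] <- nextLab
      queue <- c(queue, lin)
    }
  }
  labels
}

.neighborOffsets <- function(connectivity = c(6, 18, 26)) {
  connectivity <- match.arg(as.character(connectivity), c("6", "18", "26"))
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- switch(connectivity,
                 "6"  = rowSums(abs(g)) == 1,
                 "18" = rowSums(abs(g)) <= 2,
                 "26" = rep(TRUE, nrow(g)))
  storage.mode(g) <- "integer"
  g[keep, , drop = FALSE]
}

#' FDR and cluster-extent thresholding
#'
#' Benjamini-Hochberg control of the false discovery rate on the voxelwise
#' p-values, followed by removal of connected components smaller than the
#' extent threshold (face connectivity by default).
#'
#' @param map a \code{\link{StatMap}} carrying a spatial grid.
#' @param q FDR level (default 0.05).
#' @param extent minimum cluster size in voxels (default 10).
#' @param connectivity 6, 18 or 26 (default 6).
#' @return Logical array of surviving voxels (an empty mask is a valid
#'   outcome).
#' @export
fdrClusterThreshold <- function(map, q = 0.05, extent = 10,
                                connectivity = 6) {
  keep <- p.adjust(map@p, method = "BH") <= q
  if (length(map@dim) == 3) {
    mask <- array(keep, dim = map@dim)
    lab <- .labelComponents(mask, connectivity)
    if (max(lab) > 0) {
      sizes <- tabulate(lab[lab > 0L])
      mask <- array(lab > 0L & sizes[pmax(lab, 1L)] >= extent, dim = map@dim)
    }
    mask
  } else {
    ## no geometry: contiguity along the vector index
    runs <- rle(keep)
    runs$values <- runs$values & runs$lengths >= extent
    inverse.rle(runs)
  }
}

#' Percent signal change of a condition estimate
#'
#' PSC = 100 * beta * (peak of the unit-amplitude single-trial regressor)
#' / run mean.  The scaling convention (peak of an isolated unit trial,
#' denominated by the run mean) is the package's documented choice.
#'
#' @param fit a \code{GLMFit}.
#' @param condition task regressor name.
#' @param runMean baseline denominator (defaults to the fit's run mean).
#' @return Numeric PSC per voxel (percent units).
#' @export
percentSignalChange <- function(fit, condition, runMean = fit@runMean) {
  if (any(runMean <= 0)) stop("invalid baseline: run mean must be positive")
  if (!condition %in% fit@taskLabels) stop("unknown condition regressor")
  100 * fit@coefficients[condition, ] * fit@unitPeak / runMean
}
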