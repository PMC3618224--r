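## The MC/MI motion-coherence coefficient and repeated-measures ANOVA.

#' Motion-coherence coefficient (MC/MI)
#'
#' For each hemisphere, MC is the mean amplitude over the four coherent
#' motion conditions (translational, circular, radial, spiral) and MI the
#' random (incoherent) amplitude; the coefficient is the ratio MC/MI,
#' computed per hemisphere and then averaged (ratio of means per region,
#' mean of ratios across hemispheres), summarized as mean plus or minus
#' SEM.  A coefficient of 1 means coherent and incoherent motion drive the
#' region equally; values above 1 indicate a coherence preference, and
#' negative values arise when the random condition suppresses the region
#' below baseline (as in area CSv).  Ratios are never clamped; when any
#' |MI| falls below 5 percent of |MC| the profile is flagged numerically
#' unstable.
#'
#' @param profiles list of \code{\link{RegionalProfile}} (one per
#'   hemisphere), or a data.frame with columns \code{hemisphere},
#'   \code{condition}, \code{beta}.
#' @param measure which estimate to use from profiles: "betas" or "psc".
#' @return A \code{\link{CoherenceProfile}}.
#' @export
mcMiCoefficient <- function(profiles, measure = c("betas", "psc")) {
  measure <- match.arg(measure)
  if (is.data.frame(profiles)) {
    sp <- split(profiles, profiles$hemisphere)
    amps <- lapply(sp, function(df)
      stats::setNames(df$beta, df$condition))
    hemis <- names(sp)
  } else {
    amps <- lapply(profiles, function(p) slot(p, measure))
    hemis <- vapply(profiles, function(p) p@hemisphere, character(1))
  }
  rows <- lapply(seq_along(amps), function(i) {
    a <- amps[[i]]
    if (!all(.MOTION_CONDITIONS %in% names(a)))
      stop("incomplete profile: all five motion conditions are required")
    mc <- mean(a[c("translational", "circular", "radial", "spiral")])
    mi <- unname(a["random"])
    data.frame(hemisphere = hemis[i], mc = mc, mi = mi, ratio = mc / mi)
  })
  tab <- do.call(rbind, rows)
  n <- nrow(tab)
  new("CoherenceProfile", hemispheres = tab,
      meanRatio = mean(tab$ratio),
      semRatio = if (n > 1) sd(tab$ratio) / sqrt(n) else 0,
      unstable = any(abs(tab$mi) < 0.05 * abs(tab$mc)))
}

#' Coherence-profile accessors
#'
#' @param x a \code{CoherenceProfile}.
#' @return \code{coherenceRatio}: the across-hemisphere mean MC/MI;
#'   \code{coherenceSEM}: its standard error;
#'   \code{hemisphereTable}: the per-hemisphere MC, MI and ratio.
#' @export
coherenceRatio <- function(x) x@meanRatio

#' @rdname coherenceRatio
#' @export
coherenceSEM <- function(x) x@semRatio

#' @rdname coherenceRatio
#' @export
hemisphereTable <- function(x) x@hemispheres

## ---------------------------------------------------------------------------
## Repeated-measures ANOVA (classical within-subject decomposition)
## ---------------------------------------------------------------------------

## One-way within-subject sums of squares on a subjects x conditions
## matrix: F = MS_condition / MS_(condition x subject),
## df = (k - 1, (k - 1)(n - 1)).
.rmOneway <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  gm <- mean(mat)
  condMeans <- colMeans(mat)
  subjMeans <- rowMeans(mat)
  ssCond <- n * sum((condMeans - gm)^2)
  ssSubj <- k * sum((subjMeans - gm)^2)
  ssTot <- sum((mat - gm)^2)
  ssErr <- ssTot - ssCond - ssSubj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  msErr <- ssErr / df2
  Fv <- if (ssCond <= 1e-300) 0 else ssCond / df1 / msErr
  list(F = Fv, df = c(df1, df2),
       p = pf(Fv, df1, df2, lower.tail = FALSE),
       cellMeans = condMeans)
}

#' One-way repeated-measures ANOVA
#'
#' Classical within-subject decomposition with the condition-by-subject
#' interaction as the error term.  Used for the self-motion (vection)
#' ratings and for regional amplitude profiles; with 15 subjects and 6
#' conditions the degrees of freedom are (5, 70).
#'
#' @param ratings complete numeric matrix, subjects in rows, conditions in
#'   columns (at least 2 of each).
#' @return An \code{\link{AnovaResult}}.
#' @export
rmAnovaOneway <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("unbalanced design: missing cells")
  if (nrow(ratings) < 2 || ncol(ratings) < 2)
    stop("need at least 2 subjects and 2 conditions")
  r <- .rmOneway(ratings)
  cm <- r$cellMeans
  if (is.null(names(cm))) names(cm) <- paste0("c", seq_along(cm))
  new("AnovaResult", effect = "condition", F = r$F, df = r$df, p = r$p,
      cellMeans = cm)
}

#' Region-by-condition interaction (2 x k repeated measures)
#'
#' Interaction F for a two-region, k-condition within-subject design,
#' computed as the one-way repeated-measures effect of condition on the
#' between-region difference scores; df = (k - 1, (k - 1)(n - 1)).  With
#' 20 hemisphere pairs and 6 stimulus types the dfs are (5, 95).
#'
#' @param data 3-D array subjects x regions x conditions (exactly 2
#'   regions), complete.
#' @return An \code{\link{AnovaResult}} for the interaction.
#' @export
rmAnovaRegionByCondition <- function(data) {
  d <- dim(data)
  if (length(d) != 3 || d[2] != 2)
    stop("unsupported design: exactly two regions are required")
  if (anyNA(data)) stop("unbalanced design: missing cells")
  diffs <- data[, 2, ] - data[, 1, ]            # subjects x conditions
  r <- .rmOneway(diffs)
  cm <- c(colMeans(data[, 1, , drop = TRUE]), colMeans(data[, 2, , drop = TRUE]))
  names(cm) <- c(paste0("region1.c", seq_len(d[3])),
                 paste0("region2.c", seq_len(d[3])))
  new("AnovaResult", effect = "region:condition", F = r$F, df = r$df,
      p = r$p, cellMeans = cm)
}

#' Pairwise post-hoc comparisons with Holm correction
#'
#' Paired t tests between all condition pairs with Holm-adjusted
#' p-values (the package's replacement for legacy multiple-range tests).
#'
#' @param ratings subjects x conditions matrix.
#' @return data.frame with columns a, b, t, df, p, p_adj.
#' @export
pairwiseHolmPosthoc <- function(ratings) {
  ratings <- as.matrix(ratings)
  cn <- colnames(ratings)
  if (is.null(cn)) cn <- paste0("c", seq_len(ncol(ratings)))
  pairs <- utils::combn(ncol(ratings), 2)
  res <- apply(pairs, 2, function(ij) {
    d <- ratings[, ij[1]] - ratings[, ij[2]]
    tv <- mean(d) / (sd(d) / sqrt(length(d)))
    c(t = tv, df = length(d) - 1,
      p = 2 * pt(abs(tv), length(d) - 1, lower.tail = FALSE))
  })
  out <- data.frame(a = cn[pairs[1, ]], b = cn[pairs[2, ]],
                    t = res["t", ], df = res["df", ], p = res["p", ])
  out$p_adj <- p.adjust(out$p, method = "holm")
  out
}
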