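## Experimental designs: the event-related 3D flow-field run, the block
## localizers (V6 coherent-vs-scrambled; MT/MST+ lateralized radial motion)
## and the phase-encoded retinotopy runs.

#' Build the event-related flow-field trial sequence
#'
#' 105 contiguous 3-s trials: 15 per condition for the seven conditions
#' (5 per speed tier for each of the six stimulus conditions), with the 15
#' null trials placed as consecutive triplets after every 18 non-null
#' trials.  Non-null trials are pseudo-randomized under the constraint that
#' no two consecutive trials share both condition and speed tier; the order
#' is deterministic for a given seed.  The task starts at the beginning of
#' the fifth acquired volume (t = 8 s at TR = 2 s); at that TR the run
#' needs ceil((8 + 315)/2) = 162 volumes (324 s).
#'
#' @param seed integer seed for the pseudo-randomization.
#' @param TR repetition time (s, default 2).
#' @return A \code{\link{TrialSequence}}.
#' @export
buildFF3DDesign <- function(seed = 1L, TR = 2) {
  trialDur <- 3
  leadIn <- 8
  cells <- expand.grid(condition = .TASK_CONDITIONS,
                       speed_tier = .SPEED_TIERS,
                       rep = 1:5, stringsAsFactors = FALSE)
  key <- paste(cells$condition, cells$speed_tier)

  set.seed(as.integer(seed))
  repeat {
    ord <- sample.int(nrow(cells))
    if (!any(key[ord][-1] == key[ord][-nrow(cells)])) break
  }
  nn <- cells[ord, c("condition", "speed_tier")]

  ## interleave a null triplet after every 18 non-null trials
  rows <- list()
  for (block in seq_len(5)) {
    idx <- (block - 1) * 18 + 1:18
    rows[[length(rows) + 1]] <- nn[idx, ]
    rows[[length(rows) + 1]] <- data.frame(condition = rep("null", 3),
                                           speed_tier = rep(NA_character_, 3))
  }
  trials <- do.call(rbind, rows)
  trials$onset <- leadIn + trialDur * (seq_len(nrow(trials)) - 1)
  trials$duration <- trialDur
  trials <- trials[, c("onset", "duration", "condition", "speed_tier")]
  rownames(trials) <- NULL

  total <- leadIn + trialDur * nrow(trials)
  new("TrialSequence", trials = trials, TR = TR,
      nVolumes = as.integer(ceiling(total / TR)),
      discardedLeadIn = leadIn)
}

#' Trial-sequence accessors
#'
#' @param design a \code{TrialSequence} or \code{BlockDesign}.
#' @return \code{trials}: the trial table; \code{nVolumes}: the number of
#'   acquired volumes; \code{scanDuration}: total scan time (s).
#' @export
trials <- function(design) design@trials

#' @rdname trials
#' @export
nVolumes <- function(design) design@nVolumes

#' @rdname trials
#' @export
scanDuration <- function(design) design@nVolumes * design@TR

#' Build a block localizer design
#'
#' Eight 32-s cycles (16 s ON vs 16 s OFF, 256 s, 128 volumes at TR = 2 s).
#' The V6 localizer contrasts coherent with scrambled dot-field motion.
#' The MT/MST+ localizers present 15 deg/s radial motion alternating inward
#' and outward every 2 s, restricted to a 15-degree-diameter aperture
#' centered 10 degrees left or right of fixation, so that only MST-like
#' regions respond when the stimulated hemifield is ipsilateral.
#'
#' @param kind "v6", "mtmst_left" or "mtmst_right".
#' @param TR repetition time (s, default 2).
#' @return A \code{\link{BlockDesign}}.
#' @export
buildLocalizerDesign <- function(kind = c("v6", "mtmst_left", "mtmst_right"),
                                 TR = 2) {
  kind <- match.arg(kind)
  nCycles <- 8L
  cycleLength <- 32
  aperture <- list()
  reversal <- NA_real_
  on <- "coherent"; off <- "scrambled"
  if (kind != "v6") {
    side <- if (kind == "mtmst_left") "left" else "right"
    aperture <- list(center = c(if (side == "left") -10 else 10, 0),
                     diameter = 15, hemifield = side)
    reversal <- 2
    on <- "motion"; off <- "static"
  }
  new("BlockDesign", kind = kind, cycleLength = cycleLength,
      nCycles = nCycles, onCondition = on, offCondition = off, TR = TR,
      nVolumes = as.integer(nCycles * cycleLength / TR),
      aperture = aperture, reversalPeriod = reversal)
}

#' Build the phase-encoded retinotopy design
#'
#' Periodic traveling-wave stimulation: 64-s cycles, 8 cycles per scan
#' (512 s, 256 volumes at TR = 2 s); the stimulus frequency is 8 cycles
#' per scan, with 2nd and 3rd harmonics at spectral bins 16 and 24.
#'
#' @param TR repetition time (s, default 2).
#' @return A \code{\link{BlockDesign}} with kind "retinotopy".
#' @export
buildRetinotopyDesign <- function(TR = 2) {
  new("BlockDesign", kind = "retinotopy", cycleLength = 64, nCycles = 8L,
      onCondition = "wedge", offCondition = "", TR = TR,
      nVolumes = as.integer(8 * 64 / TR), aperture = list(),
      reversalPeriod = NA_real_)
}

#' Read and write event tables
#'
#' Trial sequences round-trip losslessly through the CSV event format
#' (columns onset, duration, condition, speed_tier).
#'
#' @param design a \code{TrialSequence}.
#' @param path CSV path.
#' @param TR,nVolumes,discardedLeadIn scan parameters to attach on read.
#' @return \code{writeEventTable} returns \code{path} invisibly;
#'   \code{readEventTable} a \code{TrialSequence}.
#' @export
writeEventTable <- function(design, path) {
  utils::write.csv(design@trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventTable
#' @export
readEventTable <- function(path, TR = 2, nVolumes = NULL,
                           discardedLeadIn = 8) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$speed_tier <- as.character(tab$speed_tier)
  tab$speed_tier[tab$speed_tier %in% c("", "NA")] <- NA_character_
  if (is.null(nVolumes)) {
    total <- max(tab$onset + tab$duration)
    nVolumes <- as.integer(ceiling(total / TR))
  }
  new("TrialSequence", trials = tab, TR = TR,
      nVolumes = as.integer(nVolumes), discardedLeadIn = discardedLeadIn)
}
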