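#' Round half away from zero
#'
#' Reporting in this package rounds half-up (99.615 -> 99.62), matching
#' the convention of the session accuracy tables, rather than R's
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places, default 2.
#' @return Rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Detection accuracy from per-session counts
#'
#' `100 * (TP + TN) / (TP + FP + TN + FN)`, rounded half-up to two
#' decimals. TN counts correctly rejected non-cow objects (e.g. humans
#' discarded by the noise filter); in a detection-only setting it is
#' usually 0.
#'
#' @param TP,TN,FP,FN Non-negative integer counts (vectorised).
#' @return Accuracy percentage(s), two decimals.
#' @export
#' @examples
#' detectionAccuracy(1273, 0, 4, 0)  # 99.69
detectionAccuracy <- function(TP, TN, FP, FN) {
  total <- TP + FP + TN + FN
  if (any(total <= 0))
    stop("detection accuracy needs a positive total count")
  if (any(c(TP, TN, FP, FN) < 0))
    stop("counts must be non-negative")
  roundHalfUp(100 * (TP + TN) / total, 2)
}

#' Multi-object tracking accuracy (MOTA) from per-session counts
#'
#' The CLEAR-MOT accuracy `100 * (1 - (FN + FP + IDS) / GT)`, rounded
#' half-up to two decimals: misses, false tracks and identity switches,
#' each normalised by the ground-truth object count. Strictly decreasing
#' in each error count at fixed GT; at most 100, unbounded below.
#'
#' @param GT Ground-truth object count (> 0; vectorised).
#' @param FP,FN,IDS Non-negative error counts.
#' @return MOTA percentage(s), two decimals.
#' @export
#' @examples
#' mota(1297, 0, 2, 3)  # 99.61
mota <- function(GT, FP, FN, IDS) {
  if (any(GT <= 0)) stop("MOTA needs GT > 0")
  if (any(c(FP, FN, IDS) < 0)) stop("counts must be non-negative")
  roundHalfUp(100 * (1 - (FN + FP + IDS) / GT), 2)
}

#' Per-session metrics and their unweighted average
#'
#' Applies the relevant metric to each session's counts and reports the
#' unweighted arithmetic mean across sessions (not the pooled-count
#' metric), each rounded half-up to two decimals. Alternatively accepts a
#' numeric vector of already-computed per-session percentages and just
#' averages them.
#'
#' @param sessions Either a data frame of per-session counts (columns
#'   `TP`, `TN`, `FP`, `FN` for `metric = "detection"`; `GT`, `FP`, `FN`,
#'   `IDS` for `metric = "mota"`), or a numeric vector of per-session
#'   percentages.
#' @param metric `"detection"` or `"mota"`; ignored for numeric input.
#' @return List with `perSession` (numeric vector) and `average`.
#' @export
#' @examples
#' sessionSummary(c(100, 99.69, 100, 99.95, 100, 100))$average  # 99.94
sessionSummary <- function(sessions, metric = c("detection", "mota")) {
  if (is.numeric(sessions)) {
    per <- sessions
  } else {
    metric <- match.arg(metric)
    per <- if (metric == "detection")
      detectionAccuracy(sessions$TP, sessions$TN, sessions$FP, sessions$FN)
    else
      mota(sessions$GT, sessions$FP, sessions$FN, sessions$IDS)
  }
  if (length(per) == 0L) stop("at least one session is required")
  list(perSession = per, average = roundHalfUp(mean(per), 2))
}

#' Bundled example session count tables
#'
#' Per-session detection and tracking tallies from a three-day overhead
#' depth-camera deployment on a working dairy farm (morning and evening
#' milking-path sessions, 56--64 cows each), shipped as plain CSV so the
#' accuracy metrics can be recomputed from raw counts. The `reported_pct`
#' column holds the accuracy figure reported for each session at the
#' time; one detection session's reported figure (4 Sept PM) is not
#' consistent with its own counts and is kept as-is (see the package
#' vignette).
#'
#' @param metric `"detection"` (columns `TP`, `TN`, `FP`, `FN`) or
#'   `"tracking"` (columns `GT`, `FP`, `FN`, `IDS`).
#' @return Data frame with columns `date`, `time`, `cows`, the counts,
#'   and `reported_pct`.
#' @export
#' @examples
#' head(exampleSessionCounts("detection"))
exampleSessionCounts <- function(metric = c("detection", "tracking")) {
  metric <- match.arg(metric)
  path <- system.file("extdata",
                      sprintf("session_counts_%s.csv", metric),
                      package = "DepthHerd", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Build per-frame prediction records from a tracking run
#'
#' Packages detector output plus tracker assignments in the structure
#' consumed by [scoreRun()]: one record per frame with every region's box,
#' assigned track ID (NA for rejected regions) and kind.
#'
#' @param regionsByFrame Per-frame lists of [InstanceRegion-class]
#'   (after [noiseFilter()]).
#' @param assignments Assignment data frame from [runTracker()].
#' @param frameIndices Integer frame indices, default positional.
#' @return List of records `list(frame, objects)`.
#' @export
predictionsFromRun <- function(regionsByFrame, assignments,
                               frameIndices = NULL) {
  if (is.null(frameIndices))
    frameIndices <- seq_along(regionsByFrame) - 1L
  lapply(seq_along(regionsByFrame), function(k) {
    regs <- regionsByFrame[[k]]
    objs <- lapply(seq_along(regs), function(i) {
      a <- assignments$track_id[assignments$frame_index == frameIndices[k] &
                                assignments$region_ordinal == i]
      list(box = regs[[i]]@box,
           track_id = if (length(a)) a[1L] else NA_integer_,
           kind = regs[[i]]@kind)
    })
    list(frame = frameIndices[k], objects = objs)
  })
}

#' Score a pipeline run against ground truth
#'
#' Tallies the counts the session metrics consume. Detection, per frame:
#' a kept (kind `"cow"`) prediction matching a ground-truth cow box with
#' IOU at or above `iouThreshold` is a TP; an unmatched kept prediction
#' is an FP; an unmatched ground-truth cow is an FN; a rejected region
#' that does not correspond to a cow (e.g. a human blob) is a TN.
#' Tracking follows the CLEAR-MOT convention: per-frame misses (FN) and
#' false tracks (FP), plus an identity switch (IDS) whenever a
#' ground-truth identity's matched track ID differs from its previously
#' matched ID.
#'
#' Ground-truth objects whose visible footprint fraction is below
#' `minVisibility` are ignore regions, as in the common multi-object
#' tracking benchmarks: they are not counted as misses, and predictions
#' matching only them count neither as false positives nor towards
#' identity switches. This covers animals partially cut off at the frame
#' edge while entering or leaving the field of view.
#'
#' @param predictions Per-frame prediction records from
#'   [predictionsFromRun()].
#' @param truth Ground-truth records (see [readGroundTruth()]).
#' @param iouThreshold Match threshold, default 0.5.
#' @param minVisibility Ignore ground-truth objects below this visible
#'   fraction, default 0.25.
#' @return List with `detection` (`TP`, `TN`, `FP`, `FN`, `accuracy`) and
#'   `tracking` (`GT`, `FP`, `FN`, `IDS`, `mota`). The percentages are
#'   `NA` when nothing was tallied (all counts zero).
#' @export
scoreRun <- function(predictions, truth, iouThreshold = 0.5,
                     minVisibility = 0.25) {
  truthByFrame <- stats::setNames(truth,
    vapply(truth, `[[`, integer(1), "frame"))
  TP <- TN <- FP <- FN <- 0L
  tGT <- tFP <- tFN <- tIDS <- 0L
  lastTrackOfGt <- list()
  for (rec in predictions) {
    gt <- truthByFrame[[as.character(rec$frame)]]
    if (is.null(gt))
      stop("ground truth does not cover frame ", rec$frame)
    objs <- gt$objects
    isCow <- vapply(objs, function(o) o$label != "human", logical(1))
    vis <- vapply(objs, `[[`, numeric(1), "visibility")
    cowVisible <- which(isCow & vis >= minVisibility)
    cowIgnored <- which(isCow & vis < minVisibility)
    humans <- which(!isCow)
    kept <- which(vapply(rec$objects, function(o) o$kind == "cow",
                         logical(1)))
    rejected <- setdiff(seq_along(rec$objects), kept)

    ## greedy IOU matching: kept predictions vs visible ground-truth cows
    matchGt <- integer(0)
    matchPred <- integer(0)
    if (length(kept) && length(cowVisible)) {
      cand <- NULL
      for (gi in cowVisible) for (pi in kept) {
        v <- boxIOU(objs[[gi]]$box, rec$objects[[pi]]$box)
        if (v >= iouThreshold) cand <- rbind(cand, c(gi, pi, v))
      }
      if (!is.null(cand)) {
        for (k in order(-cand[, 3L])) {
          gi <- cand[k, 1L]; pi <- cand[k, 2L]
          if (gi %in% matchGt || pi %in% matchPred) next
          matchGt <- c(matchGt, gi)
          matchPred <- c(matchPred, pi)
        }
      }
    }

    matchesIgnored <- function(pi) {
      length(cowIgnored) > 0L && any(vapply(cowIgnored, function(gi)
        boxIOU(objs[[gi]]$box, rec$objects[[pi]]$box) >= iouThreshold,
        logical(1)))
    }
    matchesHuman <- function(pi) {
      length(humans) > 0L && any(vapply(humans, function(gi)
        boxIOU(objs[[gi]]$box, rec$objects[[pi]]$box) >= iouThreshold,
        logical(1)))
    }
    matchesVisibleCow <- function(pi) {
      length(cowVisible) > 0L && any(vapply(cowVisible, function(gi)
        boxIOU(objs[[gi]]$box, rec$objects[[pi]]$box) >= iouThreshold,
        logical(1)))
    }

    ## detection tallies
    TP <- TP + length(matchPred)
    for (pi in setdiff(kept, matchPred))
      if (!matchesIgnored(pi)) FP <- FP + 1L
    FN <- FN + length(setdiff(cowVisible, matchGt))
    for (pi in rejected)
      if (!matchesVisibleCow(pi) && !matchesIgnored(pi)) TN <- TN + 1L

    ## CLEAR-MOT tallies
    tGT <- tGT + length(cowVisible)
    tFN <- tFN + length(setdiff(cowVisible, matchGt))
    for (pi in setdiff(kept, matchPred))
      if (!matchesIgnored(pi)) tFP <- tFP + 1L
    for (k in seq_along(matchGt)) {
      gid <- as.character(objs[[matchGt[k]]]$track_id)
      tid <- rec$objects[[matchPred[k]]]$track_id
      prev <- lastTrackOfGt[[gid]]
      if (!is.null(prev) && !is.na(tid) && prev != tid)
        tIDS <- tIDS + 1L
      lastTrackOfGt[[gid]] <- tid
    }
  }
  list(
    detection = list(TP = TP, TN = TN, FP = FP, FN = FN,
                     accuracy = if (TP + TN + FP + FN > 0)
                       detectionAccuracy(TP, TN, FP, FN) else NA_real_),
    tracking = list(GT = tGT, FP = tFP, FN = tFN, IDS = tIDS,
                    mota = if (tGT > 0) mota(tGT, tFP, tFN, tIDS)
                           else NA_real_))
}
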