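#' Intersection over union of two bounding boxes
#'
#' Boxes are `c(x_min, y_min, x_max, y_max)` in 0-based half-open pixel
#' coordinates, so a box's area is `(x_max - x_min) * (y_max - y_min)`
#' pixels.
#'
#' @param boxA,boxB Numeric length-4 boxes; both must be non-degenerate.
#' @return Overlap area divided by union area, in \[0, 1\].
#' @export
#' @examples
#' boxIOU(c(0, 0, 10, 10), c(5, 0, 15, 10))  # 50 / 150
boxIOU <- function(boxA, boxB) {
  areaA <- (boxA[3] - boxA[1]) * (boxA[4] - boxA[2])
  areaB <- (boxB[3] - boxB[1]) * (boxB[4] - boxB[2])
  if (areaA <= 0 || areaB <= 0)
    stop("degenerate (zero-area) box")
  iw <- min(boxA[3], boxB[3]) - max(boxA[1], boxB[1])
  ih <- min(boxA[4], boxB[4]) - max(boxA[2], boxB[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (areaA + areaB - inter)
}

#' Create a fresh IOU tracker state
#'
#' @param iouThreshold Minimum IOU for a detection to continue a track,
#'   in (0, 1]; default 0.5.
#' @param patience Consecutive missed frames after which an open track is
#'   closed; default 1 (a single miss closes the track, appropriate for a
#'   single corridor where animals stay visible).
#' @return A [TrackerState-class] with no tracks and `nextId = 1`.
#' @export
trackerState <- function(iouThreshold = 0.5, patience = 1L) {
  new("TrackerState", active = list(), closed = list(), nextId = 1L,
      iouThreshold = iouThreshold, patience = as.integer(patience))
}

#' Advance the tracker by one frame
#'
#' Candidate pairs of (open track, detected region) with IOU at or above
#' the threshold are matched greedily in descending IOU, one-to-one, with
#' ties broken first by lower track ID, then by leftmost region. Matched
#' regions inherit the track's ID and the track's current box becomes the
#' matched detection's box (no motion model). Unmatched regions open new
#' tracks with the next sequential IDs, in left-to-right region order.
#' Tracks unmatched for `patience` consecutive frames are closed.
#'
#' @param state A [TrackerState-class].
#' @param frameIndex Integer index of this frame.
#' @param regions List of [InstanceRegion-class], all of kind `"cow"`
#'   (filter first with [noiseFilter()]).
#' @return List with `state` (updated [TrackerState-class]) and
#'   `assignments` (integer vector: track ID per region, in input order).
#' @export
trackStep <- function(state, frameIndex, regions) {
  stopifnot(is(state, "TrackerState"))
  if (length(regions) &&
      !all(vapply(regions, function(r) r@kind == "cow", logical(1))))
    stop("trackStep expects only kind = 'cow' regions")
  frameIndex <- as.integer(frameIndex)
  nT <- length(state@active)
  nR <- length(regions)
  assigned <- integer(nR)

  ## candidate pairs at or above the threshold, greedy in descending IOU
  if (nT > 0L && nR > 0L) {
    cand <- NULL
    for (ti in seq_len(nT)) {
      tb <- state@active[[ti]]$box
      for (ri in seq_len(nR)) {
        v <- boxIOU(tb, regions[[ri]]@box)
        if (v >= state@iouThreshold)
          cand <- rbind(cand, c(ti, ri, v))
      }
    }
    if (!is.null(cand)) {
      ids <- vapply(state@active, `[[`, integer(1), "id")
      xmin <- vapply(regions, function(r) r@box[1], numeric(1))
      ord <- order(-cand[, 3L], ids[cand[, 1L]], xmin[cand[, 2L]])
      usedT <- logical(nT); usedR <- logical(nR)
      for (k in ord) {
        ti <- cand[k, 1L]; ri <- cand[k, 2L]
        if (usedT[ti] || usedR[ri]) next
        usedT[ti] <- TRUE; usedR[ri] <- TRUE
        tr <- state@active[[ti]]
        tr$box <- regions[[ri]]@box
        tr$misses <- 0L
        tr$frameIndices <- c(tr$frameIndices, frameIndex)
        tr$regions <- c(tr$regions, regions[ri])
        state@active[[ti]] <- tr
        assigned[ri] <- tr$id
      }
    }
  }

  ## close stale tracks
  if (nT > 0L) {
    matchedNow <- vapply(state@active, function(tr)
      length(tr$frameIndices) > 0L &&
        tr$frameIndices[length(tr$frameIndices)] == frameIndex, logical(1))
    keep <- logical(nT)
    for (ti in seq_len(nT)) {
      if (matchedNow[ti]) { keep[ti] <- TRUE; next }
      tr <- state@active[[ti]]
      tr$misses <- tr$misses + 1L
      if (tr$misses >= state@patience) {
        state@closed <- c(state@closed, list(.finishTrack(tr)))
      } else {
        state@active[[ti]] <- tr
        keep[ti] <- TRUE
      }
    }
    state@active <- state@active[keep]
  }

  ## new tracks for unmatched regions, left to right
  if (nR > 0L) {
    un <- which(assigned == 0L)
    if (length(un)) {
      un <- un[order(vapply(regions[un], function(r) r@box[1], numeric(1)))]
      for (ri in un) {
        id <- state@nextId
        state@nextId <- state@nextId + 1L
        state@active <- c(state@active, list(list(
          id = id, box = regions[[ri]]@box, misses = 0L,
          frameIndices = frameIndex, regions = regions[ri])))
        assigned[ri] <- id
      }
    }
  }

  list(state = state, assignments = assigned)
}

.finishTrack <- function(rec) {
  new("Track", trackId = rec$id,
      frameIndices = as.integer(rec$frameIndices), regions = rec$regions)
}

#' Collect all tracks from a tracker state
#'
#' @param state A [TrackerState-class] after the last [trackStep()].
#' @return List of [Track-class], ordered by track ID.
#' @export
collectTracks <- function(state) {
  tracks <- c(state@closed, lapply(state@active, .finishTrack))
  tracks[order(vapply(tracks, trackId, integer(1)))]
}

#' Track detected regions across a whole sequence
#'
#' Convenience wrapper running [trackStep()] over per-frame region lists.
#' Rejected regions are dropped before association.
#'
#' @param regionsByFrame List (one element per frame) of lists of
#'   [InstanceRegion-class], e.g. from [detectFrames()] + [noiseFilter()].
#' @param frameIndices Integer frame indices, default taken from the
#'   regions' frames (positional 0, 1, ... when a frame has no regions).
#' @param iouThreshold,patience Passed to [trackerState()].
#' @return List with `tracks` (list of [Track-class]) and `assignments`
#'   (data frame with columns `frame_index`, `region_ordinal`, `track_id`;
#'   rejected regions get `track_id` NA).
#' @export
runTracker <- function(regionsByFrame, frameIndices = NULL,
                       iouThreshold = 0.5, patience = 1L) {
  if (is.null(frameIndices))
    frameIndices <- seq_along(regionsByFrame) - 1L
  state <- trackerState(iouThreshold, patience)
  rows <- list()
  for (k in seq_along(regionsByFrame)) {
    regions <- regionsByFrame[[k]]
    keep <- vapply(regions, function(r) r@kind == "cow", logical(1))
    st <- trackStep(state, frameIndices[k], regions[keep])
    state <- st$state
    ids <- rep(NA_integer_, length(regions))
    ids[keep] <- st$assignments
    if (length(regions))
      rows[[length(rows) + 1L]] <- data.frame(
        frame_index = frameIndices[k],
        region_ordinal = seq_along(regions),
        track_id = ids)
  }
  list(tracks = collectTracks(state),
       assignments = if (length(rows)) do.call(rbind, rows)
                     else data.frame(frame_index = integer(),
                                     region_ordinal = integer(),
                                     track_id = integer()))
}

.frameLookup <- function(frames) {
  stats::setNames(frames, vapply(frames, frameIndex, integer(1)))
}

#' Archive tracks to per-ID folders
#'
#' Mirrors the pipeline's bookkeeping: one subdirectory per track ID
#' (`1/`, `2/`, ...), each holding the track's masked depth grids as
#' one-frame depth CSV files (`frame_<index>.csv`, the [writeDepthCSV()]
#' dialect) plus a `manifest.json` with the frame indices and boxes. A
#' top-level `tracks.json` lists all archived IDs.
#'
#' @param tracks List of [Track-class].
#' @param frames List of [DepthFrame-class] covering the tracked frames.
#' @param outDir Output directory (created if needed).
#' @param force Overwrite existing non-empty per-ID directories.
#' @return `outDir`, invisibly.
#' @export
archiveTracks <- function(tracks, frames, outDir, force = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  lut <- .frameLookup(frames)
  for (tr in tracks) {
    tdir <- file.path(outDir, tr@trackId)
    if (dir.exists(tdir) && length(list.files(tdir)) > 0L && !force)
      stop("track directory already exists and is not empty: ", tdir,
           " (use force = TRUE)")
    dir.create(tdir, showWarnings = FALSE)
    boxes <- list()
    for (k in seq_along(tr@frameIndices)) {
      fi <- tr@frameIndices[k]
      fr <- lut[[as.character(fi)]]
      if (is.null(fr))
        stop("no depth frame with index ", fi, " supplied for track ",
             tr@trackId)
      masked <- extractDepthRegion(fr, tr@regions[[k]])
      writeDepthCSV(list(depthFrame(masked, index = fi)),
                    file.path(tdir, sprintf("frame_%06d.csv", fi)))
      boxes[[k]] <- tr@regions[[k]]@box
    }
    jsonlite::write_json(
      list(track_id = tr@trackId, frames = tr@frameIndices, boxes = boxes),
      file.path(tdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(
    list(track_ids = vapply(tracks, trackId, integer(1))),
    file.path(outDir, "tracks.json"), auto_unbox = TRUE)
  invisible(outDir)
}

#' Reload archived tracks
#'
#' Inverse of [archiveTracks()]: rebuilds each [Track-class] from its
#' per-ID folder. Masks are recovered as the nonzero set of each masked
#' depth grid, and pixel sums from the grid values.
#'
#' @param dir Directory written by [archiveTracks()].
#' @return List of [Track-class], ordered by track ID.
#' @export
loadTracks <- function(dir) {
  top <- jsonlite::read_json(file.path(dir, "tracks.json"),
                             simplifyVector = TRUE)
  lapply(sort(as.integer(top$track_ids)), function(id) {
    man <- jsonlite::read_json(file.path(dir, id, "manifest.json"),
                               simplifyVector = FALSE)
    fis <- as.integer(unlist(man$frames))
    regions <- lapply(seq_along(fis), function(k) {
      grid <- readDepthCSV(file.path(dir, id,
                                     sprintf("frame_%06d.csv", fis[k])))[[1]]
      masked <- grid@values
      mask <- masked != 0
      new("InstanceRegion", frameIndex = fis[k], mask = mask,
          box = .maskBox(mask), pixelSum = sum(masked[mask]), kind = "cow")
    })
    new("Track", trackId = id, frameIndices = fis, regions = regions)
  })
}
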