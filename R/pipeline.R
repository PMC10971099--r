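#' Build and validate a pipeline configuration
#'
#' Collects every stage parameter in one validated list. Numeric fields
#' are checked against the owning stage's preconditions here, so a bad
#' configuration fails before any work starts. Values can also be loaded
#' from a flat YAML file (see [readPipelineConfig()]); command-line flags
#' override file values in the CLI.
#'
#' @param input Path to the depth CSV stream.
#' @param outDir Output directory for all artifacts.
#' @param groundTruth Optional path to JSON-lines ground truth.
#' @param cameraHeightM Camera height above the floor (m), default 3.
#' @param distanceM Reference distance for the height transform (m),
#'   default 2.8.
#' @param fgDeltaM,minArea Reference-detector parameters.
#' @param noiseThreshold Pixel-sum noise threshold (metre-pixels),
#'   default 4000.
#' @param iouThreshold,patience Tracker parameters.
#' @param sigma Gaussian SD for feature smoothing (px), default 1.
#' @param cutoff Baseline lameness height cutoff (m), default 1.2.
#' @param masksDir Optional directory of external detector masks; when
#'   given, the pluggable [masksDetector()] replaces the reference
#'   detector.
#' @param minVisibility Scoring ignore threshold, default 0.25.
#' @param seed Integer seed recorded in the run manifest.
#' @param session Session tag attached to frames.
#' @return A validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(input, outDir, groundTruth = NULL,
                           cameraHeightM = 3, distanceM = 2.8,
                           fgDeltaM = 0.1, minArea = 50,
                           noiseThreshold = 4000, iouThreshold = 0.5,
                           patience = 1L, sigma = 1, cutoff = 1.2,
                           masksDir = NULL, minVisibility = 0.25,
                           seed = 1L, session = "") {
  stopifnot(cameraHeightM > 0, distanceM > 0, fgDeltaM > 0, minArea >= 0,
            noiseThreshold > 0, iouThreshold > 0, iouThreshold <= 1,
            patience >= 1, sigma > 0, cutoff > 0,
            minVisibility >= 0, minVisibility <= 1)
  structure(list(
    input = input, outDir = outDir, groundTruth = groundTruth,
    cameraHeightM = cameraHeightM, distanceM = distanceM,
    fgDeltaM = fgDeltaM, minArea = minArea,
    noiseThreshold = noiseThreshold, iouThreshold = iouThreshold,
    patience = as.integer(patience), sigma = sigma, cutoff = cutoff,
    masksDir = masksDir, minVisibility = minVisibility,
    seed = as.integer(seed), session = session),
    class = "PipelineConfig")
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Keys are the argument names of [pipelineConfig()]; unknown keys are an
#' error. `overrides` (e.g. parsed CLI flags) take precedence.
#'
#' @param path YAML file path.
#' @param overrides Named list of values overriding the file.
#' @return A `PipelineConfig` list.
#' @export
readPipelineConfig <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(pipelineConfig, vals)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full pipeline on one depth stream
#'
#' Executes detect, noise-filter, track, archive, featurise and (when
#' ground truth is supplied) score, writing every intermediate artifact
#' under `config$outDir`: `tracks/` (per-ID folders), `assignments.jsonl`,
#' `features.csv` (with the baseline cutoff prediction per frame, and
#' labels joined from ground truth when available), `scores.json` and a
#' machine-readable `manifest.json` (configuration, seed, package
#' version, per-stage counts). Per-stage progress is logged with
#' [message()]. Reruns with the same configuration produce identical
#' reports.
#'
#' @param config A `PipelineConfig` from [pipelineConfig()].
#' @return The manifest list, invisibly.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!file.exists(config$input))
    stop("input not found: ", config$input)
  if (!is.null(config$groundTruth) && !file.exists(config$groundTruth))
    stop("ground truth not found: ", config$groundTruth)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)

  frames <- .stage("read", readDepthCSV(config$input, config$session))
  message(sprintf("[read] %d frames", length(frames)))

  detector <- if (!is.null(config$masksDir))
    masksDetector(config$masksDir)
  else function(fr) referenceDetect(fr, config$cameraHeightM,
                                    config$fgDeltaM, config$minArea)
  regions <- .stage("detect", detectFrames(frames, detector))
  message(sprintf("[detect] %d regions", sum(lengths(regions))))

  filtered <- .stage("filter",
    lapply(regions, noiseFilter, threshold = config$noiseThreshold))
  nKept <- sum(vapply(filtered, function(rs)
    sum(vapply(rs, function(r) r@kind == "cow", logical(1))), integer(1)))
  message(sprintf("[filter] %d kept / %d rejected",
                  nKept, sum(lengths(filtered)) - nKept))

  run <- .stage("track", runTracker(filtered,
    frameIndices = vapply(frames, frameIndex, integer(1)),
    iouThreshold = config$iouThreshold, patience = config$patience))
  message(sprintf("[track] %d tracks", length(run$tracks)))

  .stage("archive", archiveTracks(run$tracks, frames,
                                  file.path(config$outDir, "tracks"),
                                  force = TRUE))
  .writeAssignments(run$assignments,
                    file.path(config$outDir, "assignments.jsonl"))

  featTab <- .stage("features",
    featureTable(run$tracks, frames, config$distanceM, config$sigma))
  message(sprintf("[features] %d full-width frames from %d tracks",
                  nrow(featTab), length(unique(featTab$track_id))))
  if (nrow(featTab) > 0L) {
    prof <- as.matrix(featTab[, -(1:2)])
    featTab$baseline_prediction <-
      ifelse(apply(prof, 1L, max) < config$cutoff, "lame", "sound")
  }

  scores <- NULL
  truth <- NULL
  if (!is.null(config$groundTruth)) {
    truth <- .stage("score", readGroundTruth(config$groundTruth))
    preds <- predictionsFromRun(filtered, run$assignments,
      vapply(frames, frameIndex, integer(1)))
    scores <- .stage("score", scoreRun(preds, truth,
      iouThreshold = config$iouThreshold,
      minVisibility = config$minVisibility))
    message(sprintf("[score] detection %.2f%%, MOTA %.2f%%",
                    scores$detection$accuracy, scores$tracking$mota))
    if (nrow(featTab) > 0L) {
      labels <- assignTrackLabels(run$tracks, truth, config$iouThreshold)
      featTab$label <- unname(labels[as.character(featTab$track_id)])
    }
    jsonlite::write_json(scores, file.path(config$outDir, "scores.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  utils::write.csv(featTab, file.path(config$outDir, "features.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "DepthHerd",
    version = as.character(utils::packageVersion("DepthHerd")),
    seed = config$seed,
    config = unclass(config),
    counts = list(frames = length(frames),
                  regions = sum(lengths(regions)),
                  kept = nKept,
                  tracks = length(run$tracks),
                  featureFrames = nrow(featTab)),
    features_md5 = unname(tools::md5sum(
      file.path(config$outDir, "features.csv"))),
    scores = scores)
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

.writeAssignments <- function(assignments, path) {
  lines <- vapply(seq_len(nrow(assignments)), function(i) {
    jsonlite::toJSON(as.list(assignments[i, ]), auto_unbox = TRUE,
                     na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Featurise archived tracks
#'
#' Rebuilds backbone-profile features straight from an [archiveTracks()]
#' directory: each archived masked depth grid is height-transformed,
#' smoothed and reduced to its per-column maxima. Only full-width frames
#' contribute rows.
#'
#' @param dir Archive directory.
#' @param distance Reference camera-to-floor distance (m), default 2.8.
#' @param sigma Gaussian SD (px), default 1.
#' @return Feature data frame as in [featureTable()].
#' @export
featuresFromArchive <- function(dir, distance = 2.8, sigma = 1) {
  tracks <- loadTracks(dir)
  rows <- list()
  for (tr in tracks) {
    sel <- selectFullWidthFrames(tr)
    for (k in seq_along(sel@frameIndices)) {
      fi <- sel@frameIndices[k]
      grid <- readDepthCSV(file.path(dir, tr@trackId,
                                     sprintf("frame_%06d.csv", fi)))[[1]]
      h <- heightTransform(grid@values, distance,
                           mask = sel@regions[[k]]@mask)
      prof <- backboneProfile(gaussianSmooth(h, sigma))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(track_id = tr@trackId, frame_index = fi),
        as.data.frame(t(prof)))
    }
  }
  if (length(rows) == 0L)
    return(featureTable(list(), list()))
  out <- do.call(rbind, rows)
  names(out)[-(1:2)] <- sprintf("h_%03d", seq_len(.FRAME_COLS) - 1L)
  rownames(out) <- NULL
  out
}

#' Run the full pipeline over a benchmark suite and build a dataset
#'
#' Renders every scene of a [makeBenchmarkSuite()] suite, runs detection,
#' noise filtering, tracking and feature extraction on it, and assembles
#' the resulting backbone profiles into a [LabelledDataset-class] with
#' the suite's per-cow labels and its by-cow train/test split. The height
#' transform uses each scene's camera height as the reference distance,
#' so profile heights are true heights above the simulated floor.
#'
#' @param suite A suite from [makeBenchmarkSuite()].
#' @param sigma Gaussian SD for feature smoothing (px), default 1.
#' @param noiseThreshold Pixel-sum filter threshold, default 4000.
#' @param iouThreshold Tracker association threshold, default 0.5.
#' @param fgDeltaM,minArea Reference-detector parameters.
#' @return A [LabelledDataset-class], one row per full-width frame.
#' @export
suiteDataset <- function(suite, sigma = 1, noiseThreshold = 4000,
                         iouThreshold = 0.5, fgDeltaM = 0.1, minArea = 50) {
  feats <- list(); labs <- character(0)
  splits <- character(0); cows <- integer(0)
  for (split in c("train", "test")) {
    for (scene in suite[[split]]) {
      out <- renderScene(scene$config)
      cam <- scene$config@cameraHeightM
      regions <- detectFrames(out$frames, function(fr)
        referenceDetect(fr, cam, fgDeltaM, minArea))
      filtered <- lapply(regions, noiseFilter, threshold = noiseThreshold)
      run <- runTracker(filtered, iouThreshold = iouThreshold)
      for (tr in run$tracks) {
        ft <- withCallingHandlers(
          featurizeTrack(tr, out$frames, distance = cam, sigma = sigma),
          warning = function(w) invokeRestart("muffleWarning"))
        if (nrow(ft$profiles) == 0L) next
        feats[[length(feats) + 1L]] <- ft$profiles
        n <- nrow(ft$profiles)
        labs <- c(labs, rep(scene$label, n))
        splits <- c(splits, rep(split, n))
        cows <- c(cows, rep(scene$cowId, n))
      }
    }
  }
  labelledDataset(do.call(rbind, feats), labs, splits, cows)
}
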