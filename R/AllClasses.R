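#' @import methods
NULL

## Fixed raster geometry of the overhead time-of-flight camera stream:
## every frame is 132 rows x 176 columns of distance-in-metres values.
.FRAME_ROWS <- 132L
.FRAME_COLS <- 176L

#' Raster dimensions of a depth frame
#'
#' All depth frames handled by this package share one fixed geometry:
#' 132 rows by 176 columns.
#'
#' @return Integer vector `c(rows, cols)`, i.e. `c(132L, 176L)`.
#' @export
#' @examples
#' frameDims()
frameDims <- function() c(.FRAME_ROWS, .FRAME_COLS)

#' DepthFrame: one overhead depth raster
#'
#' A single frame of the depth stream: a 132 x 176 numeric matrix of
#' camera-to-surface distances in metres, with a non-negative frame index
#' and an opaque session tag (e.g. a date plus AM/PM marker).
#'
#' @slot index Non-negative integer frame number within its session.
#' @slot values 132 x 176 numeric matrix of distances in metres; all values
#'   finite and non-negative. Row-major flattening of this matrix is the
#'   on-disk CSV row (see [writeDepthCSV()]).
#' @slot session Character scalar session tag; `""` when untagged.
#'
#' @seealso [depthFrame()], [readDepthCSV()]
#' @export
setClass("DepthFrame",
  representation(index = "integer", values = "matrix", session = "character"),
  prototype(index = 0L,
            values = matrix(0, .FRAME_ROWS, .FRAME_COLS),
            session = ""))

setValidity("DepthFrame", function(object) {
  v <- object@values
  if (!is.numeric(v) || !identical(dim(v), c(.FRAME_ROWS, .FRAME_COLS)))
    return(sprintf("values must be a %d x %d numeric matrix",
                   .FRAME_ROWS, .FRAME_COLS))
  if (anyNA(v) || any(!is.finite(v)))
    return("values must be finite")
  if (any(v < 0))
    return("distances must be non-negative")
  if (length(object@index) != 1L || is.na(object@index) || object@index < 0L)
    return("index must be a single non-negative integer")
  if (length(object@session) != 1L)
    return("session must be a single string")
  TRUE
})

#' Construct a DepthFrame
#'
#' @param values 132 x 176 numeric matrix of distances (m).
#' @param index Non-negative integer frame number.
#' @param session Session tag string.
#' @return A [DepthFrame-class] object.
#' @export
#' @examples
#' fr <- depthFrame(matrix(3, 132, 176), index = 0)
#' frameIndex(fr)
depthFrame <- function(values, index = 0L, session = "") {
  new("DepthFrame", index = as.integer(index),
      values = values, session = as.character(session))
}

#' InstanceRegion: one detected object in one frame
#'
#' A binary mask over the frame raster with its tight bounding box, the sum
#' of the masked depth values (metre-pixels, the quantity the noise filter
#' thresholds), and a kind flag: `"cow"` for regions kept for tracking,
#' `"rejected"` for regions discarded as noise (e.g. humans on the pathway).
#'
#' @slot frameIndex Integer index of the frame the region was detected in.
#' @slot mask 132 x 176 logical matrix; `TRUE` marks object pixels.
#' @slot box Numeric length-4 vector `c(x_min, y_min, x_max, y_max)` in
#'   0-based half-open pixel coordinates (x = column, y = row); always the
#'   tight bounding box of the mask.
#' @slot pixelSum Sum of depth values under the mask (metre-pixels).
#' @slot kind `"cow"` or `"rejected"`.
#' @seealso [instanceRegion()], [noiseFilter()], [extractDepthRegion()]
#' @export
setClass("InstanceRegion",
  representation(frameIndex = "integer", mask = "matrix",
                 box = "numeric", pixelSum = "numeric", kind = "character"))

setValidity("InstanceRegion", function(object) {
  m <- object@mask
  if (!is.logical(m) || !identical(dim(m), c(.FRAME_ROWS, .FRAME_COLS)))
    return("mask must be a 132 x 176 logical matrix")
  if (length(object@box) != 4L)
    return("box must be c(x_min, y_min, x_max, y_max)")
  if (any(m)) {
    tight <- .maskBox(m)
    if (!isTRUE(all.equal(unname(object@box), unname(tight))))
      return("box is not the tight bounding box of the mask")
  }
  if (length(object@pixelSum) != 1L || object@pixelSum < 0)
    return("pixelSum must be a single non-negative number")
  if (!object@kind %in% c("cow", "rejected"))
    return("kind must be 'cow' or 'rejected'")
  TRUE
})

## tight 0-based half-open bounding box of a logical mask
.maskBox <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) return(c(0, 0, 0, 0))
  c(min(w[, 2L]) - 1, min(w[, 1L]) - 1, max(w[, 2L]), max(w[, 1L]))
}

#' Construct an InstanceRegion from a mask and its depth frame
#'
#' Computes the tight bounding box and the masked pixel sum from the frame's
#' depth values.
#'
#' @param frame A [DepthFrame-class].
#' @param mask 132 x 176 logical matrix.
#' @param kind `"cow"` (default) or `"rejected"`.
#' @return An [InstanceRegion-class] object.
#' @export
instanceRegion <- function(frame, mask, kind = "cow") {
  stopifnot(is(frame, "DepthFrame"))
  new("InstanceRegion", frameIndex = frame@index, mask = mask,
      box = .maskBox(mask), pixelSum = sum(frame@values[mask]), kind = kind)
}

#' Track: one persistent object identity
#'
#' An ordered sequence of (frame index, [InstanceRegion-class]) observations
#' sharing a single integer track ID. IDs are assigned sequentially
#' 1, 2, 3, ... in order of first appearance.
#'
#' @slot trackId Positive integer identity.
#' @slot frameIndices Strictly increasing integer vector of frame indices.
#' @slot regions List of [InstanceRegion-class], parallel to `frameIndices`.
#' @seealso [trackerState()], [trackStep()], [archiveTracks()]
#' @export
setClass("Track",
  representation(trackId = "integer", frameIndices = "integer",
                 regions = "list"))

setValidity("Track", function(object) {
  if (length(object@trackId) != 1L || object@trackId < 1L)
    return("trackId must be a single positive integer")
  if (length(object@frameIndices) != length(object@regions))
    return("frameIndices and regions must be parallel")
  if (length(object@frameIndices) > 1L &&
      any(diff(object@frameIndices) <= 0L))
    return("frame indices within a track must be strictly increasing")
  TRUE
})

#' TrackerState: the IOU tracker between frames
#'
#' Functional state for the greedy IOU tracker: open tracks, the next
#' sequential ID, the IOU association threshold and the miss patience.
#' Update with [trackStep()]; finalise with [collectTracks()].
#'
#' @slot active List of open-track records (internal layout).
#' @slot closed List of finished [Track-class] objects.
#' @slot nextId Integer, the next ID to assign (1 + max assigned).
#' @slot iouThreshold Association threshold in (0, 1].
#' @slot patience Number of consecutive missed frames before a track closes.
#' @export
setClass("TrackerState",
  representation(active = "list", closed = "list", nextId = "integer",
                 iouThreshold = "numeric", patience = "integer"))

setValidity("TrackerState", function(object) {
  if (object@iouThreshold <= 0 || object@iouThreshold > 1)
    return("iouThreshold must lie in (0, 1]")
  if (object@patience < 1L)
    return("patience must be at least 1")
  if (object@nextId < 1L)
    return("nextId must be positive")
  TRUE
})

#' LabelledDataset: feature vectors with lameness labels
#'
#' Rows of length-176 backbone-height profiles with per-row class labels
#' (`lame`/`sound`), a train/test split tag and the originating cow (track)
#' ID. Splits are made by cow, never by frame, so no animal contributes to
#' both splits.
#'
#' @slot features Numeric matrix, one row per frame, 176 columns.
#' @slot labels Factor with levels `lame`, `sound`.
#' @slot split Factor with levels `train`, `test`.
#' @slot cowId Integer vector of originating cow/track IDs.
#' @seealso [labelledDataset()], [trainEval()], [thresholdBaseline()]
#' @export
setClass("LabelledDataset",
  representation(features = "matrix", labels = "factor", split = "factor",
                 cowId = "integer"))

setValidity("LabelledDataset", function(object) {
  n <- nrow(object@features)
  if (ncol(object@features) != .FRAME_COLS)
    return(sprintf("features must have %d columns", .FRAME_COLS))
  if (length(object@labels) != n || length(object@split) != n ||
      length(object@cowId) != n)
    return("labels, split and cowId must match the feature row count")
  if (!identical(levels(object@labels), c("lame", "sound")))
    return("labels must be a factor with levels lame, sound")
  if (!identical(levels(object@split), c("train", "test")))
    return("split must be a factor with levels train, test")
  if (n > 0L && any(rowSums(abs(object@features)) == 0))
    return("all-zero feature rows are not allowed")
  TRUE
})

#' Construct a LabelledDataset
#'
#' @param features Numeric matrix with 176 columns.
#' @param labels Character or factor, `"lame"`/`"sound"` per row.
#' @param split Character or factor, `"train"`/`"test"` per row.
#' @param cowId Integer cow/track ID per row.
#' @return A [LabelledDataset-class] object.
#' @export
labelledDataset <- function(features, labels, split, cowId) {
  new("LabelledDataset",
      features = as.matrix(features),
      labels = factor(as.character(labels), levels = c("lame", "sound")),
      split = factor(as.character(split), levels = c("train", "test")),
      cowId = as.integer(cowId))
}

#' ClassifierReport: fit-and-evaluate result for one model
#'
#' Accuracy on both splits, the test-split confusion matrix and per-frame
#' predictions with correctness flags, for one of the supported models
#' (`RF`, `KNN`, `DT`, or the transparent `baseline` height cutoff).
#'
#' @slot model Model name.
#' @slot trainAccuracy Train-split accuracy, percent.
#' @slot testAccuracy Test-split accuracy, percent.
#' @slot confusion 2 x 2 integer matrix of test-split counts
#'   (rows = truth, cols = prediction, order lame then sound).
#' @slot predictions Data frame with columns `cowId`, `truth`, `predicted`,
#'   `correct`, `split`.
#' @slot params Named list of hyperparameters used (provenance).
#' @export
setClass("ClassifierReport",
  representation(model = "character", trainAccuracy = "numeric",
                 testAccuracy = "numeric", confusion = "matrix",
                 predictions = "data.frame", params = "list"))

setValidity("ClassifierReport", function(object) {
  cm <- object@confusion
  if (!identical(dim(cm), c(2L, 2L)))
    return("confusion must be 2 x 2")
  acc <- 100 * sum(diag(cm)) / sum(cm)
  if (abs(acc - object@testAccuracy) > 1e-8)
    return("testAccuracy must equal the confusion-matrix accuracy")
  TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "DepthFrame", function(object) {
  v <- object@values
  cat(sprintf("DepthFrame #%d%s  %d x %d  depth [%.3f, %.3f] m\n",
              object@index,
              if (nzchar(object@session)) paste0(" (", object@session, ")") else "",
              nrow(v), ncol(v), min(v), max(v)))
})

setMethod("show", "InstanceRegion", function(object) {
  cat(sprintf(
    "InstanceRegion frame %d  kind=%s  box=[%g,%g,%g,%g]  area=%d px  pixelSum=%.1f\n",
    object@frameIndex, object@kind,
    object@box[1], object@box[2], object@box[3], object@box[4],
    sum(object@mask), object@pixelSum))
})

setMethod("show", "Track", function(object) {
  n <- length(object@frameIndices)
  cat(sprintf("Track %d  %d observation%s", object@trackId, n,
              if (n == 1L) "" else "s"))
  if (n > 0L)
    cat(sprintf("  frames %d..%d", min(object@frameIndices),
                max(object@frameIndices)))
  cat("\n")
})

setMethod("show", "TrackerState", function(object) {
  cat(sprintf(
    "TrackerState  %d active, %d closed  nextId=%d  iou>=%.2f  patience=%d\n",
    length(object@active), length(object@closed), object@nextId,
    object@iouThreshold, object@patience))
})

setMethod("show", "LabelledDataset", function(object) {
  cat(sprintf(
    "LabelledDataset  %d frames (%d train / %d test)  %d lame / %d sound  %d cows\n",
    nrow(object@features), sum(object@split == "train"),
    sum(object@split == "test"), sum(object@labels == "lame"),
    sum(object@labels == "sound"), length(unique(object@cowId))))
})

setMethod("show", "ClassifierReport", function(object) {
  cat(sprintf("ClassifierReport [%s]  train %.1f%%  test %.1f%%\n",
              object@model, object@trainAccuracy, object@testAccuracy))
  print(object@confusion)
})
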