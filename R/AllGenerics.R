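#' Accessors for DepthHerd classes
#'
#' Small generic accessors for the package's S4 containers; prefer these to
#' direct slot access.
#'
#' @param object A DepthHerd S4 object.
#' @return The slot value documented for each accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frameIndex", function(object) standardGeneric("frameIndex"))
#' @rdname accessors
#' @export
setMethod("frameIndex", "DepthFrame", function(object) object@index)
#' @rdname accessors
#' @export
setMethod("frameIndex", "InstanceRegion", function(object) object@frameIndex)

#' @rdname accessors
#' @export
setGeneric("depthValues", function(object) standardGeneric("depthValues"))
#' @rdname accessors
#' @export
setMethod("depthValues", "DepthFrame", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("frameSession", function(object) standardGeneric("frameSession"))
#' @rdname accessors
#' @export
setMethod("frameSession", "DepthFrame", function(object) object@session)

#' @rdname accessors
#' @export
setGeneric("regionMask", function(object) standardGeneric("regionMask"))
#' @rdname accessors
#' @export
setMethod("regionMask", "InstanceRegion", function(object) object@mask)

#' @rdname accessors
#' @export
setGeneric("boundingBox", function(object) standardGeneric("boundingBox"))
#' @rdname accessors
#' @export
setMethod("boundingBox", "InstanceRegion", function(object) object@box)

#' @rdname accessors
#' @export
setGeneric("pixelSum", function(object) standardGeneric("pixelSum"))
#' @rdname accessors
#' @export
setMethod("pixelSum", "InstanceRegion", function(object) object@pixelSum)

#' @rdname accessors
#' @export
setGeneric("regionKind", function(object) standardGeneric("regionKind"))
#' @rdname accessors
#' @export
setMethod("regionKind", "InstanceRegion", function(object) object@kind)

#' @rdname accessors
#' @export
setGeneric("trackId", function(object) standardGeneric("trackId"))
#' @rdname accessors
#' @export
setMethod("trackId", "Track", function(object) object@trackId)

#' @rdname accessors
#' @export
setGeneric("trackFrames", function(object) standardGeneric("trackFrames"))
#' @rdname accessors
#' @export
setMethod("trackFrames", "Track", function(object) object@frameIndices)

#' @rdname accessors
#' @export
setGeneric("trackRegions", function(object) standardGeneric("trackRegions"))
#' @rdname accessors
#' @export
setMethod("trackRegions", "Track", function(object) object@regions)

#' @rdname accessors
#' @export
setGeneric("datasetFeatures", function(object) standardGeneric("datasetFeatures"))
#' @rdname accessors
#' @export
setMethod("datasetFeatures", "LabelledDataset", function(object) object@features)

#' @rdname accessors
#' @export
setGeneric("datasetLabels", function(object) standardGeneric("datasetLabels"))
#' @rdname accessors
#' @export
setMethod("datasetLabels", "LabelledDataset", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("datasetSplit", function(object) standardGeneric("datasetSplit"))
#' @rdname accessors
#' @export
setMethod("datasetSplit", "LabelledDataset", function(object) object@split)

#' @rdname accessors
#' @export
setGeneric("modelName", function(object) standardGeneric("modelName"))
#' @rdname accessors
#' @export
setMethod("modelName", "ClassifierReport", function(object) object@model)

#' @rdname accessors
#' @export
setGeneric("trainAccuracy", function(object) standardGeneric("trainAccuracy"))
#' @rdname accessors
#' @export
setMethod("trainAccuracy", "ClassifierReport", function(object) object@trainAccuracy)

#' @rdname accessors
#' @export
setGeneric("testAccuracy", function(object) standardGeneric("testAccuracy"))
#' @rdname accessors
#' @export
setMethod("testAccuracy", "ClassifierReport", function(object) object@testAccuracy)

#' @rdname accessors
#' @export
setGeneric("confusionMatrix", function(object) standardGeneric("confusionMatrix"))
#' @rdname accessors
#' @export
setMethod("confusionMatrix", "ClassifierReport", function(object) object@confusion)

#' @rdname accessors
#' @export
setGeneric("reportPredictions", function(object) standardGeneric("reportPredictions"))
#' @rdname accessors
#' @export
setMethod("reportPredictions", "ClassifierReport",
          function(object) object@predictions)
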