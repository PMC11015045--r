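#' @include AllClasses.R
NULL

#' @rdname SpatialSession-accessors
#' @export
setGeneric("eventMatrix", function(x) standardGeneric("eventMatrix"))

#' @rdname SpatialSession-accessors
#' @export
setGeneric("behaviorFrames", function(x) standardGeneric("behaviorFrames"))

#' @rdname SpatialSession-accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname SpatialSession-accessors
#' @export
setGeneric("beltLength", function(x) standardGeneric("beltLength"))

#' @rdname SpatialSession-accessors
#' @export
setGeneric("nSpatialBins", function(x) standardGeneric("nSpatialBins"))

#' @rdname SpatialSession-accessors
#' @export
setGeneric("rewardZone", function(x) standardGeneric("rewardZone"))

#' @rdname SpatialSession-accessors
#' @export
setGeneric("textureBoundaries", function(x) standardGeneric("textureBoundaries"))

#' @rdname SpatialSession-accessors
#' @export
setGeneric("projecting", function(x) standardGeneric("projecting"))

#' @rdname SpatialSession-accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' Accessors for SpatialSession
#'
#' `eventMatrix` returns the neurons x frames deconvolved event matrix
#' (assay `"S"`); `behaviorFrames` the frame-aligned behavior as a
#' data.frame; the remaining accessors return session geometry and
#' annotation stored in `metadata()` / `rowData()`.
#'
#' @param x a \linkS4class{SpatialSession}.
#' @return see individual descriptions.
#' @name SpatialSession-accessors
NULL

#' @rdname SpatialSession-accessors
setMethod("eventMatrix", "SpatialSession", function(x) assay(x, "S"))

#' @rdname SpatialSession-accessors
setMethod("behaviorFrames", "SpatialSession",
          function(x) as.data.frame(colData(x)))

#' @rdname SpatialSession-accessors
setMethod("frameRate", "SpatialSession", function(x) metadata(x)$frameRate)

#' @rdname SpatialSession-accessors
setMethod("beltLength", "SpatialSession", function(x) metadata(x)$beltLength)

#' @rdname SpatialSession-accessors
setMethod("nSpatialBins", "SpatialSession", function(x) metadata(x)$nBins)

#' @rdname SpatialSession-accessors
setMethod("rewardZone", "SpatialSession", function(x) metadata(x)$rewardZone)

#' @rdname SpatialSession-accessors
setMethod("textureBoundaries", "SpatialSession",
          function(x) metadata(x)$textureBoundaries)

#' @rdname SpatialSession-accessors
setMethod("projecting", "SpatialSession",
          function(x) rowData(x)$projecting)

#' @rdname SpatialSession-accessors
setMethod("groundTruth", "SpatialSession", function(x) metadata(x)$groundTruth)
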