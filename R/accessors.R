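#' Accessors for leitrack objects
#'
#' Small generics giving read access to the slots of the package's S4
#' classes, so user code never touches slots directly.
#'
#' @param x a leitrack S4 object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("plantId", function(x) standardGeneric("plantId"))
#' @rdname accessors
#' @export
setMethod("plantId", "FrameMeta", function(x) x@plantId)
#' @rdname accessors
#' @export
setMethod("plantId", "Frame", function(x) x@meta@plantId)

#' @rdname accessors
#' @export
setGeneric("frameView", function(x) standardGeneric("frameView"))
#' @rdname accessors
#' @export
setMethod("frameView", "FrameMeta", function(x) x@view)
#' @rdname accessors
#' @export
setMethod("frameView", "Frame", function(x) x@meta@view)

#' @rdname accessors
#' @export
setGeneric("timestampMin", function(x) standardGeneric("timestampMin"))
#' @rdname accessors
#' @export
setMethod("timestampMin", "FrameMeta", function(x) x@timestampMin)
#' @rdname accessors
#' @export
setMethod("timestampMin", "Frame", function(x) x@meta@timestampMin)

#' @rdname accessors
#' @export
setGeneric("framePixels", function(x) standardGeneric("framePixels"))
#' @rdname accessors
#' @export
setMethod("framePixels", "Frame", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("frameMeta", function(x) standardGeneric("frameMeta"))
#' @rdname accessors
#' @export
setMethod("frameMeta", "Frame", function(x) x@meta)
#' @rdname accessors
#' @export
setMethod("frameMeta", "BinaryMask", function(x) x@meta)

#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))
#' @rdname accessors
#' @export
setMethod("maskMatrix", "BinaryMask", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("maskArea", function(x) standardGeneric("maskArea"))
#' @rdname accessors
#' @export
setMethod("maskArea", "BinaryMask", function(x) sum(x@mask))

#' @rdname accessors
#' @export
setGeneric("maskFlags", function(x) standardGeneric("maskFlags"))
#' @rdname accessors
#' @export
setMethod("maskFlags", "BinaryMask", function(x) x@flags)
#' @rdname accessors
#' @export
setMethod("maskFlags", "EllipseFit", function(x)
  if (x@degenerate) "degenerate" else character(0))
#' @rdname accessors
#' @export
setMethod("maskFlags", "HeightMeasurement", function(x)
  if (x@flagged) "below_line" else character(0))

#' @rdname accessors
#' @export
setGeneric("majorAxisPx", function(x) standardGeneric("majorAxisPx"))
#' @rdname accessors
#' @export
setMethod("majorAxisPx", "EllipseFit", function(x) x@majorAxisPx)

#' @rdname accessors
#' @export
setGeneric("minorAxisPx", function(x) standardGeneric("minorAxisPx"))
#' @rdname accessors
#' @export
setMethod("minorAxisPx", "EllipseFit", function(x) x@minorAxisPx)

#' @rdname accessors
#' @export
setGeneric("orientationRad", function(x) standardGeneric("orientationRad"))
#' @rdname accessors
#' @export
setMethod("orientationRad", "EllipseFit", function(x) x@orientationRad)

#' @rdname accessors
#' @export
setGeneric("heightPx", function(x) standardGeneric("heightPx"))
#' @rdname accessors
#' @export
setMethod("heightPx", "HeightMeasurement", function(x) x@heightPx)

#' @rdname accessors
#' @export
setGeneric("seriesPairs", function(x) standardGeneric("seriesPairs"))
#' @rdname accessors
#' @export
setMethod("seriesPairs", "SeriesIndex", function(x) x@pairs)

#' @rdname accessors
#' @export
setGeneric("seriesPlants", function(x) standardGeneric("seriesPlants"))
#' @rdname accessors
#' @export
setMethod("seriesPlants", "SeriesIndex", function(x) x@plants)

#' @rdname accessors
#' @export
setGeneric("seriesTimepoints", function(x) standardGeneric("seriesTimepoints"))
#' @rdname accessors
#' @export
setMethod("seriesTimepoints", "SeriesIndex", function(x) x@timepoints)

#' @rdname accessors
#' @export
setGeneric("seriesIncomplete", function(x) standardGeneric("seriesIncomplete"))
#' @rdname accessors
#' @export
setMethod("seriesIncomplete", "SeriesIndex", function(x) x@incomplete)

#' @rdname accessors
#' @export
setGeneric("seriesIssues", function(x) standardGeneric("seriesIssues"))
#' @rdname accessors
#' @export
setMethod("seriesIssues", "SeriesIndex", function(x) x@issues)

#' @rdname accessors
#' @export
setGeneric("leiTrueDeg", function(x) standardGeneric("leiTrueDeg"))
#' @rdname accessors
#' @export
setMethod("leiTrueDeg", "SceneTruth", function(x) x@leiTrueDeg)

#' @rdname accessors
#' @export
setGeneric("rTrueMm", function(x) standardGeneric("rTrueMm"))
#' @rdname accessors
#' @export
setMethod("rTrueMm", "SceneTruth", function(x) x@rTrueMm)

#' @rdname accessors
#' @export
setGeneric("hTrueMm", function(x) standardGeneric("hTrueMm"))
#' @rdname accessors
#' @export
setMethod("hTrueMm", "SceneTruth", function(x) x@hTrueMm)

#' @rdname accessors
#' @export
setGeneric("silhouettePxCount", function(x) standardGeneric("silhouettePxCount"))
#' @rdname accessors
#' @export
setMethod("silhouettePxCount", "SceneTruth", function(x)
  c(top = x@topPxCount, side = x@sidePxCount))
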