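#' @rdname MosaicImage-class
#' @param object an object.
#' @export
setGeneric("imageMatrix", function(object) standardGeneric("imageMatrix"))

#' @rdname MosaicImage-class
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname QualityMask-class
#' @export
setGeneric("qualityScores", function(object) standardGeneric("qualityScores"))

#' @rdname QualityMask-class
#' @export
setGeneric("maskMatrix", function(object) standardGeneric("maskMatrix"))

#' @rdname QualityMask-class
#' @export
setGeneric("nonMaskedPortion", function(object) standardGeneric("nonMaskedPortion"))

#' @rdname Tessellation-class
#' @export
setGeneric("cellCenters", function(object) standardGeneric("cellCenters"))

#' @rdname Tessellation-class
#' @export
setGeneric("cellPolygons", function(object) standardGeneric("cellPolygons"))

#' @rdname Tessellation-class
#' @export
setGeneric("neighborGraph", function(object) standardGeneric("neighborGraph"))

#' @rdname Tessellation-class
#' @export
setGeneric("keptFlags", function(object) standardGeneric("keptFlags"))

#' @rdname MosaicSummary-class
#' @export
setGeneric("perCellTable", function(object) standardGeneric("perCellTable"))

#' @rdname HypoRegionSet-class
#' @export
setGeneric("perRegionTable", function(object) standardGeneric("perRegionTable"))

#' @rdname MosaicSummary-class
#' @export
setGeneric("imageStats", function(object) standardGeneric("imageStats"))

#' @rdname MosaicSummary-class
#' @export
setGeneric("densityPerMm2", function(object) standardGeneric("densityPerMm2"))

#' @rdname HypoRegionSet-class
#' @export
setGeneric("regionContours", function(object) standardGeneric("regionContours"))
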