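#' @rdname MosaicImage-class
#' @aliases imageMatrix,MosaicImage-method
setMethod("imageMatrix", "MosaicImage", function(object) object@image)

#' @rdname MosaicImage-class
#' @aliases pixelSize,MosaicImage-method
setMethod("pixelSize", "MosaicImage", function(object) object@pixelSize)

#' @rdname QualityMask-class
#' @aliases qualityScores,QualityMask-method
setMethod("qualityScores", "QualityMask", function(object) object@scores)

#' @rdname QualityMask-class
#' @aliases maskMatrix,QualityMask-method
setMethod("maskMatrix", "QualityMask", function(object) object@mask)

#' @rdname QualityMask-class
#' @aliases nonMaskedPortion,QualityMask-method
setMethod("nonMaskedPortion", "QualityMask", function(object) object@nonMaskedPortion)

#' @rdname Tessellation-class
#' @aliases cellCenters,Tessellation-method
setMethod("cellCenters", "Tessellation", function(object) object@centers)

#' @rdname Tessellation-class
#' @aliases cellPolygons,Tessellation-method
setMethod("cellPolygons", "Tessellation", function(object) object@polygons)

#' @rdname Tessellation-class
#' @aliases neighborGraph,Tessellation-method
setMethod("neighborGraph", "Tessellation", function(object) object@neighbors)

#' @rdname Tessellation-class
#' @aliases keptFlags,Tessellation-method
setMethod("keptFlags", "Tessellation", function(object) object@keptFlags)

#' @rdname MosaicSummary-class
#' @aliases perCellTable,MosaicSummary-method
setMethod("perCellTable", "MosaicSummary", function(object) object@perCell)

#' @rdname MosaicSummary-class
#' @aliases imageStats,MosaicSummary-method
setMethod("imageStats", "MosaicSummary", function(object) object@imageStats)

#' @rdname HypoRegionSet-class
#' @aliases imageStats,HypoRegionSet-method
setMethod("imageStats", "HypoRegionSet", function(object) object@imageStats)

#' @rdname MosaicSummary-class
#' @aliases densityPerMm2,MosaicSummary-method
setMethod("densityPerMm2", "MosaicSummary", function(object) object@density)

#' @rdname HypoRegionSet-class
#' @aliases densityPerMm2,HypoRegionSet-method
setMethod("densityPerMm2", "HypoRegionSet", function(object) object@density)

#' @rdname MosaicSummary-class
#' @aliases nonMaskedPortion,MosaicSummary-method
setMethod("nonMaskedPortion", "MosaicSummary", function(object) object@nonMaskedPortion)

#' @rdname HypoRegionSet-class
#' @aliases nonMaskedPortion,HypoRegionSet-method
setMethod("nonMaskedPortion", "HypoRegionSet", function(object) object@nonMaskedPortion)

#' @rdname HypoRegionSet-class
#' @aliases perRegionTable,HypoRegionSet-method
setMethod("perRegionTable", "HypoRegionSet", function(object) object@perRegion)

#' @rdname HypoRegionSet-class
#' @aliases regionContours,HypoRegionSet-method
setMethod("regionContours", "HypoRegionSet", function(object) object@contours)

setMethod("show", "MosaicImage", function(object) {
  d <- dim(object@image)
  cat(sprintf("MosaicImage: %d x %d px, %.3g um/px (%.0f x %.0f um)\n",
              d[1], d[2], object@pixelSize,
              d[1] * object@pixelSize, d[2] * object@pixelSize))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "QualityMask", function(object) {
  cat(sprintf(
    "QualityMask: %d x %d tiles of %d px, threshold %.2f, non-masked %.1f%%\n",
    nrow(object@scores), ncol(object@scores), object@tileSize,
    object@threshold, 100 * object@nonMaskedPortion))
})

setMethod("show", "Tessellation", function(object) {
  cat(sprintf("Tessellation: %d cells (%d kept after border filter)\n",
              nrow(object@centers), sum(object@keptFlags)))
})

setMethod("show", "MosaicSummary", function(object) {
  cat(sprintf("MosaicSummary: %d kept cells, density %.0f cells/mm^2\n",
              nrow(object@perCell), object@density))
  print(round(object@imageStats, 3))
})

setMethod("show", "HypoRegionSet", function(object) {
  cat(sprintf("HypoRegionSet: %d regions, density %.0f /mm^2 (%d degenerate dropped)\n",
              nrow(object@perRegion), object@density, object@nDropped))
})

setMethod("show", "SimilarityTransform", function(object) {
  cat(sprintf("SimilarityTransform: scale %.6g, rotation %.6g rad, translation (%.6g, %.6g)\n",
              object@scale, object@rotation,
              object@translation[1], object@translation[2]))
})

setMethod("show", "MosaicParams", function(object) {
  cat(sprintf(
    "MosaicParams: spacing %.3g um, disorder %.3g, %d x %d px @ %.3g um/px, seed %d\n",
    object@latticeSpacing, object@disorder, object@imageSize[1],
    object@imageSize[2], object@pixelSize, object@seed))
})
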