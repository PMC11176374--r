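# Readers/writers for the pipeline's external formats: 16-bit grayscale
# TIFF images, 8-bit PNG masks, CSV tables, JSON geometry and sidecars.
# Image matrices follow the package's width-first convention (dim1 = x), so
# they are transposed at the file boundary (file rows = y).

#' Write a mosaic image as 16-bit grayscale TIFF
#' @param image a [MosaicImage-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeMosaicTIFF <- function(image, path) {
  stopifnot(is(image, "MosaicImage"))
  tiff::writeTIFF(t(image@image), path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a grayscale TIFF/PNG as a MosaicImage
#' @param path file path (.tif/.tiff/.png).
#' @param pixelSize um per pixel to attach.
#' @param metadata optional metadata list.
#' @return a [MosaicImage-class].
#' @export
readMosaicImage <- function(path, pixelSize, metadata = list()) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stopParam("unsupported image format: %s", ext))
  if (length(dim(m)) == 3L) m <- m[, , 1]
  new("MosaicImage", image = t(m), pixelSize = pixelSize,
      metadata = metadata)
}

#' Write a quality mask as 8-bit PNG (0/255) with CSV scores and JSON sidecar
#' @param qmask a [QualityMask-class].
#' @param prefix output path prefix; writes `<prefix>_mask.png`,
#'   `<prefix>_scores.csv`, `<prefix>_quality.json`.
#' @return the three paths, invisibly.
#' @export
writeQualityMask <- function(qmask, prefix) {
  stopifnot(is(qmask, "QualityMask"))
  pngPath <- paste0(prefix, "_mask.png")
  csvPath <- paste0(prefix, "_scores.csv")
  jsonPath <- paste0(prefix, "_quality.json")
  png::writePNG(t(qmask@mask * 1), pngPath)
  utils::write.table(qmask@scores, csvPath, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(tile_size_px = qmask@tileSize,
                            threshold = qmask@threshold,
                            non_masked_portion = qmask@nonMaskedPortion),
                       jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(c(pngPath, csvPath, jsonPath))
}

#' Write tessellation geometry as JSON (um vertex lists)
#' @param tess a [Tessellation-class].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeTessellationJSON <- function(tess, path) {
  stopifnot(is(tess, "Tessellation"))
  jsonlite::write_json(list(
    centers_um = unname(apply(tess@centers, 1, as.numeric, simplify = FALSE)),
    polygons_um = lapply(tess@polygons, function(p)
      unname(apply(p, 1, as.numeric, simplify = FALSE))),
    kept = tess@keptFlags,
    bounds_um = tess@bounds), path, digits = NA)
  invisible(path)
}

#' Read a landmark pair table
#' @param path CSV with columns x_src, y_src, x_dst, y_dst (px).
#' @return list with matrices `src` and `dst`.
#' @export
readLandmarks <- function(path) {
  d <- utils::read.csv(path)
  need <- c("x_src", "y_src", "x_dst", "y_dst")
  if (!all(need %in% names(d)))
    stopValidation("landmark file must have columns %s",
                   paste(need, collapse = ", "))
  list(src = as.matrix(d[, c("x_src", "y_src")]),
       dst = as.matrix(d[, c("x_dst", "y_dst")]))
}

#' Write a similarity transform as JSON
#' @param tr a [SimilarityTransform-class].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeTransformJSON <- function(tr, path) {
  jsonlite::write_json(list(scale = tr@scale, rotation_rad = tr@rotation,
                            translation = as.numeric(tr@translation),
                            rmse = attr(tr, "rmse")),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
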