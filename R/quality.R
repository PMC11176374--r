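# Tile-based image quality scoring and masking.
#
# The study's quality scorer is a trained model; here the score is a
# deterministic band-pass contrast statistic: the RMS of the image filtered
# in a spatial-frequency band centered on the expected cell spacing,
# normalized by the tile's mean intensity (Weber-style band contrast). A
# sharp mosaic has strong contrast at the cell frequency (score near 1);
# blurring suppresses the band so blurred or structureless tiles score near
# 0. Dividing by the mean makes the score invariant to global intensity
# rescaling. (Normalizing by the tile's total AC RMS instead would be blur-
# blind: in a blurred mosaic the surviving AC power is still concentrated at
# the attenuated cell band, so that ratio stays high.)

setClass("QualityMap",
  representation(tileSize = "integer", scores = "matrix", spacing = "numeric"))

setMethod("show", "QualityMap", function(object) {
  cat(sprintf("QualityMap: %d x %d tiles of %d px, scores in [%.2f, %.2f]\n",
              nrow(object@scores), ncol(object@scores), object@tileSize,
              min(object@scores), max(object@scores)))
})

# Calibration divisor for the band-contrast ratio, chosen once so a sharp
# synthetic mosaic scores > 0.8 in every tile (raw ratio >= ~0.14 across
# seeds) and a heavily blurred version (Gaussian sigma = 4x the band's fine
# scale, i.e. 0.72 * spacing in px) scores < 0.2 (raw ratio <= ~0.024).
.qualityCalibration <- 0.15

#' Score local image quality on a tile grid
#'
#' @param image a [MosaicImage-class].
#' @param tileSize tile edge in pixels (>= 8); tiles are non-overlapping and
#'   the last row/column may be smaller.
#' @param spacing expected cell spacing in um defining the band center.
#' @return a `QualityMap` (tile scores in `[0, 1]`).
#' @export
qualityMap <- function(image, tileSize = 64L, spacing = 14) {
  stopifnot(is(image, "MosaicImage"))
  img <- image@image
  nx <- nrow(img); ny <- ncol(img)
  if (tileSize < 8L) stopParam("tileSize must be >= 8 px")
  if (tileSize > nx || tileSize > ny)
    stopParam("tile (%d px) larger than image (%d x %d px)", tileSize, nx, ny)
  ps <- image@pixelSize
  spx <- spacing / ps
  band <- gblurCapped(img, max(0.75, 0.18 * spx)) -
          gblurCapped(img, max(1.5, 0.60 * spx))
  ti <- ceiling(nx / tileSize); tj <- ceiling(ny / tileSize)
  sc <- matrix(0, ti, tj)
  eps <- 1e-6
  for (a in seq_len(ti)) {
    is <- ((a - 1) * tileSize + 1):min(a * tileSize, nx)
    for (b in seq_len(tj)) {
      js <- ((b - 1) * tileSize + 1):min(b * tileSize, ny)
      tileI <- img[is, js]
      m <- mean(tileI)
      if (m < eps || sqrt(mean((tileI - m)^2)) < eps) { sc[a, b] <- 0; next }
      bandRMS <- sqrt(mean(band[is, js]^2))
      sc[a, b] <- min(1, (bandRMS / m) / .qualityCalibration)
    }
  }
  new("QualityMap", tileSize = as.integer(tileSize), scores = sc,
      spacing = spacing)
}

#' Derive the analyzable-pixel mask from tile quality scores
#'
#' A pixel is analyzable iff the score of its tile is at least `threshold`.
#' The non-masked portion is exactly the fraction of analyzable pixels.
#'
#' @param qmap a `QualityMap` from [qualityMap()].
#' @param threshold score threshold in `[0, 1]` (default 0.5).
#' @param imageDim integer `c(nx, ny)` of the underlying image.
#' @return a [QualityMask-class].
#' @export
maskFromQuality <- function(qmap, threshold = 0.5, imageDim) {
  stopifnot(is(qmap, "QualityMap"))
  if (threshold < 0 || threshold > 1)
    stopParam("threshold must lie in [0, 1]")
  nx <- imageDim[1]; ny <- imageDim[2]
  t <- qmap@tileSize
  tilePass <- qmap@scores >= threshold
  ix <- pmin(nrow(tilePass), (seq_len(nx) - 1L) %/% t + 1L)
  jx <- pmin(ncol(tilePass), (seq_len(ny) - 1L) %/% t + 1L)
  mask <- tilePass[ix, jx, drop = FALSE]
  new("QualityMask", tileSize = t, scores = qmap@scores,
      threshold = threshold, mask = mask,
      nonMaskedPortion = sum(mask) / length(mask))
}

#' Image-inclusion rule for quantitative analysis
#'
#' An image enters the quantitative analysis iff its non-masked portion is
#' strictly over 5% and an RPE mosaic was found (at least `minCells`
#' tessellated cells).
#'
#' @param qmask a [QualityMask-class].
#' @param nCells number of cells found by the tessellation stage.
#' @param minCells minimum cell count that counts as "mosaic present".
#' @return logical.
#' @export
includeImage <- function(qmask, nCells, minCells = 10L) {
  stopifnot(is(qmask, "QualityMask"))
  (qmask@nonMaskedPortion > 0.05) && (nCells >= minCells)
}
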