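#' @useDynLib rpemosaic, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif sd pt qt quantile median fft setNames aggregate
#' @importFrom utils write.csv read.csv head tail
#' @importFrom grDevices chull
NULL

#' MosaicImage: a grayscale retinal image with physical pixel size
#'
#' Container for one adaptive-optics trans-scleral flood-illumination
#' (AO-TFI) style image of the retinal pigment epithelium (RPE) mosaic.
#' The image matrix follows the width-first convention (`dim1` = x,
#' `dim2` = y, as in \pkg{EBImage}); pixel `[i, j]` (1-based) has physical
#' coordinates `((i-1) * pixelSize, (j-1) * pixelSize)` in micrometers,
#' origin at the top-left pixel center, y pointing down. Intensities are
#' stored in `[0, 1]`.
#'
#' @slot image numeric matrix of intensities in `[0, 1]`, dim1 = x.
#' @slot pixelSize physical pixel pitch in micrometers per pixel.
#' @slot metadata named list of acquisition metadata (eye id, zone,
#'   refraction, axial length, ...).
#' @export
setClass("MosaicImage",
  representation(image = "matrix", pixelSize = "numeric", metadata = "list"),
  prototype(pixelSize = 1, metadata = list())
)

setValidity("MosaicImage", function(object) {
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive number (um/px)")
  if (!is.numeric(object@image) || length(object@image) == 0L)
    return("image must be a non-empty numeric matrix")
  rng <- range(object@image, finite = TRUE)
  if (rng[1] < -1e-8 || rng[2] > 1 + 1e-8)
    return("image intensities must lie in [0, 1]")
  TRUE
})

#' Parameters of the synthetic RPE mosaic generator
#'
#' The generator emulates the appearance of a healthy RPE mosaic in AO-TFI
#' imaging: polygonal cells with hypo-reflective centers and bright edges in
#' a honeycomb arrangement over a mixed-reflectance background. Cell centers
#' sit on a hexagonal lattice jittered by an isotropic Gaussian whose SD is
#' `disorder * latticeSpacing`; intracellular hypo-reflective blobs are
#' discs with a Fourier-perturbed boundary whose amplitude is set by
#' `blobRoughness` (0 = digitized disc).
#'
#' @slot latticeSpacing nearest-neighbor cell spacing, micrometers.
#' @slot disorder center jitter SD as a fraction of the spacing (>= 0).
#' @slot imageSize integer `c(nx, ny)` image size in pixels.
#' @slot pixelSize micrometers per pixel.
#' @slot edgeBrightness,interiorBrightness,backgroundMix intensities in
#'   `[0, 1]`: ridge level, cell interior level, amplitude of the smooth
#'   background reflectance field.
#' @slot blobsPerCell expected hypo-reflective blobs per cell (>= 0).
#' @slot blobRadius nominal blob radius, micrometers.
#' @slot blobRoughness boundary perturbation amplitude in `[0, 1]`.
#' @slot noiseSd additive Gaussian noise SD (intensity units).
#' @slot lowqFraction fraction of the field degraded to sub-threshold
#'   quality (blurred, contrast-compressed strip), in `[0, 1]`.
#' @slot seed integer RNG seed.
#' @export
setClass("MosaicParams",
  representation(
    latticeSpacing = "numeric", disorder = "numeric",
    imageSize = "integer", pixelSize = "numeric",
    edgeBrightness = "numeric", interiorBrightness = "numeric",
    backgroundMix = "numeric", blobsPerCell = "numeric",
    blobRadius = "numeric", blobRoughness = "numeric",
    noiseSd = "numeric", lowqFraction = "numeric", seed = "integer"
  )
)

setValidity("MosaicParams", function(object) {
  msg <- character()
  if (object@latticeSpacing <= 0) msg <- c(msg, "latticeSpacing must be > 0")
  if (object@disorder < 0) msg <- c(msg, "disorder must be >= 0")
  if (length(object@imageSize) != 2L || any(object@imageSize < 1L))
    msg <- c(msg, "imageSize must be two positive integers")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  ints <- c(object@edgeBrightness, object@interiorBrightness,
            object@backgroundMix)
  if (any(ints < 0 | ints > 1))
    msg <- c(msg, "intensity parameters must lie in [0, 1]")
  if (object@blobsPerCell < 0) msg <- c(msg, "blobsPerCell must be >= 0")
  if (object@blobRoughness < 0 || object@blobRoughness > 1)
    msg <- c(msg, "blobRoughness must lie in [0, 1]")
  if (object@lowqFraction < 0 || object@lowqFraction > 1)
    msg <- c(msg, "lowqFraction must lie in [0, 1]")
  if (object@blobsPerCell > 0 &&
      object@blobRadius >= object@latticeSpacing / 2)
    msg <- c(msg, "blobRadius must be < latticeSpacing/2 (blobs would merge across cells)")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Ground truth of a synthetic mosaic
#'
#' @slot centers matrix of cell-center coordinates (x, y) in micrometers.
#' @slot cellPolygons list of Voronoi cell polygons (vertex matrices, um).
#' @slot blobContours list of blob boundary polygons (vertex matrices, um).
#' @slot blobCell integer index of the parent cell of each blob.
#' @slot degradedMask logical matrix (dim1 = x), TRUE where the image was
#'   degraded to low quality.
#' @export
setClass("GroundTruth",
  representation(centers = "matrix", cellPolygons = "list",
                 blobContours = "list", blobCell = "integer",
                 degradedMask = "matrix")
)

#' Tile-based quality scores and the analyzable-pixel mask
#'
#' @slot tileSize tile edge length in pixels.
#' @slot scores per-tile quality scores in `[0, 1]` (dim1 = tile column).
#' @slot threshold score threshold in `[0, 1]`; a pixel is analyzable iff
#'   its tile score is >= threshold.
#' @slot mask logical matrix, image-sized (dim1 = x); TRUE = analyzable.
#' @slot nonMaskedPortion fraction of analyzable pixels, exactly
#'   `sum(mask) / length(mask)`.
#' @export
setClass("QualityMask",
  representation(tileSize = "integer", scores = "matrix",
                 threshold = "numeric", mask = "matrix",
                 nonMaskedPortion = "numeric")
)

setValidity("QualityMask", function(object) {
  if (any(object@scores < -1e-9 | object@scores > 1 + 1e-9))
    return("scores must lie in [0, 1]")
  if (object@threshold < 0 || object@threshold > 1)
    return("threshold must lie in [0, 1]")
  if (!is.logical(object@mask)) return("mask must be logical")
  p <- sum(object@mask) / length(object@mask)
  if (abs(p - object@nonMaskedPortion) > 1e-12)
    return("nonMaskedPortion must equal sum(mask)/length(mask) exactly")
  TRUE
})

#' Bounded Voronoi tessellation of detected cell centers
#'
#' @slot centers matrix of site coordinates (x, y), micrometers.
#' @slot polygons list of clipped Voronoi polygons (CCW vertex matrices, um).
#' @slot neighbors list of integer vectors: indices of cells sharing a
#'   finite Voronoi edge (symmetric relation).
#' @slot keptFlags logical; FALSE for cells removed by the border filter.
#' @slot bounds numeric `c(xmin, ymin, xmax, ymax)` clipping rectangle, um.
#' @export
setClass("Tessellation",
  representation(centers = "matrix", polygons = "list", neighbors = "list",
                 keptFlags = "logical", bounds = "numeric")
)

setValidity("Tessellation", function(object) {
  n <- nrow(object@centers)
  if (length(object@polygons) != n || length(object@neighbors) != n ||
      length(object@keptFlags) != n)
    return("polygons, neighbors and keptFlags must match the number of centers")
  for (i in seq_len(n)) {
    for (j in object@neighbors[[i]]) {
      if (!(i %in% object@neighbors[[j]]))
        return("neighbor relation must be symmetric")
    }
  }
  TRUE
})

#' Per-image mosaic morphometry summary
#'
#' Per-cell metrics (area, perimeter, equivalent diameter, neighbor count)
#' for kept cells, their per-image mean and sample SD, Voronoi density in
#' cells/mm^2 and the non-masked portion. Neighbor counts are taken over the
#' full tessellation graph so that an undisturbed hexagonal mosaic has
#' exactly six neighbors per cell (see the package vignette).
#'
#' @slot perCell data.frame with columns `area_um2`, `perimeter_um`,
#'   `eq_diameter_um`, `n_neighbors` for kept cells.
#' @slot imageStats named numeric vector of per-image means and sample SDs.
#' @slot density kept cells per square millimeter of unmasked area.
#' @slot nonMaskedPortion fraction of analyzable pixels after border filter.
#' @export
setClass("MosaicSummary",
  representation(perCell = "data.frame", imageStats = "numeric",
                 density = "numeric", nonMaskedPortion = "numeric")
)

#' Segmented intracellular hypo-reflective regions with shape descriptors
#'
#' @slot contours list of closed boundary polygons (vertex matrices, um).
#' @slot perRegion data.frame with columns `area_um2`, `perimeter_um`,
#'   `solidity`, `circularity`.
#' @slot imageStats named numeric vector of per-image means and sample SDs.
#' @slot density regions per square millimeter of unmasked area.
#' @slot nonMaskedPortion fraction of analyzable pixels.
#' @slot nDropped count of degenerate (zero-area) contours dropped.
#' @export
setClass("HypoRegionSet",
  representation(contours = "list", perRegion = "data.frame",
                 imageStats = "numeric", density = "numeric",
                 nonMaskedPortion = "numeric", nDropped = "integer")
)

setValidity("HypoRegionSet", function(object) {
  if (nrow(object@perRegion)) {
    s <- object@perRegion$solidity
    ci <- object@perRegion$circularity
    if (any(s <= 0 | s > 1 + 1e-9)) return("solidity must lie in (0, 1]")
    if (any(ci <= 0 | ci > 1.05))
      return("circularity must lie in (0, 1 + digitization tolerance]")
  }
  TRUE
})

#' Physical pixel-size model for AO-TFI montages
#'
#' Pixel size in micrometers per pixel as an affine function of the eye's
#' spherical-equivalent refraction RE (diopters) and axial length AL (mm):
#' `a*RE + b*(AL - 23.5) + c`. The default coefficients are placeholders to
#' be replaced by device calibration values.
#'
#' @slot a um/px per diopter.
#' @slot b um/px per millimeter of axial length above the 23.5 mm reference.
#' @slot c um/px at RE = 0 D, AL = 23.5 mm; must be positive.
#' @export
setClass("ScalingModel",
  representation(a = "numeric", b = "numeric", c = "numeric")
)

setValidity("ScalingModel", function(object) {
  if (object@c <= 0) return("c must be > 0 (pixel size at the reference eye)")
  TRUE
})

#' Similarity transform (uniform scale + rotation + translation)
#'
#' Maps source-frame coordinates to target-frame coordinates as
#' `R(rotation) * scale * p + translation`.
#'
#' @slot scale dimensionless positive scale factor.
#' @slot rotation rotation angle, radians (counter-clockwise).
#' @slot translation numeric length-2 translation in target-frame units.
#' @export
setClass("SimilarityTransform",
  representation(scale = "numeric", rotation = "numeric",
                 translation = "numeric")
)

setValidity("SimilarityTransform", function(object) {
  if (object@scale <= 0) return("scale must be > 0")
  if (length(object@translation) != 2L)
    return("translation must have length 2")
  TRUE
})

#' Group effect applied to the simulated CSCR arm
#'
#' Additive shifts applied to the generator parameters of "CSCR" eyes
#' relative to the healthy baseline: more lattice disorder (greater
#' dispersion of neighbor counts) and rougher hypo-reflective blob
#' boundaries (lower mean circularity/solidity, more dispersed solidity and
#' perimeter), matching the direction of the clinical findings.
#'
#' @slot disorderDelta added to `disorder`.
#' @slot roughnessDelta added to `blobRoughness`.
#' @export
setClass("EffectSpec",
  representation(disorderDelta = "numeric", roughnessDelta = "numeric")
)
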