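#' Construct synthetic-mosaic generator parameters
#'
#' Defaults describe a healthy perifoveal RPE mosaic as seen by AO-TFI:
#' ~14 um cell spacing (about 5000 cells/mm^2), mild lattice disorder
#' (`disorder = 0.18` yields about 75% hexagonal cells, matching healthy
#' epithelial mosaics; below ~0.12 the hexagonal topology is rigid and the
#' neighbor-count SD degenerates to exactly zero), one
#' intracellular hypo-reflective blob of ~3 um radius per cell with a gently
#' irregular boundary, bright cell edges over darker interiors, a weak
#' smooth background reflectance field and mild sensor noise. The field is
#' 512 x 512 px at 0.7 um/px (~360 um square), comfortably above the
#' system's 3 um lateral resolution.
#'
#' @param latticeSpacing cell spacing, um.
#' @param disorder center jitter SD as a fraction of the spacing.
#' @param imageSize integer `c(nx, ny)` in pixels.
#' @param pixelSize um per pixel.
#' @param edgeBrightness,interiorBrightness,backgroundMix intensities in
#'   `[0, 1]` (ridge level, interior level, background variation amplitude).
#' @param blobsPerCell integer hypo-reflective blobs drawn per cell.
#' @param blobRadius nominal blob radius, um.
#' @param blobRoughness blob boundary perturbation amplitude in `[0, 1]`.
#' @param noiseSd additive Gaussian noise SD, intensity units.
#' @param lowqFraction fraction of the field degraded to low quality.
#' @param seed integer RNG seed.
#' @return A [MosaicParams-class] object.
#' @examples
#' p <- mosaicParams(disorder = 0, imageSize = c(256L, 256L))
#' p
#' @export
mosaicParams <- function(latticeSpacing = 14, disorder = 0.18,
                         imageSize = c(512L, 512L), pixelSize = 0.7,
                         edgeBrightness = 0.8, interiorBrightness = 0.35,
                         backgroundMix = 0.06, blobsPerCell = 1,
                         blobRadius = 3, blobRoughness = 0.1,
                         noiseSd = 0.02, lowqFraction = 0, seed = 1L) {
  if (latticeSpacing <= 0) stopParam("latticeSpacing must be > 0")
  new("MosaicParams",
      latticeSpacing = latticeSpacing, disorder = disorder,
      imageSize = as.integer(imageSize), pixelSize = pixelSize,
      edgeBrightness = edgeBrightness,
      interiorBrightness = interiorBrightness,
      backgroundMix = backgroundMix, blobsPerCell = blobsPerCell,
      blobRadius = blobRadius, blobRoughness = blobRoughness,
      noiseSd = noiseSd, lowqFraction = lowqFraction,
      seed = as.integer(seed))
}

#' Construct a CSCR-like group effect for the cohort simulator
#'
#' The defaults raise lattice disorder from the healthy baseline 0.18 to
#' 0.30 and blob boundary roughness from 0.10 to 0.25 in the simulated CSCR
#' arm, reproducing the direction of the clinical findings: greater
#' dispersion of neighbor counts, lower mean blob circularity and solidity,
#' and greater dispersion of blob solidity and perimeter. A zero effect
#' (`effectSpec(0, 0)`) yields exchangeable groups for type-I-error checks.
#'
#' @param disorderDelta added to the healthy `disorder`.
#' @param roughnessDelta added to the healthy `blobRoughness`.
#' @return An [EffectSpec-class] object.
#' @export
effectSpec <- function(disorderDelta = 0.12, roughnessDelta = 0.15) {
  new("EffectSpec", disorderDelta = disorderDelta,
      roughnessDelta = roughnessDelta)
}

#' Construct the physical pixel-size model
#'
#' @param a um/px per diopter of spherical equivalent.
#' @param b um/px per mm of axial length above 23.5 mm.
#' @param c um/px at the reference eye (RE = 0 D, AL = 23.5 mm).
#' @return A [ScalingModel-class] object.
#' @note The default coefficients are placeholders; replace them with the
#'   device calibration for quantitative use.
#' @export
scalingModel <- function(a = 0.02, b = 0.5, c = 0.7) {
  new("ScalingModel", a = a, b = b, c = c)
}

#' Construct a similarity transform
#'
#' @param scale positive scale factor.
#' @param rotation rotation in radians (counter-clockwise).
#' @param translation length-2 numeric translation.
#' @return A [SimilarityTransform-class] object.
#' @export
similarityTransform <- function(scale = 1, rotation = 0,
                                translation = c(0, 0)) {
  new("SimilarityTransform", scale = scale, rotation = rotation,
      translation = as.numeric(translation))
}
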