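# Segmentation of intracellular hypo-reflective regions and shape
# descriptors. The threshold is locally adaptive (local mean minus
# k * local SD over a window of about two cell diameters), which tracks the
# mixed reflectance background of AO-TFI mosaics; connected components
# within size bounds are kept and their boundaries traced as closed
# polygons.

#' Segment hypo-reflective regions with a locally adaptive threshold
#'
#' Pixels darker than `localMean - k * localSD` (box window of `window` px)
#' are labeled; 8-connected components with pixel count in
#' `[minArea, maxArea]` that lie entirely in the analyzable region (and away
#' from the image border) are kept. Boundaries are traced along the outer
#' pixel centers, lightly smoothed (circular 3-point vertex average) to
#' remove rasterization staircase, and returned in um.
#'
#' @param image a [MosaicImage-class].
#' @param qmask optional [QualityMask-class]; regions touching masked pixels
#'   are discarded.
#' @param k threshold depth in local SD units (default 0.8).
#' @param window adaptive window edge in px (default 96; use about two cell
#'   diameters).
#' @param minArea,maxArea component size bounds in pixels; `maxArea`
#'   defaults to the area of one lattice cell at `spacing`.
#' @param spacing expected cell spacing in um (sets the default `maxArea`).
#' @return list of closed contour polygons (matrices, um).
#' @export
segmentHyporeflective <- function(image, qmask = NULL, k = 0.8,
                                  window = 96L, minArea = 4L,
                                  maxArea = NULL, spacing = 14) {
  stopifnot(is(image, "MosaicImage"))
  img <- image@image
  ps <- image@pixelSize
  nx <- nrow(img); ny <- ncol(img)
  mask <- if (is.null(qmask)) matrix(TRUE, nx, ny) else qmask@mask
  if (!any(mask)) stopValidation("no unmasked area to segment")
  if (is.null(maxArea))
    maxArea <- ceiling(sqrt(3) / 2 * spacing^2 / ps^2)
  w <- as.integer(window)
  if (w %% 2L == 0L) w <- w + 1L
  mu <- boxMean(img, w)
  mu2 <- boxMean(img * img, w)
  sdl <- sqrt(pmax(0, mu2 - mu^2))
  dark <- (img < mu - k * sdl) & mask
  if (!any(dark)) return(list())
  # watershed on the distance map splits touching regions at their necks
  lab <- EBImage::watershed(EBImage::distmap(dark), tolerance = 1)
  nlab <- max(lab)
  if (nlab == 0) return(list())
  sizes <- tabulate(lab[lab > 0], nbins = nlab)
  okSize <- which(sizes >= minArea & sizes <= maxArea)
  if (length(okSize) == 0L) return(list())
  # drop components touching the image border or adjacent to masked pixels
  border <- unique(c(lab[1, ], lab[nx, ], lab[, 1], lab[, ny]))
  okSize <- setdiff(okSize, border[border > 0])
  if (!is.null(qmask) && any(!mask)) {
    # drop components adjacent to masked pixels (mask dilated by one pixel)
    nearMask <- EBImage::dilate(!mask, EBImage::makeBrush(3, "box")) > 0
    badm <- unique(lab[nearMask & lab > 0])
    okSize <- setdiff(okSize, badm)
  }
  if (length(okSize) == 0L) return(list())
  keepLab <- array(0L, dim = dim(lab))
  keepLab[lab %in% okSize] <- lab[lab %in% okSize]
  oc <- EBImage::ocontour(keepLab)
  oc <- oc[vapply(oc, nrow, integer(1)) >= 3L]
  lapply(oc, function(p) {
    p <- as.matrix(p)
    n <- nrow(p)
    # circular 3-point smoothing of the traced boundary
    prev <- p[c(n, seq_len(n - 1L)), , drop = FALSE]
    nxt <- p[c(seq_len(n - 1L) + 1L, 1L), , drop = FALSE]
    p <- (prev + p + nxt) / 3
    # the trace runs through outer pixel centers; push each vertex out by
    # half a pixel (radially from the centroid) to the half-pixel boundary,
    # removing the systematic area shrinkage of center-traced contours
    ctr <- colMeans(p)
    d <- sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)
    d[d < 1e-9] <- 1e-9
    p <- p + 0.5 * (p - rep(ctr, each = n)) / d
    p * ps
  })
}

# Shape descriptors of one closed polygon: area (shoelace), perimeter,
# solidity (area / convex hull area) and circularity (4*pi*A / P^2, the
# isoperimetric ratio of the area to that of the circle with the same
# perimeter -- the only reading of "ratio to its perfect circle area"
# bounded by one).
polygonDescriptors <- function(poly) {
  A <- polygonArea(poly)
  P <- polygonPerimeter(poly)
  if (A <= 0 || P <= 0) return(NULL)
  H <- convexHullArea(poly)
  c(area = A, perimeter = P,
    solidity = min(1, A / H),
    circularity = 4 * pi * A / P^2)
}

#' Shape descriptors of hypo-reflective regions
#'
#' @param contours list of closed polygons in um, e.g. from
#'   [segmentHyporeflective()] or synthetic blob ground truth.
#' @param unmaskedAreaUm2 analyzable area in um^2 (density denominator).
#' @param nonMaskedPortion analyzable fraction carried into the summary.
#' @return a [HypoRegionSet-class]; degenerate (zero-area) contours are
#'   dropped and counted in `nDropped`.
#' @export
shapeDescriptors <- function(contours, unmaskedAreaUm2,
                             nonMaskedPortion = NA_real_) {
  pstats <- poly_stats_cpp(contours)
  ok <- pstats[, "area"] > 0 & pstats[, "perimeter"] > 0
  nDropped <- sum(!ok)
  contours <- contours[ok]
  pstats <- pstats[ok, , drop = FALSE]
  if (length(contours) == 0L) {
    return(new("HypoRegionSet", contours = list(),
               perRegion = data.frame(area_um2 = numeric(0),
                                      perimeter_um = numeric(0),
                                      solidity = numeric(0),
                                      circularity = numeric(0)),
               imageStats = c(n_regions = 0), density = 0,
               nonMaskedPortion = nonMaskedPortion,
               nDropped = as.integer(nDropped)))
  }
  A <- pstats[, "area"]; P <- pstats[, "perimeter"]
  # digitization can push the isoperimetric ratio slightly above 1
  perRegion <- data.frame(area_um2 = A,
                          perimeter_um = P,
                          solidity = pmin(1, A / pstats[, "hull_area"]),
                          circularity = pmin(4 * pi * A / P^2, 1.05))
  st <- c(area_mean = mean(perRegion$area_um2),
          area_sd = sampleSD(perRegion$area_um2),
          perimeter_mean = mean(perRegion$perimeter_um),
          perimeter_sd = sampleSD(perRegion$perimeter_um),
          solidity_mean = mean(perRegion$solidity),
          solidity_sd = sampleSD(perRegion$solidity),
          circularity_mean = mean(perRegion$circularity),
          circularity_sd = sampleSD(perRegion$circularity),
          n_regions = nrow(perRegion))
  dens <- nrow(perRegion) / (unmaskedAreaUm2 / 1e6)
  new("HypoRegionSet", contours = contours, perRegion = perRegion,
      imageStats = st, density = dens,
      nonMaskedPortion = nonMaskedPortion, nDropped = as.integer(nDropped))
}
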