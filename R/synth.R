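# Synthetic AO-TFI mosaic generator: jittered hexagonal lattice of cell
# centers, bright Voronoi-edge ridges over dark interiors, per-cell
# hypo-reflective blobs with Fourier-perturbed boundaries, smooth background
# reflectance, optional degraded strip and sensor noise. All randomness is
# derived from the seed in MosaicParams via a documented splitting rule
# (childSeeds), so images and ground truth are bit-reproducible.

fieldBounds <- function(params) {
  ps <- params@pixelSize
  c(xmin = -ps / 2, ymin = -ps / 2,
    xmax = (params@imageSize[1] - 0.5) * ps,
    ymax = (params@imageSize[2] - 0.5) * ps)
}

#' Generate synthetic RPE cell centers
#'
#' Places sites on a hexagonal lattice covering the image field (with a one-
#' spacing margin so boundary cells are well formed) and jitters each site
#' independently by an isotropic Gaussian with SD `disorder * latticeSpacing`.
#' `disorder = 0` returns the exact lattice.
#'
#' @param params a [MosaicParams-class] object.
#' @return numeric matrix of (x, y) center coordinates in micrometers.
#' @examples
#' ctr <- generateCenters(mosaicParams(disorder = 0, imageSize = c(128L, 128L)))
#' head(ctr)
#' @export
generateCenters <- function(params) {
  stopifnot(is(params, "MosaicParams"))
  validObject(params)
  s <- params@latticeSpacing
  b <- fieldBounds(params)
  if ((b["xmax"] - b["xmin"]) < 3 * s || (b["ymax"] - b["ymin"]) < 3 * s)
    stopParam("image too small for a 3x3 lattice at spacing %.3g um", s)
  dy <- s * sqrt(3) / 2
  margin <- 1.5 * s
  rows <- seq(floor((b["ymin"] - margin) / dy), ceiling((b["ymax"] + margin) / dy))
  pts <- lapply(rows, function(r) {
    off <- ifelse(r %% 2 == 0, 0, s / 2)
    x <- seq(floor((b["xmin"] - margin - off) / s),
             ceiling((b["xmax"] + margin - off) / s)) * s + off
    cbind(x = x, y = rep(r * dy, length(x)))
  })
  ctr <- do.call(rbind, pts)
  if (params@disorder > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(params@seed)
    ctr <- ctr + matrix(rnorm(length(ctr), sd = params@disorder * s),
                        ncol = 2)
  }
  unname(ctr)
}

# Radial blob boundary: disc of radius r0 perturbed by low-order Fourier
# harmonics with relative amplitude set by roughness. Returns a closed
# polygon (not repeating the first vertex) and the radial function used for
# rasterization, so drawn pixels and the ground-truth contour agree.
blobShape <- function(center, r0, roughness, nHarm = 5L, nVert = 48L) {
  if (roughness > 0) {
    amp <- roughness * 0.35 / sqrt(nHarm)
    a <- rnorm(nHarm, sd = amp)
    bb <- rnorm(nHarm, sd = amp)
  } else {
    a <- bb <- numeric(nHarm)
  }
  ks <- seq(2L, length.out = nHarm)
  radial <- function(theta) {
    pert <- 1 + drop(cos(outer(theta, ks)) %*% a + sin(outer(theta, ks)) %*% bb)
    pmax(0.25, pmin(1.9, pert)) * r0
  }
  if (nHarm == 5L && nVert == 48L) {
    # cached Fourier basis for the default discretization
    r <- pmax(0.25, pmin(1.9, 1 + drop(.blobCosBasis %*% a +
                                       .blobSinBasis %*% bb))) * r0
    poly <- cbind(center[1] + r * .blobCosTh, center[2] + r * .blobSinTh)
  } else {
    th <- 2 * pi * (seq_len(nVert) - 1L) / nVert
    r <- radial(th)
    poly <- cbind(center[1] + r * cos(th), center[2] + r * sin(th))
  }
  list(polygon = poly, radial = radial, center = center)
}

.blobThetaDefault <- 2 * pi * (0:47) / 48
.blobCosTh <- cos(.blobThetaDefault)
.blobSinTh <- sin(.blobThetaDefault)
.blobCosBasis <- cos(outer(.blobThetaDefault, 2:6))
.blobSinBasis <- sin(outer(.blobThetaDefault, 2:6))

#' Render a synthetic AO-TFI mosaic image with ground truth
#'
#' Draws bright ridges along the Voronoi boundaries of the supplied centers
#' (Gaussian profile on the distance to the boundary, computed from the two
#' nearest sites), dark cell interiors, per-cell hypo-reflective blobs, a
#' smooth mixed-reflectance background, an optional degraded (blurred,
#' contrast-compressed) strip of width `lowqFraction * nx`, and additive
#' Gaussian noise. Intensities are clipped to `[0, 1]`.
#'
#' @param centers matrix of (x, y) cell centers in um, e.g. from
#'   [generateCenters()].
#' @param params a [MosaicParams-class] object.
#' @return list with elements `image` ([MosaicImage-class]) and `truth`
#'   ([GroundTruth-class]).
#' @export
renderMosaic <- function(centers, params) {
  stopifnot(is(params, "MosaicParams"))
  validObject(params)
  if (!is.matrix(centers) || nrow(centers) < 1L)
    stopParam("centers must be a non-empty matrix")
  if (params@blobsPerCell > 0 &&
      params@blobRadius >= params@latticeSpacing / 2)
    stopParam("blobRadius must be < latticeSpacing/2")
  nx <- params@imageSize[1]; ny <- params@imageSize[2]
  ps <- params@pixelSize
  s <- params@latticeSpacing
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  cs <- childSeeds(params@seed, 3L)

  g <- grid_nearest2_cpp(nx, ny, ps, centers)
  ridgeW <- 0.8  # um; Gaussian half-width of the bright cell edges
  ridge <- exp(-((g$d2 - g$d1) / 2)^2 / (2 * ridgeW^2))

  base <- matrix(params@interiorBrightness, nx, ny)
  if (params@backgroundMix > 0) {
    set.seed(cs[1])
    bg <- matrix(rnorm(nx * ny), nx, ny)
    bg <- gblurCapped(bg, sigma = max(2, s / ps))
    bg <- (bg - mean(bg)) / max(sd(bg), 1e-12)
    base <- base + params@backgroundMix * bg
  }
  img <- base * (1 - ridge) + params@edgeBrightness * ridge

  # hypo-reflective blobs, one radial shape per (cell, blob)
  blobContours <- list()
  blobCell <- integer(0)
  if (params@blobsPerCell >= 1) {
    set.seed(cs[2])
    b <- fieldBounds(params)
    inField <- centers[, 1] > b["xmin"] & centers[, 1] < b["xmax"] &
               centers[, 2] > b["ymin"] & centers[, 2] < b["ymax"]
    lvl <- 0.3 * params@interiorBrightness
    idxIn <- which(inField)
    # Each clipped Voronoi cell contains the ball around its site whose
    # radius is the smaller of half the nearest-site distance and the
    # clearance to the field bounds; shrinking the blob offset and boundary
    # into that ball guarantees the ground-truth invariant that every blob
    # lies inside its parent cell, even for cells squeezed by disorder or
    # cut by the field edge.
    clearance <- pmin(0.5 * nearestSiteDistance(centers, idxIn),
                      centers[idxIn, 1] - b["xmin"],
                      b["xmax"] - centers[idxIn, 1],
                      centers[idxIn, 2] - b["ymin"],
                      b["ymax"] - centers[idxIn, 2])
    for (w in seq_along(idxIn)) {
      ci <- idxIn[w]
      for (k in seq_len(round(params@blobsPerCell))) {
        ang <- runif(1, 0, 2 * pi)
        rad <- runif(1, 0, 0.12 * s)
        r0 <- params@blobRadius * exp(rnorm(1, sd = 0.08))
        r0 <- min(r0, 0.45 * s / 1.9)
        sh <- blobShape(c(0, 0), r0, params@blobRoughness)
        vr <- sqrt(rowSums(sh$polygon^2))
        fac <- min(1, 0.98 * clearance[w] / (rad + max(vr)))
        if (fac * max(vr) < 0.5 * ps) next  # sub-pixel blob: drop it
        q <- centers[ci, ] + fac * rad * c(cos(ang), sin(ang))
        poly <- cbind(q[1] + fac * sh$polygon[, 1],
                      q[2] + fac * sh$polygon[, 2])
        blobContours[[length(blobContours) + 1L]] <- poly
        blobCell <- c(blobCell, ci)
        # rasterize via the radial function on the blob's bounding box
        rmax <- fac * max(vr)
        i0 <- max(1L, floor((q[1] - rmax) / ps) + 1L)
        i1 <- min(nx, ceiling((q[1] + rmax) / ps) + 1L)
        j0 <- max(1L, floor((q[2] - rmax) / ps) + 1L)
        j1 <- min(ny, ceiling((q[2] + rmax) / ps) + 1L)
        if (i0 > i1 || j0 > j1) next
        px <- (i0:i1 - 1) * ps - q[1]
        py <- (j0:j1 - 1) * ps - q[2]
        dx <- matrix(px, length(px), length(py))
        dy <- matrix(py, length(px), length(py), byrow = TRUE)
        dd <- sqrt(dx^2 + dy^2)
        th <- atan2(dy, dx)
        inside <- dd < fac * matrix(sh$radial(as.vector(th)),
                                    nrow(dd), ncol(dd))
        sub <- img[i0:i1, j0:j1]
        sub[inside] <- lvl
        img[i0:i1, j0:j1] <- sub
      }
    }
  }

  degraded <- matrix(FALSE, nx, ny)
  if (params@lowqFraction > 0) {
    wd <- round(params@lowqFraction * nx)
    if (wd >= 1) {
      cols <- (nx - wd + 1L):nx
      blur <- gblurCapped(img, sigma = max(3, 1.5 * s / ps))
      m <- mean(img[cols, ])
      img[cols, ] <- m + 0.15 * (blur[cols, ] - m)
      degraded[cols, ] <- TRUE
    }
  }

  if (params@noiseSd > 0) {
    set.seed(cs[3])
    img <- img + matrix(rnorm(nx * ny, sd = params@noiseSd), nx, ny)
  }
  img <- pmax(pmin(img, 1), 0)  # attributes (dim) follow the first argument

  b <- fieldBounds(params)
  vor <- voronoi_cells_cpp(centers, b["xmin"], b["ymin"], b["xmax"],
                           b["ymax"], 0)
  truth <- new("GroundTruth", centers = centers,
               cellPolygons = vor$polygons, blobContours = blobContours,
               blobCell = blobCell, degradedMask = degraded)
  mi <- new("MosaicImage", image = img, pixelSize = ps,
            metadata = list(synthetic = TRUE, seed = params@seed,
                            latticeSpacing = s))
  list(image = mi, truth = truth)
}
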