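# Synthetic two-group cohorts: "healthy" eyes drawn from the baseline
# parameters and "CSCR" eyes with elevated lattice disorder and blob
# roughness (see effectSpec). Eye-level biological heterogeneity is modeled
# as small Gaussian perturbations of disorder and roughness around the group
# value. The default analysis path measures the generated geometry directly
# (Voronoi tessellation of the true centers, shape descriptors of the true
# blob contours) through the same measurement code used on images, which
# keeps large simulation ensembles tractable; set render = TRUE to obtain
# rasterized images with ground truth instead.

truncNorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lo | x >= hi)
  for (i in bad) {
    for (tries in 1:100) {
      v <- rnorm(1, mean, sd)
      if (v > lo && v < hi) { x[i] <- v; break }
      if (tries == 100) x[i] <- min(max(v, lo + 1e-6), hi - 1e-6)
    }
  }
  x
}

# Tessellation + blob-shape features of one synthetic image, measured on
# the generated geometry. Uses the same C++ core and formulas as the public
# API path (voronoiPartition -> filterBorderCells -> mosaicMetrics and
# shapeDescriptors) but skips intermediate object construction, so large
# cohort ensembles stay tractable; the equivalence is covered by tests.
imageGeometryFeatures <- function(params, withBlobs = TRUE) {
  centers <- generateCenters(params)
  b <- fieldBounds(params)
  n <- nrow(centers)
  jit <- 1e-8 * max(b[3] - b[1], b[4] - b[2]) *
    cbind(sin(seq_len(n) * 12.9898), cos(seq_len(n) * 78.233))
  cj <- centers + jit
  v <- voronoi_cells_cpp(cj, b[1], b[2], b[3], b[4], params@pixelSize)
  kept <- which(!v$on_bounds)
  nnAll <- tabulate(c(v$edges[, 1], v$edges[, 2]), nbins = n)
  nn <- nnAll[kept]
  st <- poly_stats_cpp(v$polygons[kept])
  area <- st[, "area"]; per <- st[, "perimeter"]
  eqd <- 2 * sqrt(area / pi)
  unmasked <- sum(area)
  out <- c(nn_mean = mean(nn), nn_sd = sampleSD(nn),
           area_mean = mean(area), area_sd = sampleSD(area),
           perimeter_mean = mean(per), perimeter_sd = sampleSD(per),
           eqd_mean = mean(eqd), eqd_sd = sampleSD(eqd),
           cell_density = length(kept) / (unmasked / 1e6))
  if (withBlobs && params@blobsPerCell >= 1) {
    s <- params@latticeSpacing
    perCell <- round(params@blobsPerCell)
    ki <- rep(kept, each = perCell)
    nb <- length(ki)
    # nearest-site distance per site from the edge list (the nearest
    # neighbor always shares a Voronoi edge; kept cells are interior, so
    # their edges survive the bounds clipping)
    e1 <- v$edges[, 1]; e2 <- v$edges[, 2]
    de <- sqrt((centers[e1, 1] - centers[e2, 1])^2 +
               (centers[e1, 2] - centers[e2, 2])^2)
    ii <- c(e1, e2); dd <- rep(de, 2L)
    ord <- order(ii, dd)
    firsts <- !duplicated(ii[ord])
    dminAll <- rep(Inf, n)
    dminAll[ii[ord][firsts]] <- dd[ord][firsts]
    ang <- runif(nb, 0, 2 * pi)
    rad <- runif(nb, 0, 0.12 * s)
    r0 <- pmin(params@blobRadius * exp(rnorm(nb, sd = 0.08)), 0.45 * s / 1.9)
    amp <- params@blobRoughness * 0.35 / sqrt(5)
    A <- matrix(rnorm(nb * 5L, sd = amp), nb, 5L)
    B <- matrix(rnorm(nb * 5L, sd = amp), nb, 5L)
    Rm <- 1 + tcrossprod(A, .blobCosBasis) + tcrossprod(B, .blobSinBasis)
    Rm <- pmin(pmax(Rm, 0.25), 1.9) * r0  # pmax first so dims are kept
    # same containment shrink as renderMosaic: keep each blob inside the
    # inscribed ball (radius dmin/2) of its parent cell
    fac <- pmin(1, 0.98 * 0.5 * dminAll[ki] /
                     (rad + apply(Rm, 1, max)))
    rad <- fac * rad
    Rm <- fac * Rm
    qx <- centers[ki, 1] + rad * cos(ang)
    qy <- centers[ki, 2] + rad * sin(ang)
    X <- qx + Rm * matrix(.blobCosTh, nb, 48L, byrow = TRUE)
    Y <- qy + Rm * matrix(.blobSinTh, nb, 48L, byrow = TRUE)
    bs <- blob_stats_cpp(X, Y)
    ha <- bs[, "area"]; hp <- bs[, "perimeter"]
    sol <- pmin(1, ha / bs[, "hull_area"])
    circ <- pmin(4 * pi * ha / hp^2, 1.05)
    out <- c(out,
             hypo_area_mean = mean(ha), hypo_area_sd = sampleSD(ha),
             hypo_perim_mean = mean(hp), hypo_perim_sd = sampleSD(hp),
             hypo_solidity_mean = mean(sol), hypo_solidity_sd = sampleSD(sol),
             hypo_circ_mean = mean(circ), hypo_circ_sd = sampleSD(circ),
             hypo_density = nb / (unmasked / 1e6))
  }
  out
}

#' Generate a synthetic two-group cohort
#'
#' Draws `nEyesPerGroup` eyes per group. Healthy eyes use `healthyParams`;
#' CSCR eyes add the [effectSpec()] shifts to disorder and blob roughness.
#' Eye metadata is sampled as age ~ N(40, 10) years, AL ~ N(23.5, 0.8) mm
#' and RE ~ N(-0.5, 1.5) D truncated to the inclusion window (-6, +5) D.
#' Everything is reproducible from `seed` via per-eye/per-image child seeds.
#'
#' @param nEyesPerGroup eyes per group; either one count for both groups or
#'   a named vector `c(healthy = ..., CSCR = ...)`.
#' @param imagesPerEye perifoveal images per eye (cycled through Z1-Z4).
#' @param healthyParams baseline [MosaicParams-class].
#' @param effect an [EffectSpec-class]; `effectSpec(0, 0)` gives
#'   exchangeable groups.
#' @param seed root integer seed.
#' @param render if TRUE, return rendered [MosaicImage-class] objects with
#'   ground truth instead of geometry-measured features (slower).
#' @param eyeSdDisorder,eyeSdRoughness SD of the eye-level heterogeneity of
#'   the two generator parameters.
#' @return list with `eyes` (per-eye metadata), and either `images`
#'   (features per image, for `render = FALSE`) or `renders` (list of
#'   `renderMosaic()` outputs parallel to the `images` metadata rows).
#' @export
generateCohort <- function(nEyesPerGroup = c(healthy = 33, CSCR = 12),
                           imagesPerEye = 2,
                           healthyParams = mosaicParams(),
                           effect = effectSpec(), seed = 1L,
                           render = FALSE,
                           eyeSdDisorder = 0.015, eyeSdRoughness = 0.03) {
  if (length(nEyesPerGroup) == 1L)
    nEyesPerGroup <- c(healthy = nEyesPerGroup, CSCR = nEyesPerGroup)
  if (any(nEyesPerGroup < 1)) stopParam("need at least one eye per group")
  nH <- as.integer(nEyesPerGroup[["healthy"]])
  nC <- as.integer(nEyesPerGroup[["CSCR"]])
  nEyes <- nH + nC
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  eyeSeeds <- childSeeds(seed, nEyes)

  set.seed(childSeeds(seed, nEyes + 1L)[nEyes + 1L])
  eyes <- data.frame(
    eye_id = sprintf("eye%03d", seq_len(nEyes)),
    participant_id = sprintf("p%03d", seq_len(nEyes)),
    group = rep(c("healthy", "CSCR"), c(nH, nC)),
    age = truncNorm(nEyes, 40, 10, lo = 18),
    AL_mm = truncNorm(nEyes, 23.5, 0.8, lo = 20.5, hi = 29.5),
    RE_D = truncNorm(nEyes, -0.5, 1.5, lo = -6, hi = 5),
    stringsAsFactors = FALSE)
  isC <- eyes$group == "CSCR"
  eyes$disorder <- pmax(0.005, truncNorm(nEyes, 0, eyeSdDisorder) +
                        healthyParams@disorder +
                        ifelse(isC, effect@disorderDelta, 0))
  eyes$roughness <- pmin(0.9, pmax(0, truncNorm(nEyes, 0, eyeSdRoughness) +
                         healthyParams@blobRoughness +
                         ifelse(isC, effect@roughnessDelta, 0)))

  zones <- rep(c("Z1", "Z2", "Z3", "Z4"), length.out = imagesPerEye)
  rows <- vector("list", nEyes * imagesPerEye)
  renders <- if (render) vector("list", nEyes * imagesPerEye) else NULL
  r <- 0L
  for (e in seq_len(nEyes)) {
    imgSeeds <- childSeeds(eyeSeeds[e], imagesPerEye)
    for (k in seq_len(imagesPerEye)) {
      r <- r + 1L
      p <- healthyParams
      p@disorder <- eyes$disorder[e]
      p@blobRoughness <- eyes$roughness[e]
      p@seed <- imgSeeds[k]
      meta <- data.frame(image_id = sprintf("%s_img%02d", eyes$eye_id[e], k),
                         eye_id = eyes$eye_id[e], group = eyes$group[e],
                         zone = zones[k], seed = imgSeeds[k],
                         stringsAsFactors = FALSE)
      if (render) {
        ctr <- generateCenters(p)
        renders[[r]] <- renderMosaic(ctr, p)
        rows[[r]] <- meta
      } else {
        set.seed(imgSeeds[k])
        feat <- imageGeometryFeatures(p, withBlobs = p@blobsPerCell >= 1)
        rows[[r]] <- cbind(meta, as.data.frame(as.list(feat)))
      }
    }
  }
  images <- do.call(rbind, rows)
  out <- list(eyes = eyes, images = images)
  if (render) out$renders <- renders
  out
}
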