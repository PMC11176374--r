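test_that("parameter validation rejects impossible generators", {
  expect_error(mosaicParams(latticeSpacing = -1), class = "rpe_param_error")
  expect_error(mosaicParams(latticeSpacing = 0), class = "rpe_param_error")
  # blobs would merge across cells
  expect_error(mosaicParams(blobRadius = 7, latticeSpacing = 14),
               "blobRadius")
  # image too small for a 3x3 lattice
  p <- mosaicParams(imageSize = c(16L, 16L))
  expect_error(generateCenters(p), class = "rpe_param_error")
})

test_that("disorder = 0 yields the exact hexagonal lattice", {
  p <- mosaicParams(disorder = 0, imageSize = c(128L, 128L))
  ctr <- generateCenters(p)
  s <- p@latticeSpacing
  # nearest-neighbor distance is exactly the lattice spacing for every site
  nn <- vapply(seq_len(nrow(ctr)), function(i) {
    d2 <- (ctr[-i, 1] - ctr[i, 1])^2 + (ctr[-i, 2] - ctr[i, 2])^2
    sqrt(min(d2))
  }, numeric(1))
  expect_true(all(abs(nn - s) < 1e-9))
})

test_that("generation is deterministic in the seed", {
  p <- mosaicParams(imageSize = c(96L, 96L), seed = 11L)
  r1 <- renderMosaic(generateCenters(p), p)
  r2 <- renderMosaic(generateCenters(p), p)
  expect_identical(r1$image@image, r2$image@image)
  expect_identical(r1$truth@centers, r2$truth@centers)
  expect_identical(r1$truth@blobContours, r2$truth@blobContours)
  p3 <- mosaicParams(imageSize = c(96L, 96L), seed = 12L)
  r3 <- renderMosaic(generateCenters(p3), p3)
  expect_false(identical(r1$image@image, r3$image@image))
})

test_that("noise-free blob-free render has a bimodal intensity histogram", {
  p <- mosaicParams(disorder = 0, blobsPerCell = 0, noiseSd = 0,
                    backgroundMix = 0, imageSize = c(128L, 128L))
  img <- renderMosaic(generateCenters(p), p)$image@image
  nearInterior <- mean(abs(img - p@interiorBrightness) < 0.05)
  nearEdge <- mean(abs(img - p@edgeBrightness) < 0.05)
  expect_gt(nearInterior, 0.4)
  expect_gt(nearEdge, 0.05)
  # the two levels dominate; the ridge profile contributes the remainder
  expect_gt(nearInterior + nearEdge, 0.6)
  expect_true(all(img >= 0 & img <= 1))
})

test_that("lowqFraction = 0.3 degrades 30 +/- 2 % of the field", {
  p <- mosaicParams(lowqFraction = 0.3, imageSize = c(256L, 256L), seed = 4L)
  r <- renderMosaic(generateCenters(p), p)
  expect_equal(mean(r$truth@degradedMask), 0.3, tolerance = 0.02 / 0.3)
})

test_that("every blob contour lies inside its parent cell polygon", {
  p <- mosaicParams(imageSize = c(192L, 192L), seed = 5L)
  r <- renderMosaic(generateCenters(p), p)
  tr <- r$truth
  expect_length(tr@blobContours, length(tr@blobCell))
  ok <- vapply(seq_along(tr@blobContours), function(k) {
    cell <- tr@cellPolygons[[tr@blobCell[k]]]
    if (nrow(cell) < 3L) return(TRUE)  # cell clipped away outside the field
    bc <- tr@blobContours[[k]]
    all(pointsInPolygon(cell, bc[, 1], bc[, 2]))
  }, logical(1))
  expect_true(all(ok))
})

test_that("neighbor-count dispersion increases with lattice disorder", {
  meanNNSD <- vapply(c(0.05, 0.15, 0.30), function(d) {
    mean(vapply(1:6, function(s) {
      p <- mosaicParams(disorder = d, imageSize = c(192L, 192L), seed = s)
      ctr <- generateCenters(p)
      tess <- voronoiPartition(ctr, fieldBoundsOf(p))
      f <- filterBorderCells(tess)$tessellation
      nn <- lengths(neighborGraph(f)[keptFlags(f)])
      stats::sd(nn)
    }, numeric(1)))
  }, numeric(1))
  expect_true(meanNNSD[1] < meanNNSD[2])
  expect_true(meanNNSD[2] < meanNNSD[3])
})

test_that("blob solidity decreases as roughness increases", {
  sols <- vapply(c(0, 0.2, 0.4), function(rg) {
    mean(vapply(1:3, function(s) {
      p <- mosaicParams(blobRoughness = rg, imageSize = c(160L, 160L),
                        seed = s)
      r <- renderMosaic(generateCenters(p), p)
      hy <- shapeDescriptors(r$truth@blobContours,
                             unmaskedAreaUm2 = prod(p@imageSize) * p@pixelSize^2)
      unname(hy@imageStats["solidity_mean"])
    }, numeric(1)))
  }, numeric(1))
  expect_true(sols[1] > sols[2])
  expect_true(sols[2] > sols[3])
  expect_equal(sols[1], 1, tolerance = 1e-3)  # roughness 0 = digitized discs
})

test_that("cohort bookkeeping: rows, metadata windows, determinism", {
  p <- mosaicParams(imageSize = c(128L, 128L))
  co <- generateCohort(nEyesPerGroup = c(healthy = 3, CSCR = 2),
                       imagesPerEye = 2, healthyParams = p, seed = 7L)
  expect_identical(nrow(co$images), 10L)   # (3 + 2) eyes x 2 images
  expect_identical(nrow(co$eyes), 5L)
  expect_true(all(co$eyes$age > 18))
  expect_true(all(co$eyes$AL_mm > 20.5 & co$eyes$AL_mm < 29.5))
  expect_true(all(co$eyes$RE_D > -6 & co$eyes$RE_D < 5))
  co2 <- generateCohort(nEyesPerGroup = c(healthy = 3, CSCR = 2),
                        imagesPerEye = 2, healthyParams = p, seed = 7L)
  expect_identical(co$images, co2$images)
  expect_error(generateCohort(nEyesPerGroup = c(healthy = 0, CSCR = 2)),
               class = "rpe_param_error")
})
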