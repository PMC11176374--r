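test_that("pixel-size model: reference point, linearity, worked example", {
  m <- scalingModel(a = 0.02, b = 0.5, c = 0.7)
  expect_identical(predictPixelSize(0, 23.5, m), 0.7)
  expect_equal(predictPixelSize(3, 24, m) - predictPixelSize(2, 24, m), 0.02,
               tolerance = 1e-12)
  expect_equal(predictPixelSize(-2, 24.5, m), 1.16, tolerance = 1e-12)
  expect_error(predictPixelSize(0, 31, m), class = "rpe_param_error")
  expect_error(predictPixelSize(12, 24, m), class = "rpe_param_error")
  # inconsistent coefficients driving the size non-positive
  bad <- scalingModel(a = 0.02, b = 0.5, c = 0.1)
  expect_error(predictPixelSize(0, 22, bad), class = "rpe_validation_error")
  expect_error(scalingModel(c = -1))  # validity: c > 0
})

test_that("similarity estimation recovers a known transform to 1e-6", {
  set.seed(42)
  src <- matrix(runif(12, 0, 100), 6, 2)
  tr0 <- similarityTransform(scale = 1.8, rotation = 0.3,
                             translation = c(5, -7))
  dst <- applySimilarity(tr0, src)
  est <- estimateSimilarity(src, dst)
  expect_lt(abs(est@scale - 1.8), 1e-6)
  expect_lt(abs(est@rotation - 0.3), 1e-6)
  expect_lt(max(abs(est@translation - c(5, -7))), 1e-6)
  expect_lt(attr(est, "rmse"), 1e-9)
  # identity
  id <- estimateSimilarity(src, src)
  expect_lt(abs(id@scale - 1), 1e-9)
  expect_lt(abs(id@rotation), 1e-9)
  expect_lt(max(abs(id@translation)), 1e-9)
})

test_that("estimation preconditions and degeneracies", {
  src <- matrix(runif(12, 0, 100), 6, 2)
  expect_error(estimateSimilarity(src[1:3, ], src[1:3, ]),
               class = "rpe_validation_error")
  expect_error(estimateSimilarity(src, src[1:5, ]),
               class = "rpe_validation_error")
  expect_error(estimateSimilarity(matrix(1, 6, 2), matrix(1, 6, 2)),
               class = "rpe_validation_error")  # coincident points
  col <- cbind(1:6, 2 * (1:6))
  expect_warning(estimateSimilarity(col, col), "collinear")
})

test_that("residual RMS follows the sigma * sqrt(1 - 2/n) trend", {
  set.seed(9)
  tr0 <- similarityTransform(1.8, 0.3, c(5, -7))
  sigma <- 1
  meanRms <- vapply(c(6, 12, 48), function(n) {
    mean(replicate(120, {
      s <- matrix(runif(2 * n, 0, 100), n, 2)
      d <- applySimilarity(tr0, s) + matrix(rnorm(2 * n, sd = sigma), n, 2)
      attr(estimateSimilarity(s, d), "rmse")
    }))
  }, numeric(1))
  expect_true(all(diff(meanRms) > 0))  # residuals grow toward sigma with n
  expected <- sigma * sqrt(1 - 2 / c(6, 12, 48))
  expect_equal(meanRms, expected, tolerance = 0.05)
})

test_that("transforms form a group (compose/invert at 1e-6)", {
  set.seed(3)
  src <- matrix(runif(16, 0, 50), 8, 2)
  trA <- similarityTransform(1.4, 0.5, c(2, 3))
  trB <- similarityTransform(0.6, -0.9, c(-4, 1))
  dst <- applySimilarity(trA, src)
  dst2 <- applySimilarity(trB, dst)
  eA <- estimateSimilarity(src, dst)
  eB <- estimateSimilarity(dst, dst2)
  eAB <- estimateSimilarity(src, dst2)
  comp <- composeSimilarity(eA, eB)
  expect_lt(abs(comp@scale - eAB@scale), 1e-6)
  expect_lt(abs(comp@rotation - eAB@rotation), 1e-6)
  expect_lt(max(abs(comp@translation - eAB@translation)), 1e-6)
  id <- composeSimilarity(trA, invertSimilarity(trA))
  expect_lt(abs(id@scale - 1), 1e-9)
  expect_lt(abs(id@rotation), 1e-9)
  expect_lt(max(abs(id@translation)), 1e-9)
  # composition with the inverse is the identity on points too
  back <- applySimilarity(invertSimilarity(trA), applySimilarity(trA, src))
  expect_lt(max(abs(back - src)), 1e-9)
})

test_that("warp: identity is exact, scale 2 quadruples the footprint", {
  p <- mosaicParams(imageSize = c(128L, 128L), seed = 2L)
  r <- renderMosaic(generateCenters(p), p)
  w <- warpMontage(r$image, similarityTransform())
  expect_true(all(w$lowResMask))
  expect_lt(max(abs(w$lowRes[2:127, 2:127] - r$image@image[2:127, 2:127])),
            1e-9)
  w2 <- warpMontage(r$image, similarityTransform(scale = 2))
  expect_equal(sum(w2$lowResMask) / sum(w$lowResMask), 4, tolerance = 0.05)
})

test_that("warp round trip loses < 2% intensity on smooth images", {
  # smooth image: heavily blurred mosaic
  p <- mosaicParams(imageSize = c(128L, 128L), seed = 6L)
  r <- renderMosaic(generateCenters(p), p)
  smooth <- EBImage::gblur(r$image@image, sigma = 4)
  si <- new("MosaicImage", image = pmax(pmin(smooth, 1), 0), pixelSize = 0.7)
  tr <- similarityTransform(1.3, 0.25, c(10, -4))
  wf <- warpMontage(si, tr)
  # map the warped export back with the inverse, accounting for the origin
  fwdImg <- new("MosaicImage", image = pmax(pmin(wf$lowRes, 1), 0),
                pixelSize = 0.7)
  trBack <- composeSimilarity(
    similarityTransform(1, 0, wf$origin),  # export grid -> target frame
    invertSimilarity(tr))
  wb <- warpMontage(fwdImg, trBack)
  ox <- wb$origin
  nx <- nrow(si@image); ny <- ncol(si@image)
  # compare on the interior (a 3 px rim samples the exports' zero padding)
  ix <- 4:(nx - 3); iy <- 4:(ny - 3)
  xs <- ix - ox[1]; ys <- iy - ox[2]
  ok <- xs >= 1 & xs <= nrow(wb$lowRes)
  oky <- ys >= 1 & ys <= ncol(wb$lowRes)
  rec <- wb$lowRes[xs[ok], ys[oky]]
  msk <- wb$lowResMask[xs[ok], ys[oky]]
  orig <- si@image[ix[ok], iy[oky]]
  expect_lt(mean(abs(rec[msk] - orig[msk])), 0.02)  # 2% of the [0,1] range
})

test_that("warping preserves a compact blob's total intensity within 5%", {
  img <- matrix(0, 96, 96)
  xs <- seq_len(96) - 1
  img[outer((xs - 48)^2, (xs - 48)^2, "+") < 8^2] <- 1
  img <- EBImage::gblur(img, sigma = 2)
  mi <- new("MosaicImage", image = pmax(pmin(img, 1), 0), pixelSize = 1)
  tr <- similarityTransform(1.7, 0.4, c(6, 2))
  w <- warpMontage(mi, tr)
  # intensity integral scales with the footprint: divide by scale^2
  expect_equal(sum(w$lowRes) / tr@scale^2, sum(mi@image), tolerance = 0.05)
})

test_that("stitching recovers known tile shifts exactly", {
  p <- mosaicParams(imageSize = c(300L, 300L), seed = 9L)
  big <- renderMosaic(generateCenters(p), p)$image@image
  t1 <- new("MosaicImage", image = big[1:160, 1:160], pixelSize = 0.7)
  t2 <- new("MosaicImage", image = big[131:290, 1:160], pixelSize = 0.7)
  t3 <- new("MosaicImage", image = big[1:160, 131:290], pixelSize = 0.7)
  st <- stitchTranslation(list(t1, t2, t3),
                          rbind(c(0, 0), c(127, 3), c(-2, 133)))
  truth <- rbind(c(0, 0), c(130, 0), c(0, 130))
  expect_true(all(abs(st$offsets - truth) <= 1))
  # single image: montage equals the image
  s1 <- stitchTranslation(list(t1), rbind(c(0, 0)))
  expect_identical(s1$montage@image, t1@image)
  # disjoint tiles: nominal layout with a warning
  expect_warning(
    sd <- stitchTranslation(list(t1, t3), rbind(c(0, 0), c(500, 500))),
    "overlap")
  expect_equal(sd$offsets, rbind(c(0, 0), c(500, 500)))
})
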