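# Physical scaling and landmark-based similarity registration of AO-TFI
# montages onto the infrared-fundus frame.

#' Physical pixel size of an AO-TFI montage
#'
#' Evaluates the affine scaling model `a*RE + b*(AL - 23.5) + c` in um/px,
#' where RE is the spherical-equivalent refraction (diopters) and AL the
#' axial length (mm).
#'
#' @param RE spherical equivalent, diopters (in (-10, 10)).
#' @param AL axial length, mm (in (20, 30)).
#' @param model a [ScalingModel-class] (see [scalingModel()]).
#' @return pixel size in um/px.
#' @examples
#' predictPixelSize(-2, 24.5, scalingModel(a = 0.02, b = 0.5, c = 0.7))
#' @export
predictPixelSize <- function(RE, AL, model = scalingModel()) {
  stopifnot(is(model, "ScalingModel"))
  if (any(AL <= 20 | AL >= 30)) stopParam("AL must lie in (20, 30) mm")
  if (any(RE <= -10 | RE >= 10)) stopParam("RE must lie in (-10, 10) D")
  px <- model@a * RE + model@b * (AL - 23.5) + model@c
  if (any(px <= 0))
    stopValidation("scaling model yields non-positive pixel size (inconsistent coefficients)")
  px
}

simMatrix <- function(tr) {
  R <- matrix(c(cos(tr@rotation), sin(tr@rotation),
                -sin(tr@rotation), cos(tr@rotation)), 2, 2)
  tr@scale * R
}

#' Apply a similarity transform to points
#'
#' @param tr a [SimilarityTransform-class].
#' @param pts matrix of (x, y) points.
#' @return transformed points.
#' @export
applySimilarity <- function(tr, pts) {
  stopifnot(is(tr, "SimilarityTransform"))
  pts <- rbind(pts)
  sweep(pts %*% t(simMatrix(tr)), 2, -tr@translation)
}

#' Invert a similarity transform
#' @param tr a [SimilarityTransform-class].
#' @return the inverse transform.
#' @export
invertSimilarity <- function(tr) {
  M <- simMatrix(tr)
  tinv <- -solve(M) %*% tr@translation
  similarityTransform(scale = 1 / tr@scale, rotation = -tr@rotation,
                      translation = as.numeric(tinv))
}

#' Compose two similarity transforms (`second` after `first`)
#' @param first,second [SimilarityTransform-class] objects.
#' @return the composed transform `p -> second(first(p))`.
#' @export
composeSimilarity <- function(first, second) {
  M <- simMatrix(second)
  similarityTransform(
    scale = first@scale * second@scale,
    rotation = first@rotation + second@rotation,
    translation = as.numeric(M %*% first@translation) + second@translation)
}

#' Least-squares similarity transform from landmark pairs
#'
#' Estimates the scale, rotation and translation minimizing the sum of
#' squared target-frame residuals (the Procrustes/Umeyama solution without
#' reflection), from at least four landmark pairs, e.g. vessel landmarks
#' identified on the AO-TFI montage and the IR fundus image.
#'
#' @param src matrix of source-frame landmarks (x, y), n >= 4.
#' @param dst matrix of matching target-frame landmarks.
#' @return a [SimilarityTransform-class] with attributes `rmse` (per-
#'   coordinate RMS residual) and `n`.
#' @export
estimateSimilarity <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) < 4L || nrow(dst) < 4L)
    stopValidation("at least 4 landmark pairs are required")
  if (nrow(src) != nrow(dst))
    stopValidation("src and dst must have the same number of landmarks")
  zc <- complex(real = src[, 1], imaginary = src[, 2])
  wc <- complex(real = dst[, 1], imaginary = dst[, 2])
  zm <- mean(zc); wm <- mean(wc)
  denom <- sum(Mod(zc - zm)^2)
  if (denom < 1e-12 * (1 + Mod(zm)^2))
    stopValidation("degenerate landmark configuration (coincident points)")
  ev <- eigen(stats::cov(src), symmetric = TRUE, only.values = TRUE)$values
  if (sqrt(max(ev[2], 0) / ev[1]) < 0.05)
    warning("landmarks are nearly collinear; similarity fit may be poorly conditioned")
  alpha <- sum((wc - wm) * Conj(zc - zm)) / denom
  beta <- wm - alpha * zm
  tr <- similarityTransform(scale = Mod(alpha), rotation = Arg(alpha),
                            translation = c(Re(beta), Im(beta)))
  fit <- applySimilarity(tr, src)
  attr(tr, "rmse") <- sqrt(sum((fit - dst)^2) / (2 * nrow(src)))
  attr(tr, "n") <- nrow(src)
  tr
}

bilinearSample <- function(img, x, y) {
  # x, y in 0-based pixel coordinates (dim1 = x); out-of-field -> NA
  nx <- nrow(img); ny <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 0 & y0 >= 0 & x0 <= nx - 2 & y0 <= ny - 2
  # clamp the exact far edge into the last cell
  edge <- x >= nx - 1 & x <= nx - 1 + 1e-9
  x0[edge] <- nx - 2; fx[edge] <- 1; ok[edge & y0 >= 0 & y0 <= ny - 2] <- TRUE
  edgey <- y >= ny - 1 & y <= ny - 1 + 1e-9
  y0[edgey] <- ny - 2; fy[edgey] <- 1
  ok <- ok | (x0 >= 0 & y0 >= 0 & x0 <= nx - 2 & y0 <= ny - 2)
  out <- rep(NA_real_, length(x))
  i <- which(ok)
  if (length(i)) {
    i1 <- x0[i] + 1L; j1 <- y0[i] + 1L
    v00 <- img[cbind(i1, j1)]; v10 <- img[cbind(i1 + 1L, j1)]
    v01 <- img[cbind(i1, j1 + 1L)]; v11 <- img[cbind(i1 + 1L, j1 + 1L)]
    out[i] <- v00 * (1 - fx[i]) * (1 - fy[i]) + v10 * fx[i] * (1 - fy[i]) +
              v01 * (1 - fx[i]) * fy[i] + v11 * fx[i] * fy[i]
  }
  out
}

#' Warp a montage into the target (IR-fundus) frame
#'
#' Resamples the montage under a similarity transform mapping source pixel
#' coordinates to target pixel coordinates, producing two exports: the
#' target-frame image at `targetPixelSize` (default the 20 um/px of IR
#' fundus images) and a high-resolution warped montage at the montage's
#' native resolution in the target frame. Bilinear interpolation;
#' out-of-field pixels are zero with a validity mask.
#'
#' @param montage a [MosaicImage-class].
#' @param tr a [SimilarityTransform-class] from montage px to target px
#'   (target grid at `targetPixelSize`).
#' @param targetPixelSize um/px of the low-resolution export (default 20).
#' @return list with `lowRes`, `lowResMask`, `highRes`, `highResMask`,
#'   `origin` (target-frame px offset of the exports) and `highResStep`
#'   (target px per high-res output px).
#' @export
warpMontage <- function(montage, tr, targetPixelSize = 20) {
  stopifnot(is(montage, "MosaicImage"), is(tr, "SimilarityTransform"))
  img <- montage@image
  nx <- nrow(img); ny <- ncol(img)
  corners <- cbind(c(0, nx - 1, nx - 1, 0), c(0, 0, ny - 1, ny - 1))
  tc <- applySimilarity(tr, corners)
  x0 <- floor(min(tc[, 1])); x1 <- ceiling(max(tc[, 1]))
  y0 <- floor(min(tc[, 2])); y1 <- ceiling(max(tc[, 2]))
  inv <- invertSimilarity(tr)
  renderGrid <- function(step) {
    gx <- seq(x0, x1, by = step)
    gy <- seq(y0, y1, by = step)
    G <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
    S <- applySimilarity(inv, G)
    v <- bilinearSample(img, S[, 1], S[, 2])
    out <- matrix(v, length(gx), length(gy))
    maskv <- matrix(!is.na(v), length(gx), length(gy))
    out[is.na(out)] <- 0
    list(image = out, mask = maskv)
  }
  low <- renderGrid(1)
  hstep <- 1 / tr@scale  # native montage resolution in target px
  high <- renderGrid(hstep)
  list(lowRes = low$image, lowResMask = low$mask,
       highRes = high$image, highResMask = high$mask,
       origin = c(x0, y0), highResStep = hstep,
       targetPixelSize = targetPixelSize)
}
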