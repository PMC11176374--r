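# Internal geometry and bookkeeping helpers.

stopParam <- function(...) {
  stop(structure(class = c("rpe_param_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

stopValidation <- function(...) {
  stop(structure(class = c("rpe_validation_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

# Signed area by the shoelace formula (positive for CCW vertex order).
signedArea <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

polygonArea <- function(poly) abs(signedArea(poly))

polygonPerimeter <- function(poly) {
  n <- nrow(poly)
  j <- c(seq_len(n - 1L) + 1L, 1L)
  sum(sqrt(rowSums((poly[j, , drop = FALSE] - poly)^2)))
}

convexHullArea <- function(poly) convex_hull_area_cpp(poly)

# Deterministic per-item child seeds derived from one root seed: the root
# seeds R's RNG once and child seeds are drawn as a single sample without
# replacement, so child i is a pure function of (root, n, i).
childSeeds <- function(root, n) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(root %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}

# Percentage rounded half-up to an integer (so 61.5 -> 62), matching how the
# study reports count percentages.
pctHalfUp <- function(count, denom) {
  if (denom == 0) return(ifelse(count == 0, 0, NA_real_))
  floor(100 * count / denom + 0.5)
}

sampleSD <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

# Gaussian blur with the kernel capped at the image size, so small fields
# do not error inside EBImage::filter2.
gblurCapped <- function(x, sigma) {
  radius <- 2 * ceiling(3 * sigma) + 1
  m <- min(dim(x))
  if (radius > m) radius <- m - (1 - m %% 2)
  EBImage::gblur(x, sigma = sigma, radius = radius)
}

# Distance from each indexed site to its nearest other site.
nearestSiteDistance <- function(centers, idx = seq_len(nrow(centers))) {
  vapply(idx, function(i) {
    d2 <- (centers[, 1] - centers[i, 1])^2 + (centers[, 2] - centers[i, 2])^2
    d2[i] <- Inf
    sqrt(min(d2))
  }, numeric(1))
}

# Pixel indices (1-based, dim1 = x) covered by a convex polygon given in um.
# Scanline over pixel-center rows; pixel centers at ((i-1)*ps, (j-1)*ps).
convexPolygonPixels <- function(poly, pixelSize, nx, ny) {
  if (is.null(poly) || nrow(poly) < 3L) return(cbind(integer(0), integer(0)))
  ys <- poly[, 2] / pixelSize + 1  # pixel-row coordinates (1-based, fractional)
  xs <- poly[, 1] / pixelSize + 1
  j0 <- max(1L, ceiling(min(ys) - 1e-9))
  j1 <- min(ny, floor(max(ys) + 1e-9))
  if (j0 > j1) return(cbind(integer(0), integer(0)))
  n <- nrow(poly)
  nxt <- c(seq_len(n - 1L) + 1L, 1L)
  out_i <- vector("list", j1 - j0 + 1L)
  for (j in j0:j1) {
    yv <- j
    # x-interval of the convex polygon at scanline y = yv
    xcross <- c()
    for (e in seq_len(n)) {
      y1 <- ys[e]; y2 <- ys[nxt[e]]
      if ((y1 <= yv && y2 >= yv) || (y2 <= yv && y1 >= yv)) {
        if (abs(y2 - y1) < 1e-12) {
          xcross <- c(xcross, xs[e], xs[nxt[e]])
        } else {
          t <- (yv - y1) / (y2 - y1)
          xcross <- c(xcross, xs[e] + t * (xs[nxt[e]] - xs[e]))
        }
      }
    }
    if (length(xcross) < 2L) next
    i0 <- max(1L, ceiling(min(xcross) - 1e-9))
    i1 <- min(nx, floor(max(xcross) + 1e-9))
    if (i0 <= i1)
      out_i[[j - j0 + 1L]] <- cbind(i0:i1, rep.int(j, i1 - i0 + 1L))
  }
  do.call(rbind, c(out_i, list(cbind(integer(0), integer(0)))))
}

# Simple separable box mean via cumulative sums with replicate padding.
boxMean <- function(m, w) {
  stopifnot(w >= 1)
  runmean1 <- function(v, w) {
    half <- w %/% 2
    vp <- c(rep(v[1], half), v, rep(v[length(v)], half))
    cs <- cumsum(vp)
    n <- length(v)
    (cs[(w):(w + n - 1L)] - c(0, cs[seq_len(n - 1L)])) / w
  }
  m1 <- apply(m, 2, runmean1, w = w)
  t(apply(m1, 1, runmean1, w = w))
}
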