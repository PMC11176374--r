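# Independent oracle implementations used by the tests. These deliberately
# avoid the package's own geometry code paths.

# Shoelace area of a closed polygon (vertex matrix, first vertex not repeated).
shoelace <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polyPerimeter <- function(poly) {
  n <- nrow(poly)
  j <- c(seq_len(n - 1L) + 1L, 1L)
  sum(sqrt(rowSums((poly[j, , drop = FALSE] - poly)^2)))
}

rotatePoly <- function(poly, angle) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  poly %*% t(R)
}

# Field bounds used by the generator: pixel centers at (i-1)*ps, field edges
# half a pixel beyond the outermost centers.
fieldBoundsOf <- function(params) {
  ps <- params@pixelSize
  c(-ps / 2, -ps / 2,
    (params@imageSize[1] - 0.5) * ps, (params@imageSize[2] - 0.5) * ps)
}

# Brute-force bounded Voronoi areas: label a g x g grid of sample points by
# nearest center, count points per label.
bruteVoronoiAreas <- function(centers, bounds, g = 1000L) {
  n <- nrow(centers)
  sx <- (bounds[3] - bounds[1]) / g
  sy <- (bounds[4] - bounds[2]) / g
  xs <- bounds[1] + (seq_len(g) - 0.5) * sx
  ys <- bounds[2] + (seq_len(g) - 0.5) * sy
  lab <- matrix(0L, g, g)
  best <- matrix(Inf, g, g)
  for (i in seq_len(n)) {
    d <- outer((xs - centers[i, 1])^2, (ys - centers[i, 2])^2, "+")
    w <- d < best
    lab[w] <- i
    best[w] <- d[w]
  }
  list(areas = tabulate(lab, n) * sx * sy, labels = lab)
}

# Even-odd point-in-polygon test for a vector of query points.
pointsInPolygon <- function(poly, qx, qy) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(qx))
  j <- n
  for (i in seq_len(n)) {
    crosses <- (poly[i, 2] > qy) != (poly[j, 2] > qy)
    xi <- poly[i, 1] + (qy - poly[i, 2]) * (poly[j, 1] - poly[i, 1]) /
      (poly[j, 2] - poly[i, 2])
    inside <- xor(inside, crosses & (qx < xi))
    j <- i
  }
  inside
}

# Intersection-over-union of two polygons by rasterization at pitch ps,
# sampled off-lattice to avoid vertex/grid coincidences.
polyIoU <- function(p1, p2, ps = 0.7) {
  allxy <- rbind(p1, p2)
  gx <- seq(floor(min(allxy[, 1]) / ps), ceiling(max(allxy[, 1]) / ps)) * ps
  gy <- seq(floor(min(allxy[, 2]) / ps), ceiling(max(allxy[, 2]) / ps)) * ps
  qx <- rep(gx + 0.33 * ps, times = length(gy))
  qy <- rep(gy + 0.21 * ps, each = length(gx))
  a <- pointsInPolygon(p1, qx, qy)
  b <- pointsInPolygon(p2, qx, qy)
  sum(a & b) / sum(a | b)
}

# Convex hull area by an all-subsets check (small n only): a point is a hull
# vertex iff it lies strictly inside no triangle of three other points; hull
# vertices are then ordered by angle around their centroid.
hullAreaOracle <- function(pts) {
  n <- nrow(pts)
  inTriangle <- function(p, a, b, c) {
    s1 <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    s2 <- (c[1] - b[1]) * (p[2] - b[2]) - (c[2] - b[2]) * (p[1] - b[1])
    s3 <- (a[1] - c[1]) * (p[2] - c[2]) - (a[2] - c[2]) * (p[1] - c[1])
    (s1 > 1e-12 & s2 > 1e-12 & s3 > 1e-12) |
      (s1 < -1e-12 & s2 < -1e-12 & s3 < -1e-12)
  }
  isVertex <- vapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    combos <- utils::combn(others, 3)
    for (k in seq_len(ncol(combos))) {
      if (inTriangle(pts[i, ], pts[combos[1, k], ], pts[combos[2, k], ],
                     pts[combos[3, k], ])) return(FALSE)
    }
    TRUE
  }, logical(1))
  hp <- pts[isVertex, , drop = FALSE]
  ctr <- colMeans(hp)
  hp <- hp[order(atan2(hp[, 2] - ctr[2], hp[, 1] - ctr[1])), , drop = FALSE]
  shoelace(hp)
}

# Five-pointed star polygon (10 vertices, alternating radii), centered at
# `center`.
starPolygon <- function(R = 10, r = 3.5, center = c(0, 0)) {
  ang <- pi / 2 + 2 * pi * (0:9) / 10
  rad <- rep(c(R, r), 5)
  cbind(center[1] + rad * cos(ang), center[2] + rad * sin(ang))
}

# Greedy one-to-one matching of detected points to truth points; returns the
# fraction of truth matched within tol and the number of unmatched detections.
matchPoints <- function(truth, detected, tol) {
  if (nrow(detected) == 0L)
    return(list(matchedFrac = 0, spurious = 0L))
  usedDet <- rep(FALSE, nrow(detected))
  matched <- 0L
  for (i in seq_len(nrow(truth))) {
    d2 <- (detected[, 1] - truth[i, 1])^2 + (detected[, 2] - truth[i, 2])^2
    d2[usedDet] <- Inf
    k <- which.min(d2)
    if (d2[k] < tol^2) {
      matched <- matched + 1L
      usedDet[k] <- TRUE
    }
  }
  list(matchedFrac = matched / nrow(truth), spurious = sum(!usedDet))
}

# Dark disc of radius rpx (px) on a bright field, returned as a MosaicImage.
discImage <- function(npx = 128L, rpx = 20, level = 0.1, bg = 1,
                      pixelSize = 1) {
  ctr <- npx / 2
  xs <- seq_len(npx) - 1
  d2 <- outer((xs - ctr)^2, (xs - ctr)^2, "+")
  img <- matrix(bg, npx, npx)
  img[d2 < rpx^2] <- level
  new("MosaicImage", image = img, pixelSize = pixelSize, metadata = list())
}

# Independent textbook Welch t implementation (summary form).
welchOracle <- function(mA, sA, nA, mB, sB, nB) {
  vA <- sA^2 / nA; vB <- sB^2 / nB
  t <- (mA - mB) / sqrt(vA + vB)
  df <- (vA + vB)^2 / (vA^2 / (nA - 1) + vB^2 / (nB - 1))
  p <- 2 * stats::pt(-abs(t), df)
  c(t = t, df = df, p = p)
}

# The grading worked example: 125 graded images with the published marginal
# counts (stage 33/77/15; grades 7/39/22/32/20 with 5 ungradable foveal
# images; grade-4 subtype counts 5/12/10 with overlap).
gradingFixture <- function() {
  stage <- c(rep("active", 33), rep("resolved", 77), rep("healthy_CL", 15))
  # grades by stage: active = 7xG1 + 12xG2 + 4xG3 + 5xG0 + 5xG4;
  # resolved = 27xG2 + 18xG3 + 18xG0 + 12xG4 + 2 foveal;
  # healthy_CL = 9xG0 + 3xG4 + 3 foveal.
  grade <- c(rep(1L, 7), rep(2L, 12), rep(3L, 4), rep(0L, 5), rep(4L, 5),
             rep(2L, 27), rep(3L, 18), rep(0L, 18), rep(4L, 12), rep(NA, 2),
             rep(0L, 9), rep(4L, 3), rep(NA, 3))
  rec <- data.frame(stage = stage, grade = grade)
  g4 <- which(!is.na(rec$grade) & rec$grade == 4L)  # 20 images
  rec$altered_contrast <- rec$hypo_dots <- rec$hyper_clusters <- FALSE
  rec$altered_contrast[g4[1:5]] <- TRUE
  rec$hypo_dots[g4[1:12]] <- TRUE
  rec$hyper_clusters[g4[11:20]] <- TRUE
  rec
}
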