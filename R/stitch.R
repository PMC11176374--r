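# Translation-only stitching of AO-TFI zone images into a montage.
# Nominal zone offsets are refined by integer-shift normalized
# cross-correlation on the pairwise overlap, then tiles are composited with
# linear feathering in the overlaps.

tileWeight <- function(nx, ny) {
  wx <- pmin(seq_len(nx), rev(seq_len(nx)))
  wy <- pmin(seq_len(ny), rev(seq_len(ny)))
  outer(wx, wy, pmin)
}

nccShift <- function(ref, mov, search = 8L) {
  best <- c(0L, 0L); bestv <- -Inf
  nx <- nrow(ref); ny <- ncol(ref)
  for (dx in -search:search) for (dy in -search:search) {
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    if (length(xs) < 8 || length(ys) < 8) next
    a <- ref[xs, ys]
    b <- mov[xs - dx, ys - dy]
    av <- a - mean(a); bv <- b - mean(b)
    den <- sqrt(sum(av^2) * sum(bv^2))
    if (den < 1e-12) next
    v <- sum(av * bv) / den
    if (v > bestv) { bestv <- v; best <- c(dx, dy) }
  }
  list(shift = best, score = bestv)
}

#' Stitch images into a montage by translation
#'
#' Places each tile at its nominal (x, y) pixel offset, refining the offset
#' by maximizing the normalized cross-correlation of its overlap with the
#' already-placed montage over integer shifts within `search` px. Tiles
#' without overlap fall back to the nominal offset with a warning. Overlaps
#' are blended by linear feathering.
#'
#' @param images list of [MosaicImage-class] tiles (equal pixel size).
#' @param offsets matrix of nominal (x, y) offsets in px, one row per tile;
#'   the first tile anchors the montage.
#' @param search refinement search radius in px (0 disables refinement).
#' @return list with `montage` ([MosaicImage-class]) and `offsets` (the
#'   refined integer offsets actually used).
#' @export
stitchTranslation <- function(images, offsets, search = 8L) {
  stopifnot(length(images) >= 1L, nrow(offsets) == length(images))
  if (length(images) == 1L)
    return(list(montage = images[[1]], offsets = rbind(c(0, 0))))
  ps <- images[[1]]@pixelSize
  offs <- round(as.matrix(offsets))
  offs <- sweep(offs, 2, offs[1, ])  # anchor first tile at the origin
  used <- offs
  dims <- t(vapply(images, function(m) dim(m@image), integer(2)))

  for (k in 2:length(images)) {
    # overlap with the union of previously placed tiles (use tile 1..k-1)
    bestOv <- 0L; refIdx <- 0L
    for (p in seq_len(k - 1L)) {
      ox <- max(used[p, 1], offs[k, 1])
      oy <- max(used[p, 2], offs[k, 2])
      ex <- min(used[p, 1] + dims[p, 1], offs[k, 1] + dims[k, 1])
      ey <- min(used[p, 2] + dims[p, 2], offs[k, 2] + dims[k, 2])
      ov <- max(0, ex - ox) * max(0, ey - oy)
      if (ov > bestOv) { bestOv <- ov; refIdx <- p }
    }
    if (bestOv < 64 || search == 0L) {
      if (bestOv < 64 && search > 0L)
        warning(sprintf("tile %d has no usable overlap; using nominal offset", k))
      used[k, ] <- offs[k, ]
      next
    }
    p <- refIdx
    ox <- max(used[p, 1], offs[k, 1]); oy <- max(used[p, 2], offs[k, 2])
    ex <- min(used[p, 1] + dims[p, 1], offs[k, 1] + dims[k, 1])
    ey <- min(used[p, 2] + dims[p, 2], offs[k, 2] + dims[k, 2])
    # margin so shifted comparisons stay inside both tiles
    refReg <- images[[p]]@image[(ox - used[p, 1] + 1):(ex - used[p, 1]),
                                (oy - used[p, 2] + 1):(ey - used[p, 2]),
                                drop = FALSE]
    movReg <- images[[k]]@image[(ox - offs[k, 1] + 1):(ex - offs[k, 1]),
                                (oy - offs[k, 2] + 1):(ey - offs[k, 2]),
                                drop = FALSE]
    sh <- nccShift(refReg, movReg, search = search)
    used[k, ] <- offs[k, ] + sh$shift
  }

  x0 <- min(used[, 1]); y0 <- min(used[, 2])
  used <- sweep(used, 2, c(x0, y0))
  W <- max(used[, 1] + dims[, 1]); H <- max(used[, 2] + dims[, 2])
  acc <- matrix(0, W, H); wacc <- matrix(0, W, H)
  for (k in seq_along(images)) {
    w <- tileWeight(dims[k, 1], dims[k, 2])
    xs <- (used[k, 1] + 1):(used[k, 1] + dims[k, 1])
    ys <- (used[k, 2] + 1):(used[k, 2] + dims[k, 2])
    acc[xs, ys] <- acc[xs, ys] + images[[k]]@image * w
    wacc[xs, ys] <- wacc[xs, ys] + w
  }
  out <- acc / pmax(wacc, 1e-12)
  out[wacc == 0] <- 0
  list(montage = new("MosaicImage", image = pmax(pmin(out, 1), 0),
                     pixelSize = ps,
                     metadata = list(stitched = TRUE, nTiles = length(images))),
       offsets = used)
}
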