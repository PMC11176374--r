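# End-to-end orchestration: synthesize -> mask -> tessellate -> segment ->
# include -> aggregate -> compare, and the registration lane
# (stitch -> landmark similarity -> warped exports). Each run serializes its
# configuration and writes a manifest with an MD5 hash of every artifact, so
# re-running the same configuration reproduces byte-identical outputs.

defaultConfig <- function() {
  list(
    seed = 1L,
    out_dir = "rpemosaic_run",
    synth = list(n_eyes_per_group = c(healthy = 3, CSCR = 3),
                 images_per_eye = 2,
                 lattice_spacing = 14, disorder = 0.18,
                 image_size = c(256L, 256L), pixel_size = 0.7,
                 blob_radius = 3, blob_roughness = 0.1,
                 noise_sd = 0.02, lowq_fraction = 0,
                 effect_disorder = 0.12, effect_roughness = 0.15),
    quality = list(tile_size = 32L, threshold = 0.5),
    tessellation = list(spacing = 14, min_cells = 10L),
    segmentation = list(k = 0.8, window = NULL, min_area = 4L),
    stats = list(tol_age = 10, tol_AL = 0.6, tol_RE = 1.5)
  )
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a run configuration from YAML (merged over defaults)
#' @param path YAML file path; NULL returns the defaults.
#' @return config list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (!is.null(path)) cfg <- mergeConfig(cfg, yaml::read_yaml(path))
  cfg
}

writeManifest <- function(outDir, files, cfg) {
  files <- files[file.exists(files)]
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  yaml::write_yaml(cfg, file.path(outDir, "config.yaml"))
  manifest
}

analyzeMosaicImage <- function(image, cfg) {
  qcfg <- cfg$quality; tcfg <- cfg$tessellation; scfg <- cfg$segmentation
  spacing <- tcfg$spacing
  qm <- qualityMap(image, tileSize = qcfg$tile_size, spacing = spacing)
  qmask <- maskFromQuality(qm, threshold = qcfg$threshold,
                           imageDim = dim(image@image))
  res <- list(qmask = qmask, included = FALSE)
  feat <- c(non_masked_portion = qmask@nonMaskedPortion)
  if (qmask@nonMaskedPortion > 0.05) {
    ctr <- detectCenters(image, mask = qmask@mask, spacing = spacing)
    res$nCells <- nrow(ctr)
    if (nrow(ctr) >= max(3L, tcfg$min_cells)) {
      ps <- image@pixelSize
      b <- c(-ps / 2, -ps / 2, (nrow(image@image) - 0.5) * ps,
             (ncol(image@image) - 0.5) * ps)
      tess <- voronoiPartition(ctr, b, minEdge = ps)
      fb <- filterBorderCells(tess, qmask, pixelSize = ps)
      unArea <- sum(fb$mask) * ps^2
      ms <- mosaicMetrics(fb$tessellation, unmaskedAreaUm2 = unArea,
                          nonMaskedPortion = fb$nonMaskedPortion)
      win <- scfg$window
      if (is.null(win)) win <- max(9L, round(2 * spacing / ps))
      qmask2 <- new("QualityMask", tileSize = qmask@tileSize,
                    scores = qmask@scores, threshold = qmask@threshold,
                    mask = fb$mask,
                    nonMaskedPortion = sum(fb$mask) / length(fb$mask))
      contours <- segmentHyporeflective(image, qmask2, k = scfg$k,
                                        window = win,
                                        minArea = scfg$min_area,
                                        spacing = spacing)
      hy <- shapeDescriptors(contours, unmaskedAreaUm2 = unArea,
                             nonMaskedPortion = fb$nonMaskedPortion)
      res$tessellation <- fb$tessellation
      res$mosaicSummary <- ms
      res$hypoRegions <- hy
      res$included <- includeImage(qmask2, sum(fb$tessellation@keptFlags),
                                   minCells = tcfg$min_cells)
      st <- ms@imageStats; hs <- hy@imageStats
      feat <- c(feat,
                n_cells = unname(st["n_cells"]),
                nn_mean = unname(st["n_neighbors_mean"]),
                nn_sd = unname(st["n_neighbors_sd"]),
                area_mean = unname(st["area_mean"]),
                area_sd = unname(st["area_sd"]),
                perimeter_mean = unname(st["perimeter_mean"]),
                perimeter_sd = unname(st["perimeter_sd"]),
                eqd_mean = unname(st["eq_diameter_mean"]),
                eqd_sd = unname(st["eq_diameter_sd"]),
                cell_density = ms@density,
                hypo_area_mean = unname(hs["area_mean"]),
                hypo_perim_mean = unname(hs["perimeter_mean"]),
                hypo_perim_sd = unname(hs["perimeter_sd"]),
                hypo_solidity_mean = unname(hs["solidity_mean"]),
                hypo_solidity_sd = unname(hs["solidity_sd"]),
                hypo_circ_mean = unname(hs["circularity_mean"]),
                hypo_circ_sd = unname(hs["circularity_sd"]),
                hypo_density = hy@density)
    }
  }
  res$features <- feat
  res
}

#' Run the quantitative pipeline end to end
#'
#' Synthesizes a cohort of images, applies quality masking, tessellation
#' with border filtering, hypo-reflective segmentation, the image-inclusion
#' rule, per-eye aggregation (perifoveal zones, matched eyes) and Welch
#' comparisons, writing per-image and per-eye CSVs, a comparison report
#' (CSV + JSON), the serialized configuration and a hash manifest.
#'
#' @param config a config list from [readRunConfig()] (or a YAML path).
#' @return list with `perImage`, `perEye`, `comparison`, `excluded` and the
#'   output directory, invisibly.
#' @export
runQuantify <- function(config = readRunConfig()) {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- mergeConfig(defaultConfig(), config)
  sc <- cfg$synth
  for (col in c("n_eyes_per_group", "images_per_eye")) {
    if (is.null(sc[[col]]) || anyNA(sc[[col]]))
      stopValidation("config validation: synth$%s is missing", col)
  }
  outDir <- cfg$out_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  params <- mosaicParams(
    latticeSpacing = sc$lattice_spacing, disorder = sc$disorder,
    imageSize = as.integer(sc$image_size), pixelSize = sc$pixel_size,
    blobRadius = sc$blob_radius, blobRoughness = sc$blob_roughness,
    noiseSd = sc$noise_sd, lowqFraction = sc$lowq_fraction,
    seed = cfg$seed)
  nepg <- unlist(sc$n_eyes_per_group)
  if (is.null(names(nepg)) || !all(c("healthy", "CSCR") %in% names(nepg)))
    names(nepg) <- c("healthy", "CSCR")[seq_along(nepg)]
  coh <- generateCohort(nEyesPerGroup = nepg,
                        imagesPerEye = sc$images_per_eye,
                        healthyParams = params,
                        effect = effectSpec(sc$effect_disorder,
                                            sc$effect_roughness),
                        seed = cfg$seed, render = TRUE)
  for (col in c("age", "AL_mm", "RE_D")) {
    if (anyNA(coh$eyes[[col]]))
      stopValidation("metadata validation: column %s has missing values", col)
  }

  rows <- vector("list", nrow(coh$images))
  excluded <- character(0)
  for (r in seq_len(nrow(coh$images))) {
    img <- coh$renders[[r]]$image
    an <- tryCatch(analyzeMosaicImage(img, cfg), error = function(e)
      stop(sprintf("stage 'analyze' failed on image %s: %s",
                   coh$images$image_id[r], conditionMessage(e))))
    feat <- an$features
    if (!an$included)
      excluded <- c(excluded, sprintf("%s (non_masked %.1f%%, cells %s)",
                                      coh$images$image_id[r],
                                      100 * feat["non_masked_portion"],
                                      an$nCells %||% 0))
    rows[[r]] <- cbind(coh$images[r, c("image_id", "eye_id", "group", "zone")],
                       data.frame(included = an$included),
                       as.data.frame(as.list(feat)))
  }
  allCols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(d) {
    for (m in setdiff(allCols, names(d))) d[[m]] <- NA_real_
    d[allCols]
  })
  perImage <- do.call(rbind, rows)
  utils::write.csv(perImage, file.path(outDir, "per_image.csv"),
                   row.names = FALSE)

  perEye <- aggregatePerEye(perImage, coh$eyes)
  utils::write.csv(perEye, file.path(outDir, "per_eye.csv"),
                   row.names = FALSE)

  eyesH <- perEye[perEye$group == "healthy", , drop = FALSE]
  eyesC <- perEye[perEye$group == "CSCR", , drop = FALSE]
  comparison <- NULL
  if (nrow(eyesH) >= 2L && nrow(eyesC) >= 2L) {
    m <- tryCatch(
      matchBaseline(eyesC, eyesH,
                    tolerances = c(age = cfg$stats$tol_age,
                                   AL_mm = cfg$stats$tol_AL,
                                   RE_D = cfg$stats$tol_RE)),
      rpe_validation_error = function(e) {
        warning("baseline matching removed all eyes from one group; ",
                "comparing unmatched groups", call. = FALSE)
        list(eyesA = eyesC, eyesB = eyesH)
      })
    comparison <- compareGroups(m$eyesA, m$eyesB)
    utils::write.csv(comparison, file.path(outDir, "comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(comparison, file.path(outDir, "comparison.json"),
                         dataframe = "rows", digits = NA)
  }
  writeLines(excluded, file.path(outDir, "excluded_images.txt"))
  files <- file.path(outDir, c("per_image.csv", "per_eye.csv",
                               "comparison.csv", "comparison.json",
                               "excluded_images.txt"))
  writeManifest(outDir, files, cfg)
  message(sprintf("runQuantify: %d images, %d eyes retained, %.1f s",
                  nrow(perImage), nrow(perEye),
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(perImage = perImage, perEye = perEye,
                 comparison = comparison, excluded = excluded,
                 outDir = outDir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the registration lane: stitch, register, warp
#'
#' Stitches tiles into a montage, optionally estimates the landmark
#' similarity transform onto the IR-fundus frame and writes the warped
#' exports (20 um/px frame and high-resolution), the transform JSON and an
#' overlay mask stack.
#'
#' @param tiles list of [MosaicImage-class] tiles.
#' @param offsets nominal tile offsets in px (one row per tile).
#' @param landmarks optional list with `src`/`dst` matrices (>= 4 rows), or
#'   a CSV path readable by [readLandmarks()]; when absent, registration is
#'   skipped with a warning and only the montage is written.
#' @param outDir output directory.
#' @param targetPixelSize um/px of the low-resolution export.
#' @return list with `montage`, `offsets`, and (when registered) `transform`
#'   and `warp`, invisibly.
#' @export
runRegister <- function(tiles, offsets, landmarks = NULL,
                        outDir = "rpemosaic_register",
                        targetPixelSize = 20) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  st <- stitchTranslation(tiles, offsets)
  writeMosaicTIFF(st$montage, file.path(outDir, "montage.tif"))
  utils::write.csv(data.frame(tile = seq_len(nrow(st$offsets)),
                              x_px = st$offsets[, 1], y_px = st$offsets[, 2]),
                   file.path(outDir, "tile_offsets.csv"), row.names = FALSE)
  out <- list(montage = st$montage, offsets = st$offsets)
  if (is.null(landmarks)) {
    warning("no landmarks provided; registration skipped, montage written")
  } else {
    if (is.character(landmarks)) landmarks <- readLandmarks(landmarks)
    if (nrow(landmarks$src) < 4L)
      stopValidation("at least 4 landmarks are required for registration")
    tr <- estimateSimilarity(landmarks$src, landmarks$dst)
    writeTransformJSON(tr, file.path(outDir, "transform.json"))
    w <- warpMontage(st$montage, tr, targetPixelSize = targetPixelSize)
    tiff::writeTIFF(t(pmax(pmin(w$lowRes, 1), 0)),
                    file.path(outDir, "warped_lowres.tif"),
                    bits.per.sample = 16L, compression = "none")
    tiff::writeTIFF(t(pmax(pmin(w$highRes, 1), 0)),
                    file.path(outDir, "warped_highres.tif"),
                    bits.per.sample = 16L, compression = "none")
    # two-layer overlay: warped montage + validity mask over the IR frame
    tiff::writeTIFF(list(t(pmax(pmin(w$lowRes, 1), 0)),
                         t(w$lowResMask * 1)),
                    file.path(outDir, "overlay_stack.tif"),
                    bits.per.sample = 16L, compression = "none")
    out$transform <- tr
    out$warp <- w
  }
  files <- list.files(outDir, full.names = TRUE)
  writeManifest(outDir, setdiff(files, file.path(outDir, c("manifest.csv", "config.yaml"))),
                list(target_pixel_size = targetPixelSize))
  invisible(out)
}
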