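# Per-eye aggregation, baseline matching and Welch-corrected group
# comparisons between CSCR and healthy eyes.

#' Aggregate per-image morphometric features to per-eye means
#'
#' Applies the study's exclusions: only included images (quality rule) from
#' perifoveal zones Z1-Z4 enter; foveal (Z5) and discretionary (Z6) images
#' are dropped, as are healthy contralateral eyes of patients. Remaining
#' feature columns are averaged per eye. Eyes left with zero included images
#' are dropped (their count is reported in the `droppedEyes` attribute).
#'
#' @param imageSummaries data.frame with columns `eye_id`, `zone`,
#'   `included` (logical) and one column per feature.
#' @param eyeInfo data.frame with columns `eye_id`, `group` and optionally
#'   `stage`, `participant_id`, `age`, `AL_mm`, `RE_D`.
#' @return data.frame of per-eye metadata plus per-eye feature means.
#' @export
aggregatePerEye <- function(imageSummaries, eyeInfo) {
  need <- c("eye_id", "zone", "included")
  if (!all(need %in% names(imageSummaries)))
    stopValidation("imageSummaries must have columns %s",
                   paste(need, collapse = ", "))
  keepEyes <- eyeInfo
  if ("stage" %in% names(eyeInfo))
    keepEyes <- eyeInfo[is.na(eyeInfo$stage) | eyeInfo$stage != "healthy_CL", , drop = FALSE]
  imgs <- imageSummaries[imageSummaries$included &
                         imageSummaries$zone %in% c("Z1", "Z2", "Z3", "Z4") &
                         imageSummaries$eye_id %in% keepEyes$eye_id, , drop = FALSE]
  featCols <- setdiff(names(imageSummaries),
                      c(need, "image_id", "zone", "group"))
  featCols <- featCols[vapply(imageSummaries[featCols], is.numeric, logical(1))]
  nBefore <- nrow(keepEyes)
  if (nrow(imgs) == 0L) {
    out <- keepEyes[0, , drop = FALSE]
    attr(out, "droppedEyes") <- nBefore
    return(out)
  }
  means <- aggregate(imgs[featCols], by = list(eye_id = imgs$eye_id), FUN = mean)
  out <- merge(keepEyes, means, by = "eye_id")
  attr(out, "droppedEyes") <- nBefore - nrow(out)
  out
}

#' Match baseline characteristics between two groups of eyes
#'
#' Iteratively trims eyes until the group means of every matching variable
#' differ by less than its tolerance. At each step the worst-offending
#' variable is found and the single eye (from either group) whose value lies
#' farthest outside the other group's range is removed; if no eye is outside
#' the range, the eye farthest from the other group's mean is removed.
#'
#' @param eyesA,eyesB data.frames of eyes with the matching variables.
#' @param tolerances named numeric vector of allowed mean differences
#'   (defaults: age 10 y, AL_mm 0.6 mm, RE_D 1.5 D). Infinite tolerances
#'   disable trimming.
#' @return list with matched `eyesA`, `eyesB` and `trimmed` (eye ids).
#' @export
matchBaseline <- function(eyesA, eyesB,
                          tolerances = c(age = 10, AL_mm = 0.6, RE_D = 1.5)) {
  vars <- names(tolerances)
  stopifnot(all(vars %in% names(eyesA)), all(vars %in% names(eyesB)))
  trimmed <- character(0)
  repeat {
    if (nrow(eyesA) == 0L || nrow(eyesB) == 0L)
      stopValidation("baseline matching removed all eyes from one group")
    gaps <- vapply(vars, function(v)
      abs(mean(eyesA[[v]]) - mean(eyesB[[v]])) / tolerances[[v]], numeric(1))
    gaps[!is.finite(gaps)] <- 0  # infinite tolerance -> never trim on it
    if (all(gaps < 1)) break
    v <- vars[which.max(gaps)]
    # distance of each eye outside the other group's range
    exceed <- function(x, other) pmax(x - max(other), min(other) - x, 0)
    eA <- exceed(eyesA[[v]], eyesB[[v]])
    eB <- exceed(eyesB[[v]], eyesA[[v]])
    if (max(eA, eB) > 0) {
      if (max(eA) >= max(eB)) {
        i <- which.max(eA)
        trimmed <- c(trimmed, as.character(eyesA$eye_id[i]))
        eyesA <- eyesA[-i, , drop = FALSE]
      } else {
        i <- which.max(eB)
        trimmed <- c(trimmed, as.character(eyesB$eye_id[i]))
        eyesB <- eyesB[-i, , drop = FALSE]
      }
    } else {
      dA <- abs(eyesA[[v]] - mean(eyesB[[v]]))
      dB <- abs(eyesB[[v]] - mean(eyesA[[v]]))
      if (max(dA) >= max(dB)) {
        i <- which.max(dA)
        trimmed <- c(trimmed, as.character(eyesA$eye_id[i]))
        eyesA <- eyesA[-i, , drop = FALSE]
      } else {
        i <- which.max(dB)
        trimmed <- c(trimmed, as.character(eyesB$eye_id[i]))
        eyesB <- eyesB[-i, , drop = FALSE]
      }
    }
  }
  list(eyesA = eyesA, eyesB = eyesB, trimmed = trimmed)
}

welchFromSummary <- function(mA, sA, nA, mB, sB, nB, feature = "feature") {
  se2A <- sA^2 / nA; se2B <- sB^2 / nB
  t <- (mA - mB) / sqrt(se2A + se2B)
  df <- (se2A + se2B)^2 /
        (se2A^2 / (nA - 1) + se2B^2 / (nB - 1))
  p <- 2 * stats::pt(-abs(t), df)
  data.frame(feature = feature, mean_A = mA, mean_B = mB,
             t = t, df = df, p = p, significant = p < 0.05)
}

#' Welch's unpaired t-test between two groups
#'
#' Two-sided unpaired t-test with Welch's correction:
#' `t = (mA - mB) / sqrt(sA^2/nA + sB^2/nB)` with Welch-Satterthwaite
#' degrees of freedom. Significance at p < 0.05.
#'
#' @param valuesA,valuesB numeric vectors (each of length >= 2).
#' @param feature label carried into the result row.
#' @return one-row data.frame: feature, group means, t, df, p, significant.
#' @export
welchT <- function(valuesA, valuesB, feature = "feature") {
  if (length(valuesA) < 2L || length(valuesB) < 2L)
    stopValidation("each group needs at least 2 values")
  if (!all(is.finite(c(valuesA, valuesB))))
    stopValidation("values must be finite")
  welchFromSummary(mean(valuesA), stats::sd(valuesA), length(valuesA),
                   mean(valuesB), stats::sd(valuesB), length(valuesB),
                   feature = feature)
}

#' Welch's t-test from summary statistics
#'
#' Variant of [welchT()] taking per-group mean, SD and n (as printed in
#' study tables) instead of raw values.
#'
#' @param meanA,sdA,nA,meanB,sdB,nB group summary statistics.
#' @param feature label carried into the result row.
#' @return one-row data.frame as in [welchT()].
#' @examples
#' welchTSummary(43.4, 5.3, 14, 36.7, 12.6, 19)
#' @export
welchTSummary <- function(meanA, sdA, nA, meanB, sdB, nB,
                          feature = "feature") {
  if (nA < 2L || nB < 2L) stopValidation("each group needs n >= 2")
  welchFromSummary(meanA, sdA, nA, meanB, sdB, nB, feature = feature)
}

#' Compare all per-eye features between two groups
#'
#' Runs [welchT()] for every shared numeric feature column. Raw p-values are
#' reported per feature with no multiple-testing correction (flagged in the
#' attribute `note`).
#'
#' @param eyesA,eyesB per-eye data.frames (e.g. from [aggregatePerEye()]).
#' @param features character vector of feature columns; defaults to all
#'   shared numeric columns except metadata.
#' @return data.frame with one row per feature.
#' @export
compareGroups <- function(eyesA, eyesB, features = NULL) {
  meta <- c("eye_id", "participant_id", "group", "stage", "age", "AL_mm",
            "RE_D", "zone")
  if (is.null(features)) {
    shared <- intersect(names(eyesA), names(eyesB))
    features <- setdiff(shared[vapply(eyesA[shared], is.numeric, logical(1))],
                        meta)
  }
  out <- do.call(rbind, lapply(features, function(f)
    welchT(eyesA[[f]], eyesB[[f]], feature = f)))
  attr(out, "note") <- "raw per-feature p-values; no multiple-testing correction"
  out
}
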