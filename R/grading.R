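# Multimodal grading bookkeeping: each AO-TFI image is graded against the
# blue-autofluorescence (BAF) and infrared (IR) fundus appearance of the
# same area. Grades: 0 = healthy on all modalities; 1 = neurosensory
# detachment (NSD); 2 = abnormal on BAF, IR and AO-TFI; 3 = abnormal on IR
# and AO-TFI only; 4 = abnormal on AO-TFI only. Combinations outside these
# definitions are ungradable (NA).

#' Assign the multimodal grade from per-image abnormality flags
#'
#' @param nsd logical: neurosensory detachment present.
#' @param baf,ir,aotfi logical: abnormality on BAF, IR fundus and AO-TFI.
#' @return integer vector of grades 0-4; NA for flag combinations the
#'   grading scheme does not define (e.g. BAF abnormal with IR normal).
#' @examples
#' assignGrade(FALSE, FALSE, TRUE, TRUE)  # IR + AO-TFI only -> 3
#' @export
assignGrade <- function(nsd, baf, ir, aotfi) {
  n <- max(length(nsd), length(baf), length(ir), length(aotfi))
  nsd <- rep_len(nsd, n); baf <- rep_len(baf, n)
  ir <- rep_len(ir, n); aotfi <- rep_len(aotfi, n)
  if (anyNA(nsd) || anyNA(baf) || anyNA(ir) || anyNA(aotfi))
    stopValidation("all grading flags must be specified (no NA)")
  g <- rep(NA_integer_, n)
  g[nsd] <- 1L
  i <- !nsd
  g[i & !baf & !ir & !aotfi] <- 0L
  g[i & baf & ir & aotfi] <- 2L
  g[i & !baf & ir & aotfi] <- 3L
  g[i & !baf & !ir & aotfi] <- 4L
  g
}

#' Classify the CSCR stage of an eye
#'
#' Active CSCR has a neurosensory detachment with subretinal fluid (SRF) on
#' OCT; resolved CSCR has no SRF but residual retinal alterations and a
#' history of active disease; healthy contralateral eyes show no alteration
#' on any clinical image.
#'
#' @param srf logical: subretinal fluid present on OCT.
#' @param alterations logical: retinal alterations (or documented history of
#'   active disease) present.
#' @return character vector in `c("active", "resolved", "healthy_CL")`.
#' @export
classifyStage <- function(srf, alterations) {
  n <- max(length(srf), length(alterations))
  srf <- rep_len(srf, n); alterations <- rep_len(alterations, n)
  if (anyNA(srf) || anyNA(alterations))
    stopValidation("stage flags must be specified (no NA)")
  ifelse(srf, "active", ifelse(alterations, "resolved", "healthy_CL"))
}

#' Tabulate grades, stages and AO-TFI abnormality subtypes
#'
#' Counts and integer percentages (rounded half-up) per CSCR stage and per
#' grade over all records, the normal/altered split among healthy-area
#' images (grades 0 and 4), and subtype frequencies among grade-4 images.
#' Subtype columns (`altered_contrast`, `hypo_dots`, `hyper_clusters`) may
#' overlap, so subtype percentages need not sum to 100. Denominators are
#' reported alongside every percentage.
#'
#' @param records data.frame with columns `stage`, `grade` and optionally
#'   the three logical subtype columns.
#' @return list of data.frames `byStage`, `byGrade`, `healthyAreas`,
#'   `grade4Subtypes`.
#' @export
tabulateGrades <- function(records) {
  if (nrow(records) < 1L) stopValidation("need at least one record")
  total <- nrow(records)
  stageLevels <- c("active", "resolved", "healthy_CL")
  byStage <- data.frame(
    stage = stageLevels,
    count = vapply(stageLevels, function(s) sum(records$stage == s), integer(1)),
    denominator = total)
  byStage$percent <- mapply(pctHalfUp, byStage$count, byStage$denominator)

  byGrade <- data.frame(
    grade = 0:4,
    count = vapply(0:4, function(g) sum(records$grade == g, na.rm = TRUE), integer(1)),
    denominator = total)
  byGrade$percent <- mapply(pctHalfUp, byGrade$count, byGrade$denominator)

  healthyArea <- records[!is.na(records$grade) & records$grade %in% c(0L, 4L), , drop = FALSE]
  nh <- nrow(healthyArea)
  healthyAreas <- data.frame(
    pattern = c("normal_mosaic", "altered_pattern"),
    count = c(sum(healthyArea$grade == 0L), sum(healthyArea$grade == 4L)),
    denominator = nh)
  healthyAreas$percent <- mapply(pctHalfUp, healthyAreas$count,
                                 healthyAreas$denominator)

  g4 <- records[!is.na(records$grade) & records$grade == 4L, , drop = FALSE]
  subtypeCols <- c("altered_contrast", "hypo_dots", "hyper_clusters")
  if (all(subtypeCols %in% names(records)) && nrow(g4)) {
    grade4Subtypes <- data.frame(
      subtype = subtypeCols,
      count = vapply(subtypeCols, function(sc) sum(g4[[sc]]), integer(1)),
      denominator = nrow(g4))
    grade4Subtypes$percent <- mapply(pctHalfUp, grade4Subtypes$count,
                                     grade4Subtypes$denominator)
  } else {
    grade4Subtypes <- data.frame(subtype = character(0), count = integer(0),
                                 denominator = integer(0), percent = numeric(0))
  }
  list(byStage = byStage, byGrade = byGrade, healthyAreas = healthyAreas,
       grade4Subtypes = grade4Subtypes)
}
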