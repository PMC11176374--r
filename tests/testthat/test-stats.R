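eyesFixture <- function() {
  data.frame(
    eye_id = c("e1", "e2", "e3", "e4"),
    participant_id = c("p1", "p2", "p3", "p4"),
    group = c("CSCR", "CSCR", "healthy", "CSCR"),
    stage = c("active", "resolved", NA, "healthy_CL"),
    stringsAsFactors = FALSE)
}

imagesFixture <- function() {
  data.frame(
    image_id = sprintf("i%02d", 1:8),
    eye_id = c("e1", "e1", "e1", "e2", "e2", "e3", "e4", "e4"),
    zone = c("Z1", "Z1", "Z5", "Z6", "Z6", "Z2", "Z1", "Z2"),
    included = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    feat = c(10, 14, 99, 50, 60, 7, 1, 3),
    stringsAsFactors = FALSE)
}

test_that("per-eye aggregation applies the study exclusions", {
  out <- aggregatePerEye(imagesFixture(), eyesFixture())
  # e1: mean of the two included Z1 images (Z5 dropped) -> 12
  expect_identical(out$feat[out$eye_id == "e1"], 12)
  # e2 has only Z6 (discretionary) images -> dropped
  expect_false("e2" %in% out$eye_id)
  # e3's only image is not included -> dropped
  expect_false("e3" %in% out$eye_id)
  # e4 is a healthy contralateral eye -> excluded by stage
  expect_false("e4" %in% out$eye_id)
  expect_identical(nrow(out), 1L)
  expect_identical(attr(out, "droppedEyes"), 2L)  # e2 and e3 (e4 pre-removed)
  expect_error(aggregatePerEye(imagesFixture()[, -3], eyesFixture()),
               class = "rpe_validation_error")
})

test_that("baseline matching trims range outliers and respects tolerances", {
  a <- data.frame(eye_id = paste0("a", 1:3), age = c(40, 41, 42),
                  AL_mm = c(23.2, 23.6, 27.0), RE_D = c(0, -1, 0.5))
  b <- data.frame(eye_id = paste0("b", 1:3), age = c(39, 40, 43),
                  AL_mm = c(23.1, 23.5, 23.9), RE_D = c(0.2, -0.8, 0))
  m <- matchBaseline(a, b)
  expect_identical(m$trimmed, "a3")  # the AL = 27 mm outlier
  expect_identical(nrow(m$eyesA), 2L)
  # identical groups: nothing trimmed
  m2 <- matchBaseline(b, b)
  expect_length(m2$trimmed, 0L)
  # infinite tolerances: no trimming even with gross imbalance
  m3 <- matchBaseline(a, b, tolerances = c(age = Inf, AL_mm = Inf, RE_D = Inf))
  expect_length(m3$trimmed, 0L)
  # impossible matching errors out rather than looping
  far <- data.frame(eye_id = "x", age = 90, AL_mm = 29, RE_D = 4)
  expect_error(matchBaseline(far, b, tolerances = c(age = 1e-6)),
               class = "rpe_validation_error")
})

test_that("welchT agrees with stats::t.test and is antisymmetric", {
  set.seed(12)
  a <- rnorm(14, 1, 2)
  b <- rnorm(19, 0, 3)
  mine <- welchT(a, b)
  ref <- stats::t.test(a, b, var.equal = FALSE)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  rev <- welchT(b, a)
  expect_equal(rev$t, -mine$t, tolerance = 1e-12)
  expect_equal(rev$p, mine$p, tolerance = 1e-12)
  # identical samples: t = 0, p = 1
  same <- welchT(a, a)
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  expect_error(welchT(a, b[1]), class = "rpe_validation_error")
  expect_error(welchT(c(a, NA), b), class = "rpe_validation_error")
})

test_that("summary-statistics Welch t matches the independent formula", {
  res <- welchTSummary(43.4, 5.3, 14, 36.7, 12.6, 19)
  oracle <- welchOracle(43.4, 5.3, 14, 36.7, 12.6, 19)
  expect_lt(abs(res$t - oracle[["t"]]), 1e-9)
  expect_lt(abs(res$df - oracle[["df"]]), 1e-9)
  expect_lt(abs(res$p - oracle[["p"]]), 1e-9)
  expect_equal(res$t, 2.08, tolerance = 0.01)
  expect_error(welchTSummary(1, 1, 1, 0, 1, 5),
               class = "rpe_validation_error")
})

test_that("compareGroups runs every shared numeric feature", {
  set.seed(4)
  a <- data.frame(eye_id = paste0("a", 1:6), group = "CSCR", age = 40,
                  f1 = rnorm(6), f2 = rnorm(6, 2))
  b <- data.frame(eye_id = paste0("b", 1:8), group = "healthy", age = 41,
                  f1 = rnorm(8), f2 = rnorm(8))
  cmp <- compareGroups(a, b)
  expect_setequal(cmp$feature, c("f1", "f2"))  # metadata columns excluded
  expect_match(attr(cmp, "note"), "no multiple-testing correction")
  expect_identical(cmp$significant, cmp$p < 0.05)
})
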