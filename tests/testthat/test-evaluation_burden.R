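test_that("ROC AUC equals the exhaustive pairwise statistic", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.7), c(1, 1, 0))@aucRoc, 1.0)
  expect_equal(rocAuc(rep(0.5, 10), rep(c(0, 1), 5))@aucRoc, 0.5)
  expect_equal(rocAuc(c(0.9, 0.8, 0.3), c(1, 0, 1))@aucRoc, 0.5)
  expect_error(rocAuc(1:3, c(1, 1, 1)), "both classes")
  ## property: AUC = Wilcoxon pairwise probability, with ties, n <= 200
  set.seed(13)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    scores <- round(runif(n), 2)          # rounded scores force ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(rocAuc(scores, labels)@aucRoc, pairwiseAuc(scores, labels),
                 tolerance = 1e-12)
    ## independent library cross-check
    expect_equal(rocAuc(scores, labels)@aucRoc,
                 as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("FP-at-sensitivity picks the largest threshold reaching the target", {
  ## separable: zero FPs at 0.9 sensitivity
  s <- c(0.9, 0.8, 0.7, 0.3, 0.2)
  y <- c(1, 1, 1, 0, 0)
  r <- fpAtSensitivity(s, y, 0.9)
  expect_identical(r$fp, 0L)
  ## an inseparable negative above all positives forces FP >= 1 at target 1
  s2 <- c(0.95, 0.9, 0.8); y2 <- c(0, 1, 1)
  expect_gte(fpAtSensitivity(s2, y2, 1.0)$fp, 1L)
  ## oracle: exhaustive threshold scan on overlapping Gaussian scores
  set.seed(14)
  y3 <- c(rep(1, 100), rep(0, 900))
  s3 <- c(rnorm(100, 1), rnorm(900, 0))
  r3 <- fpAtSensitivity(s3, y3, 0.9)
  thr_all <- sort(unique(s3), decreasing = TRUE)
  ok <- vapply(thr_all, function(t) sum(s3 >= t & y3 == 1) / 100 >= 0.9, NA)
  t_star <- thr_all[which(ok)[1]]
  expect_identical(r3$threshold, t_star)
  expect_identical(r3$fp, sum(s3 >= t_star & y3 == 0))
  expect_identical(r3$fn, sum(s3 < t_star & y3 == 1))
  ## FP count is nondecreasing in the target sensitivity
  fps <- vapply(c(0.75, 0.8, 0.85, 0.9, 0.95), function(t)
    fpAtSensitivity(s3, y3, t)$fp, 0L)
  expect_true(all(diff(fps) >= 0))
  expect_error(fpAtSensitivity(c(0.2, 0.9), c(0, 0), 0.9), "unreachable")
})

test_that("threshold metrics follow the standard definitions", {
  pred <- c(rep(1, 18), rep(0, 82))
  y <- c(rep(1, 9), rep(0, 9), rep(1, 1), rep(0, 81))
  m <- thresholdMetrics(pred, y)
  expect_equal(unname(m["sensitivity"]), 0.9)
  expect_equal(unname(m["specificity"]), 0.9)
  expect_equal(unname(m["precision"]), 0.5)
  expect_equal(unname(m["f1"]), 2 * 0.5 * 0.9 / 1.4, tolerance = 1e-12)
  perfect <- thresholdMetrics(y, y)
  expect_true(all(perfect[c("sensitivity", "specificity", "precision", "f1")] == 1))
  allneg <- suppressWarnings(thresholdMetrics(rep(0, 100), y))
  expect_equal(unname(allneg["sensitivity"]), 0)
  expect_equal(unname(allneg["specificity"]), 1)
  expect_warning(thresholdMetrics(rep(0, 4), c(1, 0, 1, 0)), "precision")
})

test_that("the k-fold harness splits at dataset level with fewest-positive validation", {
  mkds <- function(n, npos, mu) {
    y <- c(rep(1, npos), rep(0, n - npos))
    list(labels = y, x = y * mu + rnorm(n))
  }
  set.seed(15)
  ds <- list(a = mkds(30, 10, 3), b = mkds(30, 4, 3), c = mkds(30, 8, 3),
             d = mkds(30, 6, 3))
  seen <- list()
  trainer <- function(train, val) {
    seen[[length(seen) + 1L]] <<- vapply(train, function(d) sum(d$labels), 0)
    TRUE
  }
  scorer <- function(model, test) test$x
  cv <- kfoldHarness(ds, 4, trainer, scorer)
  expect_length(cv$folds, 4L)
  expect_identical(vapply(cv$folds, `[[`, "", "test"), c("a", "b", "c", "d"))
  ## validation = fewest positives among the remaining datasets, never trained on
  expect_false(any(vapply(seen[c(1, 3, 4)], function(s) 4 %in% s, NA)))
  expect_true(all(cv$auc > 0.9))
  expect_error(kfoldHarness(ds, 5, trainer, scorer), "exceeds")
  ## identical datasets give identical per-fold metrics
  ds2 <- list(a = ds$a, b = ds$a, c = ds$a)
  cv2 <- kfoldHarness(ds2, 3, function(train, val) TRUE, scorer)
  expect_identical(cv2$auc[1], cv2$auc[2])
  expect_identical(cv2$auc[1], cv2$auc[3])
})

test_that("corrections zero removals, append additions, and keep an audit log", {
  sp <- c(10, 10, 50)
  lab <- array(0L, c(20L, 20L, 6L))
  lab[2:4, 2:4, 2] <- 1L; lab[8:10, 8:10, 3] <- 2L; lab[14:16, 14:16, 4] <- 3L
  lv <- LabelVolume(lab, sp)
  out <- applyCorrections(lv, removals = 2L)
  expect_identical(labelCount(out), 2L)
  expect_true(all(voxelData(out)[lab == 2L] == 0L))
  add <- which(array(seq_len(prod(dim(lab))), dim(lab)) %in% which(lab == 0L))[1:5]
  out2 <- applyCorrections(lv, additions = list(add))
  expect_identical(labelCount(out2), 4L)
  audit <- attr(out2, "audit")
  expect_identical(audit$action, "add")
  ## remove-then-add-back: same voxels, fresh id, both edits logged
  vox2 <- which(lab == 2L)
  out3 <- applyCorrections(lv, removals = 2L, additions = list(vox2))
  expect_identical(labelCount(out3), 3L)
  expect_true(all(voxelData(out3)[vox2] == voxelData(out3)[vox2][1]))
  expect_identical(nrow(attr(out3, "audit")), 2L)
  expect_error(applyCorrections(lv, removals = 9L), "unknown")
  expect_error(applyCorrections(lv, additions = list(which(lab == 1L))), "overlaps")
})

test_that("effective radius and the growth model reproduce the printed values", {
  ## 4e6 um^3 minimum volume corresponds to a ~98 um sphere radius
  expect_equal(effectiveRadius(4e6), 98.47, tolerance = 0.005)
  expect_equal(effectiveRadius(4 * pi / 3), 1)
  r4 <- 4000  # a 4.0 mm-radius sphere inverts exactly
  expect_equal(effectiveRadius(4 / 3 * pi * r4^3), r4)
  expect_error(effectiveRadius(-1), "positive")
  ## mouse 4: 352.25 mm^3 total volume -> 1.99e7 cells, doubling time 2.62 d
  g <- growthModel(352.25)
  expect_equal(g$cellCount, 1.99e7, tolerance = 0.005)
  expect_equal(g$doublingTimeDays, 2.62, tolerance = 0.005)
  ## one doubling in one day
  cellVol <- 4 / 3 * pi * 7.5^3
  v2 <- 2e5 * cellVol / 0.1 * 1e-9
  expect_equal(growthModel(v2, days = 1)$doublingTimeDays, 1)
  ## population not grown beyond the inoculum: undefined doubling time
  expect_true(is.na(growthModel(1e-4)$doublingTimeDays))
})

test_that("burden reports count per organ and conserve total volume", {
  sp <- c(40, 40, 50)
  gd <- c(40L, 40L, 30L)
  lab <- array(0L, gd)
  lab[5:8, 5:8, 3:5] <- 1L
  lab[20:25, 20:25, 10:14] <- 2L
  lab[30:33, 30:33, 25:27] <- 3L
  lv <- LabelVolume(lab, sp)
  organs <- list(lung = array(0L, gd), liver = array(0L, gd))
  organs$lung[1:12, 1:12, 1:8] <- 1L
  organs$liver[15:30, 15:30, 8:16] <- 1L
  rep1 <- burdenReport(lv, organs)
  expect_identical(unname(rep1@organCounts),
                   c(1L, 1L, 1L))
  expect_identical(names(rep1@organCounts), c("lung", "liver", "rest of body"))
  expect_identical(sum(rep1@organCounts), 3L)
  expect_equal(rep1@totalVolumeMm3, sum(lab > 0) * prod(sp) * 1e-9)
  expect_equal(sum(rep1@perMet$volume_um3) * 1e-9, rep1@totalVolumeMm3)
  ## histogram counts sum to the per-organ counts
  expect_identical(vapply(names(rep1@radiusHist), function(o)
    sum(rep1@radiusHist[[o]]$count), 0L, USE.NAMES = FALSE),
    unname(rep1@organCounts))
  ## no organ masks: everything in "rest of body"
  rep2 <- burdenReport(lv)
  expect_identical(unname(rep2@organCounts["rest of body"]), 3L)
  ## overlapping masks warn and assign by priority
  organs$liver[1:12, 1:12, 1:8] <- 1L
  expect_warning(rep3 <- burdenReport(lv, organs), "overlap")
  expect_identical(unname(rep3@organCounts["lung"]), 1L)
})
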