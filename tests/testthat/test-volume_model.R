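test_that("loadStack stacks slices in order and validates shapes", {
  dir <- withr::local_tempdir()
  ## values on the exact 8-bit grid so TIFF round trips are lossless
  m1 <- matrix(round(seq(0, 255, length.out = 12)) / 255, 3, 4)
  m2 <- matrix(128 / 255, 3, 4)
  p1 <- file.path(dir, "a.tif"); p2 <- file.path(dir, "b.tif")
  tiff::writeTIFF(m1, p1); tiff::writeTIFF(m2, p2)
  v <- loadStack(c(p1, p2, p1), spacing = c(10.472, 10.472, 50))
  expect_identical(gridDim(v), c(4L, 3L, 3L))
  expect_identical(nChannels(v), 1L)
  expect_equal(voxelData(v)[, , 2], t(m2) * 255)
  ## RGB slices give 3 channels
  rgb <- array(runif(3 * 4 * 3), c(3, 4, 3))
  p3 <- file.path(dir, "c.tif")
  tiff::writeTIFF(rgb, p3)
  v3 <- loadStack(c(p3, p3), spacing = c(10, 10, 50))
  expect_identical(nChannels(v3), 3L)
  ## contract cases
  p4 <- file.path(dir, "d.tif")
  tiff::writeTIFF(matrix(0, 5, 5), p4)
  expect_error(loadStack(c(p1, p4), c(10, 10, 50)), "mismatched")
  expect_error(loadStack(character(0), c(10, 10, 50)), "empty")
  ## write/read round trip preserves an 8-bit volume
  out <- withr::local_tempdir()
  writeStack(v, out)
  v2 <- loadStack(sort(list.files(out, full.names = TRUE)), voxelSpacing(v))
  expect_equal(voxelData(v2), voxelData(v), tolerance = 1 / 255)
})

test_that("calibration rescales each channel to the cryo-gel standard", {
  gel <- 1:20
  v <- Volume3D(array(10, c(4, 5, 2)), c(10, 10, 50))
  cal <- calibrate(v, gel)
  expect_equal(mean(voxelData(cal)[gel]), 5)
  expect_equal(voxelData(cal), voxelData(v) * 0.5)
  ## gel mean already at standard -> identity; idempotence
  cal2 <- calibrate(cal, gel)
  expect_equal(voxelData(cal2), voxelData(cal), tolerance = 1e-6)
  ## RGB: per-channel gains, clipping to [0, 255]
  arr <- array(0, c(4, 5, 2, 3))
  arr[, , , 1] <- 75; arr[, , , 2] <- 60; arr[, , , 3] <- 60
  rgb <- calibrate(Volume3D(arr, c(10, 10, 50)), gel)
  expect_equal(mean(voxelData(rgb)[, , , 1][gel]), 150)
  expect_equal(mean(voxelData(rgb)[, , , 2][gel]), 120)
  expect_equal(mean(voxelData(rgb)[, , , 3][gel]), 120)
  expect_error(calibrate(Volume3D(array(0, c(4, 5, 2)), c(10, 10, 50)), gel),
               "zero")
  expect_error(calibrate(v, integer(0)), "empty")
})

test_that("resampling changes grids as round(extent/spacing) and keeps constants", {
  v <- Volume3D(array(7, c(40, 40, 10)), c(10.472, 10.472, 50))
  d <- resampleVolume(v, c(40, 40, 50))
  expect_identical(gridDim(d), as.integer(round(c(40, 40, 10) * c(10.472, 10.472, 50) / c(40, 40, 50))))
  expect_true(all(abs(voxelData(d) - 7) < 1e-12))
  ## nearest-mode round trip of a binary blob mask keeps Dice >= 0.9
  gd <- c(60L, 60L, 30L)
  g <- expand.grid(x = 1:60, y = 1:60, z = 1:30)
  blob <- (g$x - 30)^2 + (g$y - 30)^2 + ((g$z - 15) * 4)^2 <= 14^2
  lab <- array(0L, gd); lab[as.matrix(g[blob, ])] <- 1L
  lv <- LabelVolume(lab, c(10, 10, 40))
  down <- resampleVolume(lv, c(40, 40, 40), "nearest")
  up <- resampleVolume(down, c(10, 10, 40), "nearest")
  expect_gte(CryoMetSeg:::.dice(voxelData(up), lab), 0.9)
  expect_error(resampleVolume(v, c(1e9, 1e9, 1e9)), "zero-size")
})

test_that("chunk plans cover all slices with the exact overlap", {
  p <- planChunks(100, 40, 8)
  expect_equal(unname(p@ranges), rbind(c(0L, 40L), c(32L, 72L), c(64L, 100L)))
  expect_identical(planChunks(30, 40, 8)@ranges[1, ], c(0L, 30L))
  expect_error(planChunks(100, 10, 10), "overlap")
  expect_error(planChunks(0, 10, 2), "positive")
  ## exhaustive property: coverage, exact pairwise overlap, length bound
  for (n in c(1:8, 50, 99, 137, 200)) {
    for (cfg in list(c(20, 0), c(20, 7), c(13, 12), c(40, 8))) {
      pl <- planChunks(n, cfg[1], cfg[2])
      r <- pl@ranges
      covered <- logical(n)
      for (i in seq_len(nrow(r))) covered[(r[i, 1] + 1):r[i, 2]] <- TRUE
      expect_true(all(covered))
      expect_true(all(r[, 2] - r[, 1] <= cfg[1]))
      if (nrow(r) > 1) {
        for (i in seq_len(nrow(r) - 1))
          expect_identical(r[i, 2] - r[i + 1, 1], as.integer(cfg[2]))
      }
    }
  }
})
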