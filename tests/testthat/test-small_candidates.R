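test_that("multi-scale LoG selects the matching scale and ignores constants", {
  expect_true(all(abs(multiscaleLoG(matrix(7, 64, 64))) < 1e-9))
  ## Gaussian blob of sigma 6: strongest single-scale response at sigma = 6
  mkblob <- function(sigma_b, cx, cy, n = 96) {
    g <- expand.grid(x = 1:n, y = 1:n)
    matrix(100 * exp(-((g$x - cx)^2 + (g$y - cy)^2) / (2 * sigma_b^2)), n, n)
  }
  sl <- mkblob(6, 48, 48)
  per_scale <- vapply(c(2, 4, 6, 8, 10), function(s)
    multiscaleLoG(sl, s)[48, 48], 0)
  expect_identical(which.max(per_scale), 3L)
  ## two blobs of sigma 2 and 10: both centers are local maxima of the max-response
  sl2 <- mkblob(2, 24, 48) + mkblob(10, 72, 48)
  r <- multiscaleLoG(sl2)
  for (ctr in list(c(24, 48), c(72, 48))) {
    patch <- r[ctr[1] + (-2:2), ctr[2] + (-2:2)]
    expect_identical(unname(which(patch == max(patch), arr.ind = TRUE)[1, ]),
                     c(3L, 3L))
  }
})

test_that("in-chunk detection seeds, segments by Otsu, and respects masks", {
  sp <- c(10.472, 10.472, 50)
  gd <- c(96L, 96L, 24L)
  blob <- CryoMetSeg:::.addBlob(array(6, gd), gd, sp, c(500, 500, 600), 120, 100)
  valid <- array(1L, gd)
  out <- detectInChunk(blob$vol, valid)
  cc <- CryoMetSeg:::.cc3d_cpp(CryoMetSeg:::.asMask(out), gd, 26L)
  expect_identical(attr(cc, "label_count"), 1L)
  ## the detection covers the blob core (>= 0.9 peak)
  core <- blob$vol >= 0.9 * max(blob$vol)
  expect_gte(mean(out[core] > 0), 0.95)
  ## all-background chunk -> empty
  expect_true(all(detectInChunk(array(6, gd), valid) == 0L))
  ## blob masked out (e.g. inside a big candidate) -> empty
  expect_true(all(detectInChunk(blob$vol, array(0L, gd)) == 0L))
  ## Otsu is undefined on constant intensities (the keep-seeds fallback);
  ## LoG-derived seeds always include contrast, so test the threshold itself
  expect_true(is.na(CryoMetSeg:::.otsuThreshold(rep(5, 100))))
  expect_gt(CryoMetSeg:::.otsuThreshold(c(rep(5, 50), rep(200, 50))), 5)
  expect_lt(CryoMetSeg:::.otsuThreshold(c(rep(5, 50), rep(200, 50))), 200)
})

test_that("chunk merging ORs overlaps and validates shapes", {
  plan <- planChunks(10, 6, 2)
  d <- c(4L, 4L, 10L)
  b1 <- array(0L, c(4, 4, 6)); b1[2, 2, 5] <- 1L   # absolute slice 5
  b2 <- array(0L, c(4, 4, 6)); b2[2, 2, 1] <- 1L   # absolute slice 5 again
  b2[3, 3, 4] <- 1L                                # absolute slice 8
  m <- mergeChunks(list(b1, b2), plan, d)
  expect_identical(sum(m), 2L)                     # OR is idempotent
  expect_identical(m[2, 2, 5], 1L)
  expect_identical(m[3, 3, 8], 1L)
  expect_error(mergeChunks(list(b1, b1[, , 1:3]), plan, d), "match")
})

test_that("post-processing filters by contact, closes gaps, and thresholds volume", {
  sp <- c(10.472, 10.472, 50)
  gd <- c(80L, 80L, 24L)
  voxvol <- prod(sp)
  mkcomp <- function(arr, x0, y0, z0, nvox_xy, nz) {
    side <- ceiling(sqrt(nvox_xy))
    arr[x0:(x0 + side - 1), y0:(y0 + side - 1), z0:(z0 + nz - 1)] <- 1L
    arr
  }
  body <- array(1L, gd)
  big <- array(0L, gd)
  ## component below 4e6 um^3 (27x27x1 = 729 voxels) vs above (28x28x1 = 784)
  small <- array(0L, gd)
  small[10:36, 10:36, 5] <- 1L       # 729 voxels = 3.997e6 um^3
  small[45:72, 45:72, 18] <- 1L      # 784 voxels = 4.30e6 um^3
  out <- postprocessSmall(small, body, big, sp)
  expect_identical(labelCount(out), 1L)
  expect_true(all(voxelData(out)[45:72, 45:72, 18] > 0L))
  expect_true(all(voxelData(out)[10:36, 10:36, 5] == 0L))
  expect_lt(729 * voxvol, 4e6)
  expect_gt(784 * voxvol, 4e6)
  ## two fragments 150 um apart in z are joined by the 200 um z-closing
  frag <- array(0L, gd)
  frag[20:49, 20:49, 8] <- 1L
  frag[20:49, 20:49, 12] <- 1L      # 150 um gap: slices 9-11 empty
  out2 <- postprocessSmall(frag, body, big, sp)
  expect_identical(labelCount(out2), 1L)
  expect_true(all(voxelData(out2)[30, 30, 9:11] > 0L))
  ## a component touching the exterior is removed
  body2 <- array(1L, gd); body2[, , 1:2] <- 0L
  touch <- array(0L, gd)
  touch[20:49, 20:49, 3] <- 1L      # 26-connected to the non-body slice 2
  out3 <- postprocessSmall(touch, body2, big, sp)
  expect_identical(labelCount(out3), 0L)
  ## a component touching a big candidate is removed; big labels survive
  big2 <- array(0L, gd); big2[60:70, 60:70, 10:14] <- 1L
  nearbig <- array(0L, gd); nearbig[30:59, 30:59, 12] <- 1L
  out4 <- postprocessSmall(nearbig, body, big2, sp)
  expect_identical(labelCount(out4), 1L)
  expect_identical(attr(out4, "origin_stage"), "big")
})
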