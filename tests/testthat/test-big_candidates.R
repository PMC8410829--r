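test_that("markers capture large bright blobs and reject small or empty input", {
  fx <- twoBlobVolume()
  mk <- makeMarkers(fx$vol, fx$body)
  expect_identical(labelCount(mk$markers), 2L)
  ## each marker lies inside its blob
  for (l in 1:2) {
    idx <- which(voxelData(mk$markers) == l)
    inside <- mean(idx %in% fx$idx1) + mean(idx %in% fx$idx2)
    expect_gte(inside, 0.9)
  }
  ## blobs under 0.8 mm^3 produce no markers: a 100 um-radius blob
  sp <- fx$spacing
  gd <- fx$dim
  small <- CryoMetSeg:::.addBlob(array(0, gd), gd, sp, c(2000, 2000, 2000), 100, 200)
  mk0 <- makeMarkers(Volume3D(small$vol, sp), fx$body)
  expect_identical(labelCount(mk0$markers), 0L)
  ## zero volume -> no markers
  mkz <- makeMarkers(Volume3D(array(0, gd), sp), fx$body)
  expect_identical(labelCount(mkz$markers), 0L)
})

test_that("Prewitt gradient magnitude matches a finite-difference oracle", {
  v <- Volume3D(array(3, c(10, 12, 8)), c(40, 40, 50))
  expect_true(all(voxelData(gradientMagnitude(v)) == 0))
  ## axis-aligned step: maximal response at the step, zero far away
  s <- array(0, c(20, 10, 8)); s[11:20, , ] <- 10
  g <- voxelData(gradientMagnitude(Volume3D(s, c(40, 40, 50))))
  expect_equal(which.max(g[, 5, 4]) %in% 10:11, TRUE)
  expect_equal(g[3, 5, 4], 0)
  expect_equal(g[18, 5, 4], 0)
  ## oracle: central-difference x-gradient with 3x3 box smoothing
  set.seed(8)
  r <- array(rnorm(9 * 9 * 9), c(9, 9, 9))
  g2 <- voxelData(gradientMagnitude(Volume3D(r, c(10, 10, 10))))
  i <- 5; j <- 5; k <- 5
  ora <- function(axis) {
    acc <- 0
    for (b in -1:1) for (cc in -1:1) {
      co <- c(i, j, k)
      hi <- co; lo <- co
      hi[axis] <- hi[axis] + 1; lo[axis] <- lo[axis] - 1
      off <- setdiff(1:3, axis)
      hi[off[1]] <- hi[off[1]] + b; lo[off[1]] <- lo[off[1]] + b
      hi[off[2]] <- hi[off[2]] + cc; lo[off[2]] <- lo[off[2]] + cc
      acc <- acc + r[hi[1], hi[2], hi[3]] - r[lo[1], lo[2], lo[3]]
    }
    acc
  }
  expect_equal(g2[i, j, k], sqrt(ora(1)^2 + ora(2)^2 + ora(3)^2), tolerance = 1e-9)
})

test_that("marker-controlled watershed partitions the volume around its markers", {
  fx <- twoBlobVolume()
  mk <- makeMarkers(fx$vol, fx$body)
  gm <- gradientMagnitude(mk$smoothed)
  ws <- watershedSegment(gm, mk$markers, fx$body)
  lab <- voxelData(ws)
  ## partition: every voxel gets exactly one label (0 = border basin)
  expect_identical(length(lab), as.integer(prod(fx$dim)))
  expect_true(all(lab %in% 0:2))
  ## each foreground label contains exactly one marker
  for (l in 1:2) {
    inside <- unique(voxelData(mk$markers)[lab == l])
    expect_identical(sort(inside[inside > 0]), l)
  }
  ## each blob covered >= 80% by its own label
  expect_gte(max(table(lab[fx$idx1])) / length(fx$idx1), 0.8)
  expect_gte(max(table(lab[fx$idx2])) / length(fx$idx2), 0.8)
  ## no markers -> all background
  empty <- LabelVolume(array(0L, fx$dim), fx$spacing, relabel = FALSE)
  expect_identical(labelCount(watershedSegment(gm, empty, fx$body)), 0L)
  ## candidate count invariant under marker label permutation
  perm <- voxelData(mk$markers)
  perm[perm == 1L] <- 99L; perm[perm == 2L] <- 1L; perm[perm == 99L] <- 2L
  ws2 <- watershedSegment(gm, LabelVolume(perm, fx$spacing, relabel = FALSE), fx$body)
  big1 <- mergeFragments(ws, fx$body)
  big2 <- mergeFragments(ws2, fx$body)
  expect_identical(labelCount(big1), labelCount(big2))
  expect_identical(voxelData(big1) > 0L, voxelData(big2) > 0L)
  ## every final big candidate contains at least one marker voxel
  for (l in seq_len(labelCount(big1)))
    expect_gt(sum(voxelData(mk$markers)[voxelData(big1) == l] > 0), 0)
})

test_that("fragment merging removes gel/huge fragments and groups near ones", {
  sp <- c(40, 40, 50)
  gd <- c(60L, 60L, 20L)
  body <- new("BodyMask", mask = array(1L, gd), spacing = sp)
  ## two fragments 80 um apart (2 voxels): dilations (radius 120 um) touch
  ws <- array(0L, gd)
  ws[10:14, 10:14, 8:12] <- 1L
  ws[17:21, 10:14, 8:12] <- 2L   # gap of 2 voxels = 80 um < 2 x 120 um
  ws[40:44, 40:44, 8:12] <- 3L   # 1 mm away: separate candidate
  out <- mergeFragments(LabelVolume(ws, sp, relabel = FALSE), body)
  expect_identical(labelCount(out), 2L)
  expect_identical(unique(voxelData(out)[ws %in% 1:2 & ws > 0L])[1],
                   unique(voxelData(out)[ws == 1L]))
  expect_false(unique(voxelData(out)[ws == 3L]) %in% voxelData(out)[ws == 1L])
  ## a fragment above 10% of the body volume is background
  ws2 <- array(0L, gd)
  ws2[1:30, 1:30, 1:10] <- 1L    # 9000 voxels = 12.5% of 72000
  ws2[50:52, 50:52, 5:7] <- 2L
  out2 <- mergeFragments(LabelVolume(ws2, sp, relabel = FALSE), body)
  expect_identical(labelCount(out2), 1L)
  expect_true(all(voxelData(out2)[ws2 == 1L] == 0L))
  ## a fragment mostly outside the body (in gel) is background
  bm <- array(1L, gd); bm[, , 15:20] <- 0L
  body2 <- new("BodyMask", mask = bm, spacing = sp)
  ws3 <- array(0L, gd)
  ws3[5:9, 5:9, 15:19] <- 1L
  ws3[20:24, 20:24, 5:9] <- 2L
  out3 <- mergeFragments(LabelVolume(ws3, sp, relabel = FALSE), body2)
  expect_identical(labelCount(out3), 1L)
  expect_true(all(voxelData(out3)[ws3 == 1L] == 0L))
})

test_that("a single large phantom metastasis is recovered by the big stage", {
  ph <- generatePhantom(phantomSpec(seed = 42, nMetastases = 1L,
                                    radiusRangeUm = c(650, 720),
                                    confounders = character(0)))
  cd <- resampleVolume(ph$color, c(40, 40, 50))
  gd <- resampleVolume(ph$gf, c(40, 40, 50))
  body <- segmentExterior(cd, gd)
  ## at desk scale one 700 um metastasis occupies ~10% of the small phantom
  ## body, so the fragment-size cutoff is raised; the 10% rule itself is
  ## covered by the toy test above
  big <- detectBigCandidates(gd, body, new("WatershedParams", bodyFractionLimit = 0.3))
  expect_identical(labelCount(big), 1L)
  td <- resampleVolume(ph$truth, c(40, 40, 50), "nearest")
  expect_gte(mean(voxelData(big)[voxelData(td) > 0L] > 0L), 0.8)
  ## the final candidate volume carries it as a big-stage candidate
  cand <- detectSmallCandidates(ph$gf, body, big)
  expect_identical(attr(cand, "origin_stage")[1], "big")
})
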