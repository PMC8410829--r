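## Shared fixtures, memoised for the duration of the test session.
.fixtures <- new.env(parent = emptyenv())

.memo <- function(key, compute) {
  if (!exists(key, envir = .fixtures)) assign(key, compute(), envir = .fixtures)
  get(key, envir = .fixtures)
}

## mid-size phantom with well-separated small metastases; used for the
## chunk-equivalence oracle and determinism checks
equivalencePhantomSpec <- function(seed = 9) {
  phantomSpec(seed = seed, gridDim = c(192L, 192L, 80L),
              bodySemiAxesUm = c(870, 870, 1850), nMetastases = 4L,
              radiusRangeUm = c(90, 120), minSeparationUm = 1200,
              confounders = character(0))
}

equivalencePhantom <- function() .memo("eqph", function() {
  ph <- generatePhantom(equivalencePhantomSpec())
  cd <- resampleVolume(ph$color, c(40, 40, 50))
  gd <- resampleVolume(ph$gf, c(40, 40, 50))
  body <- segmentExterior(cd, gd)
  big <- detectBigCandidates(gd, body)
  c(ph, list(colorDown = cd, gfDown = gd, body = body, big = big))
})

## toy down-sampled-scale volume with two separated bright plateau blobs
twoBlobVolume <- function() .memo("twoblob", function() {
  sp <- c(40, 40, 50)
  gd <- c(100L, 100L, 80L)
  gf <- array(0, gd)
  b1 <- CryoMetSeg:::.addBlob(gf, gd, sp, c(1000, 2000, 2000), 600, 180)
  gf <- b1$vol
  b2 <- CryoMetSeg:::.addBlob(gf, gd, sp, c(3000, 2000, 2000), 600, 160)
  gf <- b2$vol
  list(vol = Volume3D(gf, sp),
       body = new("BodyMask", mask = array(1L, gd), spacing = sp),
       idx1 = b1$idx, idx2 = b2$idx, dim = gd, spacing = sp)
})

## small separable patch task: positives carry a bright center block
separablePatch <- function(pos) {
  p <- array(runif(100 * 100 * 12 * 2, 0, 0.2), c(100, 100, 12, 2))
  if (pos) p[41:60, 41:60, 5:8, 1] <- p[41:60, 41:60, 5:8, 1] + 0.6
  pmin(p, 1)
}

tinyArch <- function() cnnArchitecture(widths = c(2L, 3L, 4L))

## digital ball voxel set in a small grid; returns volume, gf, indices
digitalBall <- function(radius_vox = 12L, spacing = c(10, 10, 10)) {
  n <- 2L * radius_vox + 5L
  ctr <- (n + 1) / 2
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  inside <- (g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= radius_vox^2
  arr <- array(0, c(n, n, n))
  arr[as.matrix(g[inside, ])] <- 150
  list(gf = Volume3D(arr, spacing),
       color = Volume3D(array(rep(arr, 3), c(n, n, n, 3)), spacing),
       idx = which(array(inside, c(n, n, n))))
}

## brute-force pairwise (Wilcoxon) AUC oracle
pairwiseAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}
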