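test_that("receptive fields follow the layer-wise recurrence", {
  one <- list(list(type = "conv", kernel = c(3L, 3L, 3L), out = 4L))
  expect_identical(computeReceptiveField(one), c(3L, 3L, 3L))
  stack <- list(list(type = "conv", kernel = c(3L, 3L, 3L), out = 4L),
                list(type = "pool", size = c(2L, 2L, 2L)),
                list(type = "conv", kernel = c(3L, 3L, 3L), out = 4L))
  expect_identical(computeReceptiveField(stack), c(8L, 8L, 8L))
  expect_identical(computeReceptiveField(cnnArchitecture()), c(64L, 64L, 48L))
  bad <- list(list(type = "conv", kernel = c(0L, 3L, 3L), out = 4L))
  expect_error(computeReceptiveField(bad), "nonpositive")
})

test_that("weighted cross entropy matches its closed form", {
  expect_lt(weightedCrossEntropy(c(1 - 1e-9, 1e-9), c(1, 0), c(1, 20)), 1e-8)
  expect_equal(weightedCrossEntropy(c(0.2, 0.8), c(0, 1), c(1, 20)),
               20 * -log(0.8))
  expect_equal(weightedCrossEntropy(c(0.2, 0.8), c(0, 1), c(1, 20)),
               4.46287, tolerance = 1e-5)
  ## linear in the class weight
  expect_equal(weightedCrossEntropy(c(0.3, 0.7), c(0, 1), c(1, 40)),
               2 * weightedCrossEntropy(c(0.3, 0.7), c(0, 1), c(1, 20)))
  expect_warning(weightedCrossEntropy(c(1, 0), c(0, 1)), "clamped")
})

test_that("probability fusion is the fixed 0.3/0.4/0.3 convex combination", {
  expect_equal(fuseProbabilities(1, 1, 1), 1)
  expect_equal(fuseProbabilities(0.5, 0.5, 0.5), 0.5)
  expect_equal(fuseProbabilities(0.2, 0.9, 0.4), 0.54)
  ## convexity: output within [min, max] of the inputs
  set.seed(1)
  for (i in 1:50) {
    p <- runif(3)
    f <- fuseProbabilities(p[1], p[2], p[3])
    expect_gte(f, min(p)); expect_lte(f, max(p))
  }
})

test_that("augmentation applies one 2D transform to all slices and channels", {
  set.seed(2)
  p <- array(runif(20 * 20 * 4 * 2), c(20, 20, 4, 2))
  expect_equal(augmentPatch(p), p, tolerance = 1e-12)              # identity draw
  flip2 <- augmentPatch(augmentPatch(p, flipH = TRUE), flipH = TRUE)
  expect_equal(flip2, p, tolerance = 1e-12)                         # involution
  b <- augmentPatch(array(0.5, c(8, 8, 2, 2)), brightness = 1.2)
  expect_true(all(abs(b - 0.6) < 1e-12))                            # scalar gain
  expect_true(all(augmentPatch(p, brightness = 3) <= 1))            # clipping
  ## the same in-plane transform hits every slice and channel
  r <- augmentPatch(p, rotation = 90)
  for (k in 1:4) for (c in 1:2)
    expect_equal(r[, , k, c], augmentPatch(p[, , k, c, drop = FALSE],
                                           rotation = 90)[, , 1, 1])
})

test_that("analytic gradients agree with finite differences", {
  set.seed(2)
  layers <- list(list(type = "conv", kernel = c(3L, 3L, 3L), out = 3L),
                 list(type = "pool", size = c(2L, 2L, 2L)),
                 list(type = "conv", kernel = c(3L, 3L, 1L), out = 4L),
                 list(type = "gap"),
                 list(type = "dense", out = 5L),
                 list(type = "dense", out = 2L))
  mkw <- function(fan, out) list(W = matrix(rnorm(fan * out, 0, 0.3), fan, out),
                                 b = rnorm(out) * 0.1)
  weights <- list(mkw(27 * 2, 3), mkw(9 * 3, 4), mkw(4, 5), mkw(5, 2))
  dm <- c(8L, 8L, 4L, 2L, 2L)
  X <- array(runif(prod(dm)), dm)
  y <- c(0L, 1L)
  g <- CryoMetSeg:::.cnn_grad_cpp(weights, layers, as.numeric(X), dm, y, 1, 20)
  lossfn <- function(w)
    CryoMetSeg:::.cnn_grad_cpp(w, layers, as.numeric(X), dm, y, 1, 20)$loss
  eps <- 1e-3
  for (li in 1:4) {
    for (t in 1:4) {
      wp <- weights; wp[[li]]$W[t] <- wp[[li]]$W[t] + eps
      wm <- weights; wm[[li]]$W[t] <- wm[[li]]$W[t] - eps
      num <- (lossfn(wp) - lossfn(wm)) / (2 * eps)
      ana <- g$grads[[li]]$W[t]
      ## single-precision forward: compare only non-negligible entries
      if (abs(num) > 0.01)
        expect_equal(ana, num, tolerance = 0.05)
    }
  }
})

test_that("CNN training learns a separable task, is seeded, and stops early", {
  arch <- tinyArch()
  set.seed(4)
  labs <- rep(c(0L, 1L), 24)
  pats <- lapply(labs, separablePatch)
  vlabs <- rep(c(0L, 1L), 8)
  vpats <- lapply(vlabs, separablePatch)
  cfg <- new("TrainingConfig", learningRate = 1e-3, maxEpochs = 3L,
             patience = 2L, seed = 7L)
  m <- trainCnn(pats, labs, vpats, vlabs, arch, cfg)
  sc <- predictCnn(m, vpats)
  expect_gte(rocAuc(sc, vlabs)@aucRoc, 0.95)
  expect_lte(nrow(m$history), 3L)
  ## deterministic: identical seed reproduces the loss trajectory
  cfg2 <- new("TrainingConfig", learningRate = 1e-3, maxEpochs = 2L,
              patience = 1L, seed = 7L)
  m1 <- trainCnn(pats[1:16], labs[1:16], vpats[1:8], vlabs[1:8], arch, cfg2)
  m2 <- trainCnn(pats[1:16], labs[1:16], vpats[1:8], vlabs[1:8], arch, cfg2)
  expect_identical(m1$history, m2$history)
  ## a split without positives is a training error
  expect_error(trainCnn(pats[labs == 0L], labs[labs == 0L], vpats, vlabs,
                        arch, cfg2), "positives")
})

test_that("multi-scale CNN features concatenate to 768 in scale order", {
  arch <- tinyArch()
  set.seed(6)
  models <- lapply(1:3, function(s)
    list(weights = CryoMetSeg:::.initWeights(arch), arch = arch))
  ps <- new("PatchSet", patches = lapply(1:3, function(s)
    array(runif(100 * 100 * 12 * 2, 0, 1), c(100, 100, 12, 2))))
  f <- extractCnnFeatures(models, list(ps, ps))
  expect_identical(dim(f), c(2L, 768L))
  expect_identical(f[1, ], f[2, ])        # identical inputs, identical features
  ## zero weights and biases give the zero feature vector
  zmodels <- lapply(models, function(m) {
    m$weights <- lapply(m$weights, function(w)
      list(W = w$W * 0, b = w$b * 0))
    m
  })
  expect_true(all(extractCnnFeatures(zmodels, list(ps)) == 0))
  ## feature width other than 256 is a specification error
  bad <- models
  bad[[1]]$arch@featureWidth <- 128L
  expect_error(extractCnnFeatures(bad, list(ps)), "256")
})

test_that("CNN-only mode fuses the three per-scale probabilities", {
  arch <- tinyArch()
  set.seed(17)
  models <- lapply(1:3, function(s)
    list(weights = CryoMetSeg:::.initWeights(arch), arch = arch))
  ps <- lapply(1:2, function(i) new("PatchSet", patches = lapply(1:3, function(s)
    array(runif(100 * 100 * 12 * 2), c(100, 100, 12, 2)))))
  sc <- classifyCandidates(ps, NULL, models, mode = "cnn")
  expect_length(sc, 2L)
  expect_true(all(sc >= 0 & sc <= 1))
  p_scale <- vapply(1:3, function(s)
    predictCnn(models[[s]], lapply(ps, function(p) p@patches[[s]])), numeric(2))
  expect_equal(sc, fuseProbabilities(p_scale[, 1], p_scale[, 2], p_scale[, 3]),
               tolerance = 1e-12)
})

test_that("the random forest separates, is deterministic, and rejects one-class input", {
  set.seed(11)
  n <- 60
  y <- rep(c(0, 1), n / 2)
  X <- matrix(rnorm(n * 797), n, 797)
  X[y == 1, 30] <- X[y == 1, 30] + 6     # separable feature
  colnames(X) <- paste0("f", 1:797)
  cfg <- new("RfConfig", nTrees = 100L, maxDepth = 20L, maxFeaturesPerSplit = 40L,
             minSamplesLeaf = 2L, minSamplesSplit = 5L, posWeight = 5, seed = 2L)
  m <- trainRandomForest(X, y, cfg)
  expect_equal(rocAuc(predictRandomForest(m, X), y)@aucRoc, 1.0)
  ## consistent row/label permutation leaves predictions unchanged (seeded)
  p <- sample(n)
  m2 <- trainRandomForest(X[p, ], y[p], cfg)
  expect_equal(predictRandomForest(m2, X), predictRandomForest(m2, X))
  expect_error(trainRandomForest(X, rep(1, n), cfg), "both classes")
  ## label shuffling drives cross-validated AUC to chance
  aucs <- vapply(1:20, function(i) {
    set.seed(100 + i)
    ys <- sample(y)
    half <- seq_len(n / 2)
    ms <- trainRandomForest(X[half, ], ys[half], cfg)
    rocAuc(predictRandomForest(ms, X[-half, ]), ys[-half])@aucRoc
  }, 0)
  expect_equal(mean(aucs), 0.5, tolerance = 0.1)
})

test_that("hyperparameter search returns the best evaluated configuration", {
  ## single point: that point
  one <- optimizeHyperparameters(list(a = 5), function(cfg) cfg$a, nIter = 10)
  expect_identical(one$best$a, 5)
  ## exhaustive 1-D grid: unique optimum found
  grid <- optimizeHyperparameters(list(w = seq(5, 30, 5)),
                                  function(cfg) -(cfg$w - 20)^2, nIter = 100)
  expect_identical(grid$best$w, 20)
  expect_identical(nrow(grid$log), 6L)
  ## sampled 2-D space: best returned value matches the evaluation log
  res <- optimizeHyperparameters(list(a = 1:50, b = 1:50),
                                 function(cfg) cfg$a + cfg$b, nIter = 60, seed = 3)
  expect_equal(res$bestValue, max(res$log$objective))
  expect_error(optimizeHyperparameters(list(), function(cfg) 1), "empty")
})
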