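#' Construct a CnnArchitecture
#'
#' The reference layer stack (used for all three scales): eight 3x3x3
#' convolutions and a final 3x3x1 convolution interleaved with three 2x2x2
#' max-poolings, followed by global average pooling, a 256-wide dense
#' feature layer (ReLU) and a 2-class softmax. Channel widths default to
#' (32, 64, 128); reduced widths are valid as long as the feature width
#' stays 256 and the receptive field stays 64 x 64 x 48.
#'
#' @param widths integer(3) channel widths of the three blocks.
#' @param featureWidth penultimate dense width (must be 256).
#' @param inputDim input patch dims, (100, 100, 12, 2).
#' @return a \linkS4class{CnnArchitecture}.
#' @export
cnnArchitecture <- function(widths = c(32L, 64L, 128L), featureWidth = 256L,
                            inputDim = c(100L, 100L, 12L, 2L)) {
  w <- as.integer(widths)
  layers <- list(
    list(type = "conv", kernel = c(3L, 3L, 3L), out = w[1]),
    list(type = "conv", kernel = c(3L, 3L, 3L), out = w[1]),
    list(type = "pool", size = c(2L, 2L, 2L)),
    list(type = "conv", kernel = c(3L, 3L, 3L), out = w[2]),
    list(type = "pool", size = c(2L, 2L, 2L)),
    list(type = "conv", kernel = c(3L, 3L, 3L), out = w[3]),
    list(type = "conv", kernel = c(3L, 3L, 3L), out = w[3]),
    list(type = "pool", size = c(2L, 2L, 2L)),
    list(type = "conv", kernel = c(3L, 3L, 3L), out = w[3]),
    list(type = "conv", kernel = c(3L, 3L, 1L), out = w[3]),
    list(type = "gap"),
    list(type = "dense", out = as.integer(featureWidth)),
    list(type = "dense", out = 2L))
  arch <- new("CnnArchitecture", layers = layers,
              inputDim = as.integer(inputDim),
              featureWidth = as.integer(featureWidth))
  rf <- computeReceptiveField(arch)
  if (!identical(rf, c(64L, 64L, 48L)))
    stop("cnnArchitecture: receptive field must be 64 x 64 x 48, got ",
         paste(rf, collapse = " x "))
  arch
}

#' Theoretical receptive field of a CNN layer stack
#'
#' Applies the per-axis recurrence r <- r + (k - 1) * j, j <- j * s over the
#' convolution (stride 1) and pooling (stride = size) layers.
#'
#' @param arch a \linkS4class{CnnArchitecture} or a bare layer list.
#' @return integer(3): receptive-field extent per axis (x, y, z).
#' @export
computeReceptiveField <- function(arch) {
  layers <- if (is(arch, "CnnArchitecture")) arch@layers else arch
  r <- c(1L, 1L, 1L)
  j <- c(1L, 1L, 1L)
  for (lay in layers) {
    if (lay$type == "conv") {
      k <- as.integer(lay$kernel)
      if (any(k <= 0L)) stop("computeReceptiveField: nonpositive kernel extent")
      r <- r + (k - 1L) * j
    } else if (lay$type == "pool") {
      s <- as.integer(lay$size)
      if (any(s <= 0L)) stop("computeReceptiveField: nonpositive pool size")
      r <- r + (s - 1L) * j
      j <- j * s
    }
  }
  r
}

#' Class-weighted cross-entropy loss
#'
#' \code{-(w1 Y1 log P1 + w2 Y2 log P2)} with natural logarithm; class 1 is
#' cancer (-), class 2 cancer (+). Probabilities of 0 for the true class are
#' clamped at 1e-7 (with a warning).
#'
#' @param P numeric(2) predicted probability pair (sums to 1).
#' @param Y numeric(2) one-hot truth.
#' @param w numeric(2) class weights, default (1, 20).
#' @return the loss value.
#' @export
weightedCrossEntropy <- function(P, Y, w = c(1, 20)) {
  stopifnot(length(P) == 2L, length(Y) == 2L, all(Y %in% c(0, 1)), sum(Y) == 1)
  p <- P[which(Y == 1)]
  if (p <= 0) {
    warning("weightedCrossEntropy: zero probability for the true class; clamped")
    p <- 1e-7
  }
  unname(-w[which(Y == 1)] * log(p))
}

#' Fuse the per-scale predicted probabilities
#'
#' \code{p_fuse = 0.3 p1 + 0.4 p2 + 0.3 p3} for scales 100x100x12,
#' 200x200x24 and 400x400x48.
#'
#' @param p1,p2,p3 probabilities in [0, 1] (vectorized).
#' @return the fused probability.
#' @export
fuseProbabilities <- function(p1, p2, p3) 0.3 * p1 + 0.4 * p2 + 0.3 * p3

#' Augment a candidate patch
#'
#' 2D-based augmentation: one parameter draw (zoom, rotation, flips,
#' brightness) applied identically to every z-slice and both channels;
#' output clipped to [0, 1].
#'
#' @param patch array 100 x 100 x 12 x 2 (or any 4D patch).
#' @param zoom,rotation,flipH,flipV,brightness the drawn parameters.
#' @return the augmented patch.
#' @export
augmentPatch <- function(patch, zoom = 1, rotation = 0, flipH = FALSE,
                         flipV = FALSE, brightness = 1) {
  d <- dim(patch)
  array(.augment_cpp(as.numeric(patch), d, zoom, rotation, flipH, flipV,
                     brightness), d)
}

## weight initialization (He) for an architecture; all draws via R's RNG
.initWeights <- function(arch) {
  layers <- arch@layers
  cin <- arch@inputDim[4]
  weights <- list()
  for (lay in layers) {
    if (lay$type == "conv") {
      k <- prod(lay$kernel)
      fan <- k * cin
      W <- matrix(rnorm(fan * lay$out, 0, sqrt(2 / fan)), fan, lay$out)
      weights[[length(weights) + 1L]] <- list(W = W, b = rep(0, lay$out))
      cin <- lay$out
    } else if (lay$type == "dense") {
      W <- matrix(rnorm(cin * lay$out, 0, sqrt(2 / cin)), cin, lay$out)
      weights[[length(weights) + 1L]] <- list(W = W, b = rep(0, lay$out))
      cin <- lay$out
    }
  }
  weights
}

.adamInit <- function(weights) {
  lapply(weights, function(w) list(mW = w$W * 0, vW = w$W * 0,
                                   mb = w$b * 0, vb = w$b * 0))
}

.adamStep <- function(weights, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(weights)) {
    g <- grads[[i]]
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    mhW <- s$mW / (1 - beta1^t); vhW <- s$vW / (1 - beta2^t)
    mhb <- s$mb / (1 - beta1^t); vhb <- s$vb / (1 - beta2^t)
    weights[[i]]$W <- weights[[i]]$W - lr * mhW / (sqrt(vhW) + eps)
    weights[[i]]$b <- weights[[i]]$b - lr * mhb / (sqrt(vhb) + eps)
    state[[i]] <- s
  }
  list(weights = weights, state = state)
}

## stack a list of patches into the (nx, ny, nz, c, B) batch array
.stackPatches <- function(patches) {
  d <- dim(patches[[1]])
  arr <- array(0, c(d, length(patches)))
  for (i in seq_along(patches)) arr[, , , , i] <- patches[[i]]
  arr
}

.cnnForwardBatch <- function(model, patches) {
  arr <- .stackPatches(patches)
  .cnn_forward_cpp(model$weights, model$arch@layers, as.numeric(arr), dim(arr))
}

#' Train one per-scale 3D CNN
#'
#' Mini-batch Adam on the class-weighted cross entropy with on-the-fly
#' positive oversampling (every batch holds at least
#' \code{ceiling(minPosFraction * batchSize)} positives, drawn with
#' replacement) and per-candidate 2D augmentation. Training stops when the
#' validation loss has not improved for \code{patience} epochs or at
#' \code{maxEpochs}; the weights with the best validation loss are returned.
#' Fully seeded: identical config and seed give identical loss trajectories.
#'
#' @param trainPatches,valPatches lists of 100x100x12x2 arrays.
#' @param trainLabels,valLabels integer vectors (1 = cancer positive).
#' @param arch a \linkS4class{CnnArchitecture}.
#' @param config a \linkS4class{TrainingConfig}.
#' @return model list with \code{weights}, \code{arch}, \code{history}
#'   (per-epoch train/validation loss) and \code{bestEpoch}.
#' @export
trainCnn <- function(trainPatches, trainLabels, valPatches, valLabels,
                     arch = cnnArchitecture(), config = new("TrainingConfig")) {
  trainLabels <- as.integer(trainLabels)
  valLabels <- as.integer(valLabels)
  if (!any(trainLabels == 1L) || !all(c(0L, 1L) %in% trainLabels) ||
      !any(valLabels == 1L))
    stop("trainCnn: both splits must contain positives and negatives")
  set.seed(config@seed)
  weights <- .initWeights(arch)
  state <- .adamInit(weights)
  pos <- which(trainLabels == 1L)
  n <- length(trainLabels)
  bs <- config@batchSize
  minPos <- ceiling(config@minPosFraction * bs)
  valArr <- .stackPatches(valPatches)
  history <- data.frame(epoch = integer(0), train = numeric(0), val = numeric(0))
  best <- list(loss = Inf, weights = weights, epoch = 0L)
  t <- 0L
  for (epoch in seq_len(config@maxEpochs)) {
    ord <- sample.int(n)
    nb <- ceiling(n / bs)
    tr_loss <- 0
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1L) * bs + 1L):min(b * bs, n)]
      if (config@oversample) {
        np <- sum(trainLabels[idx] == 1L)
        if (np < minPos && length(pos)) {
          slots <- tail(which(trainLabels[idx] == 0L), minPos - np)
          idx[slots] <- pos[sample.int(length(pos), length(slots), replace = TRUE)]
        }
      }
      batch <- lapply(idx, function(i) {
        p <- trainPatches[[i]]
        zr <- config@zoomRange; rr <- config@rotationRange; br <- config@brightnessRange
        augmentPatch(p, zoom = runif(1, zr[1], zr[2]),
                     rotation = runif(1, rr[1], rr[2]),
                     flipH = config@flips && runif(1) < 0.5,
                     flipV = config@flips && runif(1) < 0.5,
                     brightness = runif(1, br[1], br[2]))
      })
      arr <- .stackPatches(batch)
      g <- .cnn_grad_cpp(weights, arch@layers, as.numeric(arr), dim(arr),
                         trainLabels[idx], 1, config@posWeight)
      t <- t + 1L
      up <- .adamStep(weights, g$grads, state, config@learningRate, t)
      weights <- up$weights
      state <- up$state
      tr_loss <- tr_loss + g$loss
    }
    ## validation loss (no augmentation)
    fv <- .cnn_forward_cpp(weights, arch@layers, as.numeric(valArr), dim(valArr))
    pv <- pmax(fv$probs[cbind(seq_along(valLabels), valLabels + 1L)], 1e-7)
    wv <- ifelse(valLabels == 1L, config@posWeight, 1)
    val_loss <- mean(-wv * log(pv))
    history <- rbind(history, data.frame(epoch = epoch, train = tr_loss / nb,
                                         val = val_loss))
    if (val_loss < best$loss - 1e-12) {
      best <- list(loss = val_loss, weights = weights, epoch = epoch)
    } else if (epoch - best$epoch >= config@patience) {
      break
    }
  }
  list(weights = best$weights, arch = arch, history = history,
       bestEpoch = best$epoch, config = config)
}

#' Predict cancer probabilities with a trained per-scale CNN
#'
#' @param model a model from \code{\link{trainCnn}}.
#' @param patches list of patch arrays.
#' @return numeric vector of cancer (+) probabilities.
#' @export
predictCnn <- function(model, patches) {
  .cnnForwardBatch(model, patches)$probs[, 2]
}

#' Extract the concatenated multi-scale CNN feature vector
#'
#' Penultimate-layer (256-wide) activations of the three per-scale models,
#' concatenated in scale order (1, 2, 3): 768 features per candidate.
#'
#' @param models list of three models from \code{\link{trainCnn}}.
#' @param patchSets list of \linkS4class{PatchSet} objects (one per candidate).
#' @return numeric matrix (candidates x 768).
#' @export
extractCnnFeatures <- function(models, patchSets) {
  stopifnot(length(models) == 3L)
  for (m in models)
    if (m$arch@featureWidth != 256L)
      stop("extractCnnFeatures: penultimate feature width must be 256")
  out <- NULL
  for (s in 1:3) {
    patches <- lapply(patchSets, function(ps) ps@patches[[s]])
    f <- .cnnForwardBatch(models[[s]], patches)$features
    out <- cbind(out, f)
  }
  colnames(out) <- paste0("cnn_", rep(1:3, each = 256), "_", rep(1:256, 3))
  out
}
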