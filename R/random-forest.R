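#' Train the random forest on CNN + hand-crafted features
#'
#' A probability forest on the 768 CNN features concatenated with the 29
#' hand-crafted features (797 per candidate), with positive class weighting.
#' Hyperparameters map onto ranger: number of trees, max depth, features per
#' split (mtry), minimum samples at a leaf (min.bucket), minimum samples to
#' split (min.node.size) and class weights; single-threaded and seeded for
#' determinism.
#'
#' @param features numeric matrix (candidates x 797).
#' @param labels factor or 0/1 vector of truth labels (1/"+" = cancer).
#' @param config an \linkS4class{RfConfig}.
#' @return list with the fitted \code{forest} and the \code{config}.
#' @export
trainRandomForest <- function(features, labels, config = new("RfConfig")) {
  y <- if (is.factor(labels)) labels == "+" else labels == 1
  if (length(unique(y)) < 2L)
    stop("trainRandomForest: training set must contain both classes")
  df <- as.data.frame(features)
  df$.y <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = config@nTrees,
    mtry = min(config@maxFeaturesPerSplit, ncol(features)),
    max.depth = config@maxDepth,
    min.bucket = config@minSamplesLeaf,
    min.node.size = config@minSamplesSplit,
    class.weights = c(neg = 1, pos = config@posWeight),
    probability = TRUE, num.threads = 1L, seed = config@seed)
  list(forest = fit, config = config)
}

#' Predict cancer probabilities with a trained random forest
#'
#' @param model model from \code{\link{trainRandomForest}}.
#' @param features numeric matrix with the training column layout.
#' @return numeric vector of cancer (+) probabilities.
#' @export
predictRandomForest <- function(model, features) {
  p <- predict(model$forest, data = as.data.frame(features),
               num.threads = 1L)$predictions
  unname(p[, "pos"])
}

#' Hyperparameter search maximizing validation AUC
#'
#' Seeded sequential model-free search over a discrete/integer space: when
#' the space is small enough it is enumerated exhaustively, otherwise
#' \code{nIter} configurations are drawn uniformly without replacement. The
#' returned configuration maximizes the objective among evaluated points;
#' the full evaluation log is retained.
#'
#' @param space named list; each element is the vector of candidate values
#'   of one hyperparameter (e.g. \code{list(posWeight = seq(5, 30, 5))}).
#' @param objective function(config list) -> numeric (validation AUC).
#' @param nIter evaluation budget (default 100).
#' @param seed RNG seed for the draws.
#' @return list with \code{best} (named list), \code{bestValue} and
#'   \code{log} (data.frame of evaluated points and objective values).
#' @export
optimizeHyperparameters <- function(space, objective, nIter = 100L, seed = 1L) {
  if (length(space) == 0L || any(lengths(space) == 0L))
    stop("optimizeHyperparameters: empty search space")
  total <- prod(lengths(space))
  set.seed(seed)
  if (total <= nIter) {
    grid <- expand.grid(space, KEEP.OUT.ATTRS = FALSE)
  } else {
    grid <- as.data.frame(lapply(space, function(v)
      v[sample.int(length(v), nIter, replace = TRUE)]))
    grid <- unique(grid)
  }
  vals <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid)))
    vals[i] <- objective(as.list(grid[i, , drop = FALSE]))
  best <- which.max(vals)
  list(best = as.list(grid[best, , drop = FALSE]), bestValue = vals[best],
       log = cbind(grid, objective = vals))
}

#' Classify candidates
#'
#' Scores every candidate either with the random forest on multi-scale CNN
#' plus hand-crafted features (the default, best-performing mode) or by
#' fusing the three per-scale CNN probabilities (0.3/0.4/0.3).
#'
#' @param patchSets list of \linkS4class{PatchSet}, one per candidate.
#' @param handcrafted numeric matrix (candidates x 29).
#' @param cnnModels list of three per-scale models.
#' @param rfModel model from \code{\link{trainRandomForest}} (RF mode).
#' @param mode "rf" or "cnn".
#' @return numeric vector of cancer (+) probabilities.
#' @export
classifyCandidates <- function(patchSets, handcrafted, cnnModels,
                               rfModel = NULL, mode = c("rf", "cnn")) {
  mode <- match.arg(mode)
  if (mode == "cnn") {
    ps <- lapply(1:3, function(s) lapply(patchSets, function(p) p@patches[[s]]))
    p1 <- predictCnn(cnnModels[[1]], ps[[1]])
    p2 <- predictCnn(cnnModels[[2]], ps[[2]])
    p3 <- predictCnn(cnnModels[[3]], ps[[3]])
    return(fuseProbabilities(p1, p2, p3))
  }
  stopifnot(!is.null(rfModel))
  feats <- cbind(extractCnnFeatures(cnnModels, patchSets), handcrafted)
  predictRandomForest(rfModel, feats)
}
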