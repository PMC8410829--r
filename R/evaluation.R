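#' ROC / precision-recall evaluation of candidate scores
#'
#' Threshold sweep over the unique scores (ties grouped at one threshold);
#' ROC and precision-recall areas by the trapezoid rule. The PRC is
#' integrated over recall with the curve anchored at the smallest observed
#' recall.
#'
#' @param scores numeric candidate scores (higher = more cancer-like).
#' @param labels truth labels: factor "+"/"-", logical, or 0/1.
#' @return a \linkS4class{ScoreEval}.
#' @export
rocAuc <- function(scores, labels) {
  y <- .asBinaryLabels(labels)
  if (length(unique(y)) < 2L)
    stop("rocAuc: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  grp <- !duplicated(ss)
  tp <- cumsum(ys); fp <- cumsum(!ys)
  ## keep the last index of each tie group
  last <- which(c(grp[-1], TRUE))
  thr <- ss[last]
  P <- sum(y); N <- sum(!y)
  sens <- c(0, tp[last] / P)
  fpr <- c(0, fp[last] / N)
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / P
  aucRoc <- sum(diff(fpr) * (head(sens, -1) + tail(sens, -1)) / 2)
  aucPrc <- if (length(rec) > 1) {
    sum(diff(rec) * (head(prec, -1) + tail(prec, -1)) / 2)
  } else 0
  ## anchor at the smallest observed recall
  aucPrc <- aucPrc + rec[1] * prec[1]
  new("ScoreEval",
      roc = data.frame(threshold = c(Inf, thr), sensitivity = sens,
                       specificity = 1 - fpr),
      prc = data.frame(threshold = thr, recall = rec, precision = prec),
      aucRoc = aucRoc, aucPrc = aucPrc, threshold = NA_real_,
      confusion = c(TP = NA_real_, FP = NA_real_, TN = NA_real_, FN = NA_real_))
}

.asBinaryLabels <- function(labels) {
  if (is.factor(labels)) labels == "+" else as.logical(labels == 1 | labels == TRUE)
}

#' False positives at a target sensitivity
#'
#' The largest threshold achieving sensitivity >= target, with the FP and FN
#' counts at that threshold.
#'
#' @param scores,labels as in \code{\link{rocAuc}}.
#' @param target target sensitivity in (0, 1].
#' @return list with \code{threshold}, \code{fp}, \code{fn},
#'   \code{sensitivity}.
#' @export
fpAtSensitivity <- function(scores, labels, target) {
  stopifnot(target > 0, target <= 1)
  y <- .asBinaryLabels(labels)
  if (!any(y)) stop("fpAtSensitivity: target sensitivity unreachable (no positives)")
  thr_set <- sort(unique(scores), decreasing = TRUE)
  for (t in thr_set) {
    pred <- scores >= t
    sens <- sum(pred & y) / sum(y)
    if (sens >= target)
      return(list(threshold = t, fp = sum(pred & !y), fn = sum(!pred & y),
                  sensitivity = sens))
  }
  stop("fpAtSensitivity: target sensitivity unreachable")
}

#' Threshold classification metrics
#'
#' Sensitivity, specificity, precision and F1 from binary predictions;
#' undefined ratios (zero denominators) are NA with a warning.
#'
#' @param predictions logical/0-1 predicted positives.
#' @param labels truth labels.
#' @return named numeric (sensitivity, specificity, precision, f1, tp, fp,
#'   tn, fn).
#' @export
thresholdMetrics <- function(predictions, labels) {
  y <- .asBinaryLabels(labels)
  p <- as.logical(predictions == 1 | predictions == TRUE)
  tp <- sum(p & y); fp <- sum(p & !y); tn <- sum(!p & !y); fn <- sum(!p & y)
  div <- function(a, b, what) {
    if (b == 0) { warning("thresholdMetrics: ", what, " undefined"); NA_real_ }
    else a / b
  }
  sens <- div(tp, tp + fn, "sensitivity")
  spec <- div(tn, tn + fp, "specificity")
  prec <- div(tp, tp + fp, "precision")
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  c(sensitivity = sens, specificity = spec, precision = prec, f1 = f1,
    tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Mouse-level k-fold cross-validation harness
#'
#' Splits at whole-dataset (mouse/phantom) granularity, never at candidate
#' level. In each fold one dataset is the test set; among the remaining
#' datasets the one with the fewest cancer (+) candidates is the validation
#' set and the rest are training data. Fold assignment is deterministic in
#' the dataset order.
#'
#' @param datasets named list of datasets; each must carry a \code{labels}
#'   element (truth labels) plus whatever \code{trainer} needs.
#' @param k number of folds (= number of test datasets; k <= length(datasets)).
#' @param trainer function(train, val) -> model, where train/val are lists
#'   of datasets.
#' @param scorer function(model, test) -> numeric scores for the test
#'   dataset's candidates.
#' @return list of per-fold results (test dataset name, scores,
#'   \linkS4class{ScoreEval}) plus mean and sd of the ROC AUCs.
#' @export
kfoldHarness <- function(datasets, k, trainer, scorer) {
  if (k > length(datasets)) stop("kfoldHarness: k exceeds the dataset count")
  npos <- vapply(datasets, function(d) sum(.asBinaryLabels(d$labels)), 0)
  folds <- vector("list", k)
  aucs <- numeric(k)
  for (i in seq_len(k)) {
    test <- datasets[[i]]
    rest <- datasets[-i]
    val_i <- which.min(npos[-i])
    val <- rest[[val_i]]
    train <- rest[-val_i]
    model <- trainer(train, val)
    scores <- scorer(model, test)
    ev <- rocAuc(scores, test$labels)
    aucs[i] <- ev@aucRoc
    folds[[i]] <- list(test = names(datasets)[i], scores = scores, eval = ev)
  }
  list(folds = folds, auc = aucs, meanAuc = mean(aucs), sdAuc = sd(aucs))
}

#' Apply programmatic corrections to a candidate label volume
#'
#' Programmatic replacement for interactive FP exclusion / FN inclusion:
#' removed labels are zeroed, additions get fresh labels, survivors are
#' relabeled consecutively; an audit log records every edit.
#'
#' @param cand a candidate \linkS4class{LabelVolume}.
#' @param removals integer vector of label ids to remove.
#' @param additions list of integer vectors of linear voxel indices to add.
#' @return corrected \linkS4class{LabelVolume} with attribute
#'   \code{"audit"} (data.frame of edits).
#' @export
applyCorrections <- function(cand, removals = integer(0), additions = list()) {
  stopifnot(is(cand, "LabelVolume"))
  lab <- cand@labels
  n <- cand@labelCount
  removals <- as.integer(removals)
  if (length(removals) && (any(removals < 1L) || any(removals > n)))
    stop("applyCorrections: unknown candidate id")
  audit <- data.frame(action = character(0), id = integer(0), voxels = integer(0))
  if (length(removals)) {
    sizes <- tabulate(lab[lab > 0L], n)
    lab[lab %in% removals] <- 0L
    audit <- rbind(audit, data.frame(action = "remove", id = removals,
                                     voxels = sizes[removals]))
  }
  kept <- lab > 0L
  for (add in additions) {
    if (any(lab[add] > 0L))
      stop("applyCorrections: addition overlaps a kept candidate")
    n <- n + 1L
    lab[add] <- n
    audit <- rbind(audit, data.frame(action = "add", id = n,
                                     voxels = length(add)))
  }
  rm(kept)
  out <- LabelVolume(lab, voxelSpacing(cand), cand@origin, relabel = TRUE)
  attr(out, "audit") <- audit
  out
}
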