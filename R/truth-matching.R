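#' Modified intersection-over-union
#'
#' Intersection divided by the smaller of the two region volumes
#' (tolerant of over-segmentation): \code{|A & B| / min(|A|, |B|)}.
#'
#' @param a,b integer vectors of linear voxel indices on the same grid.
#' @return ratio in [0, 1].
#' @export
modifiedIoU <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("modifiedIoU: empty voxel set")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Candidate table from a label volume
#'
#' One row per candidate label with centroid (micrometres), voxel count and
#' volume; the voxel index sets are attached as a list.
#'
#' @param cand a \linkS4class{LabelVolume} of candidates.
#' @return data.frame with attribute \code{"voxelSets"} (list of integer
#'   index vectors) and, when present on \code{cand}, \code{"origin_stage"}.
#' @export
candidateTable <- function(cand) {
  stopifnot(is(cand, "LabelVolume"))
  n <- cand@labelCount
  sp <- voxelSpacing(cand)
  if (n == 0L) {
    tab <- data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), voxels = numeric(0), volume_um3 = numeric(0))
    attr(tab, "voxelSets") <- list()
    return(tab)
  }
  st <- .label_stats_cpp(cand@labels, dim(cand@labels), n)
  tab <- data.frame(id = seq_len(n),
                    x_um = (st$cx + 0.5) * sp[1],
                    y_um = (st$cy + 0.5) * sp[2],
                    z_um = (st$cz + 0.5) * sp[3],
                    voxels = st$count,
                    volume_um3 = st$count * prod(sp))
  pos <- cand@labels > 0L
  vs <- split(which(pos), cand@labels[pos])
  attr(tab, "voxelSets") <- vs[order(as.integer(names(vs)))]
  os <- attr(cand, "origin_stage")
  if (!is.null(os)) attr(tab, "origin_stage") <- os
  tab
}

#' Assign cancer (+)/(-) truth labels to candidates
#'
#' A candidate is cancer (+) iff its center of mass lies within 60 um of the
#' center of mass of some annotated tumor, OR its modified IoU with some
#' annotation exceeds 0.5; otherwise cancer (-). The matched annotation is
#' the one maximizing the modified IoU (ties broken by the smallest
#' annotation id). With no annotations (the healthy-mouse case) all
#' candidates are cancer (-). Distances are physical (micrometres), so the
#' rule is correct under anisotropic spacing; "within 60 um" is strict.
#'
#' @param candidates a candidate table from \code{\link{candidateTable}}.
#' @param annotations a \linkS4class{LabelVolume} of manual annotations on
#'   the same grid.
#' @param distanceUm centroid distance rule (default 60).
#' @param iouThreshold modified-IoU rule (default 0.5).
#' @return the candidate table with added columns \code{truth}
#'   (factor "+"/"-") and \code{matchedAnnotation} (NA when unmatched).
#' @export
assignTruth <- function(candidates, annotations, distanceUm = 60,
                        iouThreshold = 0.5) {
  stopifnot(is(annotations, "LabelVolume"))
  vs <- attr(candidates, "voxelSets")
  ann <- truthTable(annotations)
  annSets <- {
    pos <- annotations@labels > 0L
    if (any(pos)) {
      s <- split(which(pos), annotations@labels[pos])
      s[order(as.integer(names(s)))]
    } else list()
  }
  n <- nrow(candidates)
  truth <- rep("-", n)
  matched <- rep(NA_integer_, n)
  if (nrow(ann) > 0L && n > 0L) {
    annC <- as.matrix(ann[, c("x_um", "y_um", "z_um")])
    for (i in seq_len(n)) {
      ci <- c(candidates$x_um[i], candidates$y_um[i], candidates$z_um[i])
      dd <- sqrt(colSums((t(annC) - ci)^2))
      ious <- vapply(annSets, function(s) modifiedIoU(vs[[i]], s), 0)
      if (any(dd < distanceUm) || any(ious > iouThreshold)) truth[i] <- "+"
      if (any(ious > 0)) matched[i] <- ann$label[which.max(ious)]
    }
  }
  candidates$truth <- factor(truth, levels = c("-", "+"))
  candidates$matchedAnnotation <- matched
  attr(candidates, "voxelSets") <- vs
  candidates
}
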