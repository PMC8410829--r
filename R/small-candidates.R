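#' Multi-scale Laplacian-of-Gaussian blob response of a 2D slice
#'
#' Per-sigma scale-normalized negative-LoG response (bright blobs positive),
#' maximized voxelwise across the scales. Sigmas are in in-plane voxels.
#'
#' @param slice 2D numeric matrix (single channel).
#' @param sigmas LoG scales in voxels (default 2, 4, 6, 8, 10).
#' @return matrix of the maximal response.
#' @export
multiscaleLoG <- function(slice, sigmas = c(2, 4, 6, 8, 10)) {
  stopifnot(is.matrix(slice))
  d <- c(dim(slice), 1L)
  r <- .log2d_max_cpp(as.numeric(slice), d, as.numeric(sigmas))
  matrix(r, dim(slice)[1], dim(slice)[2])
}

## upsample a 3D array onto an explicit grid with nearest-neighbour sampling
.upsampleToGrid <- function(arr, fromSpacing, toDim, toSpacing) {
  out <- .resample3_cpp(as.numeric(arr), dim(arr), as.integer(toDim),
                        toSpacing / fromSpacing, TRUE)
  array(as.integer(round(out)), toDim)
}

#' Detect and segment small-metastases candidates within one chunk
#'
#' Seeds are voxels whose maximal multi-scale LoG response exceeds the
#' threshold T1, restricted to the valid mask (body minus big candidates).
#' Seeds are dilated with the 5-slice spheroidal element (per-slice disk
#' radii 3, 7, 12, 7, 3 voxels); an Otsu threshold of the GF intensities is
#' computed within each connected dilated neighbourhood and the above-Otsu
#' voxels within the neighbourhood form the segmentation. Neighbourhoods
#' with constant intensity keep only their seeds (Otsu undefined; a warning
#' is logged). Neighbourhoods touching an interior chunk face are deferred
#' to the neighbouring chunk so that chunked and unchunked runs agree when
#' the overlap covers the neighbourhood extent.
#'
#' @param gfChunk 3D array of GF intensities (full resolution).
#' @param validMaskChunk binary 3D array; 0 voxels are never seeds.
#' @param params a \linkS4class{SmallParams}.
#' @param interiorFaces logical(2); whether the low/high z-face of this chunk
#'   is an interior face of a chunk plan (default both exterior).
#' @return binary 3D array of detected voxels.
#' @export
detectInChunk <- function(gfChunk, validMaskChunk, params = new("SmallParams"),
                          interiorFaces = c(FALSE, FALSE)) {
  d <- dim(gfChunk)
  resp <- .log2d_max_cpp(as.numeric(gfChunk), d, params@logSigmas)
  seeds <- .asMask(array(resp > params@seedThreshold & validMaskChunk > 0L, d) * 1L)
  if (!any(seeds > 0L)) return(array(0L, d))
  nb <- .morph_cpp(seeds, d, .spheroidOffsets(params@seedDilationRadii), TRUE)
  cc <- .cc3d_cpp(nb, d, 26L)
  nlab <- attr(cc, "label_count")
  out <- array(0L, d)
  warned <- FALSE
  ## neighbourhoods touching an interior face belong to the overlapping chunk
  dropped <- logical(nlab)
  if (interiorFaces[1]) dropped[unique(cc[, , 1][cc[, , 1] > 0L])] <- TRUE
  if (interiorFaces[2]) dropped[unique(cc[, , d[3]][cc[, , d[3]] > 0L])] <- TRUE
  idx_by_lab <- split(which(cc > 0L), cc[cc > 0L])
  for (l in seq_len(nlab)) {
    if (dropped[l]) next
    idx <- idx_by_lab[[as.character(l)]]
    vals <- gfChunk[idx]
    thr <- .otsuThreshold(vals)
    if (is.na(thr)) {
      if (!warned) {
        warning("detectInChunk: constant-intensity neighbourhood; keeping seeds only")
        warned <- TRUE
      }
      out[idx] <- seeds[idx]
    } else {
      out[idx] <- as.integer(vals > thr)
    }
  }
  out
}

#' Merge per-chunk segmentations into a full volume
#'
#' Voxelwise logical OR on overlapping slices, equality elsewhere.
#'
#' @param binaries list of binary 3D arrays, one per chunk of \code{plan}.
#' @param plan a \linkS4class{ChunkPlan}.
#' @param fullDim integer(3) full-volume dimensions.
#' @return binary 3D array covering all slices.
#' @export
mergeChunks <- function(binaries, plan, fullDim) {
  stopifnot(is(plan, "ChunkPlan"), length(binaries) == plan@nChunks)
  out <- array(0L, fullDim)
  for (i in seq_len(plan@nChunks)) {
    r <- plan@ranges[i, ]
    zi <- (r[1] + 1L):r[2]
    b <- binaries[[i]]
    if (!identical(dim(b), c(fullDim[1:2], length(zi))))
      stop("mergeChunks: chunk ", i, " does not match its planned range")
    out[, , zi] <- out[, , zi] | b
  }
  .asMask(out * 1L)
}

#' Post-process small candidates and assemble the final candidate volume
#'
#' Removes small-candidate components 26-connected to the exterior (non-body)
#' region or to big-candidate voxels, applies morphological closing with a
#' 40 x 40 x 200 um element to bridge inhomogeneous GF signal, removes
#' components smaller than 4e6 um^3, and unions the survivors with the
#' up-sampled big candidates into the final consecutive candidate labels
#' (big-candidate merged groups keep their identity).
#'
#' @param smallBinary binary 3D array at full resolution.
#' @param bodyFull binary 3D array: 1 = body, at full resolution.
#' @param bigFull integer 3D array of up-sampled big-candidate labels
#'   (0 = none) at full resolution.
#' @param spacing numeric(3) full-resolution spacing in micrometres.
#' @param params a \linkS4class{SmallParams}.
#' @return the final candidate \linkS4class{LabelVolume}; attribute
#'   \code{"origin_stage"} maps each label to "big" or "small".
#' @export
postprocessSmall <- function(smallBinary, bodyFull, bigFull, spacing,
                             params = new("SmallParams")) {
  d <- dim(smallBinary)
  forbidden <- .asMask(((bodyFull == 0L) | (bigFull > 0L)) * 1L)
  ## drop components touching the forbidden region (26-connectivity)
  touch <- .morph_cpp(forbidden, d, .boxOffsets(c(3L, 3L, 3L)), TRUE)
  cc <- .cc3d_cpp(.asMask(smallBinary), d, 26L)
  nlab <- attr(cc, "label_count")
  if (nlab > 0L) {
    bad <- unique(cc[cc > 0L & touch > 0L])
    keep <- .asMask(array(cc > 0L & !(cc %in% bad), d) * 1L)
  } else {
    keep <- array(0L, d)
  }
  ## closing with the 40 x 40 x 200 um element
  if (any(keep > 0L)) {
    box <- .boxOffsets(.oddExtent(params@closingSizeUm, spacing))
    keep <- .morph_cpp(.morph_cpp(keep, d, box, TRUE), d, box, FALSE)
    ## closing must not bleed into exterior or big candidates
    keep[forbidden > 0L] <- 0L
  }
  ## volume filter and relabel
  cc2 <- .cc3d_cpp(.asMask(keep), d, 26L)
  n2 <- attr(cc2, "label_count")
  voxvol <- prod(spacing)
  small_lab <- array(0L, d)
  ns <- 0L
  if (n2 > 0L) {
    sizes <- tabulate(cc2[cc2 > 0L], n2)
    keep_ids <- which(sizes * voxvol >= params@minVolumeUm3)
    ns <- length(keep_ids)
    if (ns > 0L) {
      map <- integer(n2)
      map[keep_ids] <- seq_len(ns)
      pos <- cc2 > 0L
      small_lab[pos] <- map[cc2[pos]]
    }
  }
  nb <- max(0L, max(bigFull))
  final <- array(0L, d)
  final[bigFull > 0L] <- bigFull[bigFull > 0L]
  final[small_lab > 0L] <- small_lab[small_lab > 0L] + nb
  out <- LabelVolume(final, spacing, relabel = FALSE)
  attr(out, "origin_stage") <- c(rep("big", nb), rep("small", ns))
  out
}

#' Detect small-metastases candidates and assemble the final candidates
#'
#' Runs chunked multi-scale LoG detection at full resolution (the body mask
#' and big candidates are up-sampled with nearest-neighbour mode), merges
#' chunks by logical OR, and post-processes into the final candidate label
#' volume.
#'
#' @param gfFull full-resolution GF \linkS4class{Volume3D}.
#' @param body a \linkS4class{BodyMask} on the down-sampled grid.
#' @param bigCand big-candidate \linkS4class{LabelVolume} on the down-sampled
#'   grid (may have 0 labels).
#' @param params a \linkS4class{SmallParams}.
#' @param slicesPerChunk chunk height; defaults to the full volume (one chunk).
#' @param overlapSlices chunk overlap (default 12).
#' @return the final candidate \linkS4class{LabelVolume} (see
#'   \code{\link{postprocessSmall}}).
#' @export
detectSmallCandidates <- function(gfFull, body, bigCand,
                                  params = new("SmallParams"),
                                  slicesPerChunk = NULL, overlapSlices = 12L) {
  stopifnot(is(gfFull, "Volume3D"), is(body, "BodyMask"), is(bigCand, "LabelVolume"))
  d <- gridDim(gfFull)
  sp <- voxelSpacing(gfFull)
  bodyFull <- .upsampleToGrid(body@mask, voxelSpacing(body), d, sp)
  bigFull <- .upsampleToGrid(bigCand@labels, voxelSpacing(bigCand), d, sp)
  valid <- .asMask((bodyFull > 0L & bigFull == 0L) * 1L)
  if (is.null(slicesPerChunk)) slicesPerChunk <- d[3]
  plan <- planChunks(d[3], slicesPerChunk, overlapSlices)
  gf <- gfFull@voxels
  bins <- vector("list", plan@nChunks)
  for (i in seq_len(plan@nChunks)) {
    r <- plan@ranges[i, ]
    zi <- (r[1] + 1L):r[2]
    faces <- c(r[1] > 0L, r[2] < d[3])
    bins[[i]] <- detectInChunk(gf[, , zi, drop = FALSE],
                               valid[, , zi, drop = FALSE], params, faces)
  }
  smallBin <- mergeChunks(bins, plan, d)
  postprocessSmall(smallBin, bodyFull, bigFull, sp, params)
}
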