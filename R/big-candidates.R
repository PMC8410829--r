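#' Foreground markers for the big-metastases watershed
#'
#' On the down-sampled GF volume restricted to the body: Gaussian smoothing
#' (sigma 160 um, converted per axis to voxels), intensity threshold
#' (default 20), morphological hole filling with a 400 um ball, 3D connected
#' components (26-connectivity), removal of components smaller than 0.8 mm^3,
#' and erosion with a 120 um ball. An empty marker set is a valid result.
#'
#' @param gfDown down-sampled GF \linkS4class{Volume3D}.
#' @param body a \linkS4class{BodyMask} on the same grid.
#' @param params a \linkS4class{WatershedParams}.
#' @return list with \code{markers} (\linkS4class{LabelVolume}) and
#'   \code{smoothed} (the Gaussian-smoothed GF \linkS4class{Volume3D}, the
#'   input to the gradient step).
#' @export
makeMarkers <- function(gfDown, body, params = new("WatershedParams")) {
  stopifnot(is(gfDown, "Volume3D"), is(body, "BodyMask"))
  d <- gridDim(gfDown)
  sp <- voxelSpacing(gfDown)
  v <- gfDown@voxels * body@mask
  sigma_vox <- params@gaussianSigmaUm / sp
  sm <- array(.gauss3_cpp(as.numeric(v), d, sigma_vox), d)
  fg <- .asMask((sm > params@gfThreshold) * 1L)
  ## hole filling: closing with the ball element, then fill enclosed cavities
  ball <- .ballOffsets(rep(params@holefillDiameterUm / 2, 3), sp)
  fg <- .morph_cpp(.morph_cpp(fg, d, ball, TRUE), d, ball, FALSE)
  fg <- .fill_holes_cpp(fg, d)
  cc <- .cc3d_cpp(fg, d, params@connectivity)
  nlab <- attr(cc, "label_count")
  markers <- array(0L, d)
  if (nlab > 0L) {
    voxvol_mm3 <- prod(sp) * 1e-9
    sizes <- tabulate(cc[cc > 0L], nlab)
    keep <- which(sizes * voxvol_mm3 >= params@minMarkerVolumeMm3)
    if (length(keep)) {
      kept <- .asMask(array(cc %in% keep, d) * 1L)
      ero <- .morph_cpp(kept, d, .ballOffsets(rep(params@erosionDiameterUm / 2, 3), sp),
                        FALSE)
      markers <- array(.cc3d_cpp(ero, d, params@connectivity), d)
    }
  }
  list(markers = LabelVolume(markers, sp, relabel = FALSE),
       smoothed = Volume3D(sm, sp))
}

#' Prewitt gradient-magnitude volume
#'
#' Per-axis 3 x 3 x 3 Prewitt responses combined as the Euclidean magnitude.
#'
#' @param gfSmoothed single-channel \linkS4class{Volume3D} (Gaussian-smoothed GF).
#' @return gradient-magnitude \linkS4class{Volume3D}.
#' @export
gradientMagnitude <- function(gfSmoothed) {
  stopifnot(is(gfSmoothed, "Volume3D"), nChannels(gfSmoothed) == 1L)
  d <- gridDim(gfSmoothed)
  g <- .prewitt3_cpp(as.numeric(gfSmoothed@voxels), d)
  Volume3D(array(g, d), voxelSpacing(gfSmoothed))
}

#' Marker-controlled 3D watershed
#'
#' Floods the gradient-magnitude volume from regional minima imposed at the
#' foreground markers and at the volume border (the background marker) with
#' 26-neighbour connectivity. The output labels partition the volume; every
#' nonzero label contains exactly one input marker, and the border basin is
#' label 0. Flooding ties are broken by deterministic insertion order.
#'
#' @param gradmag gradient-magnitude \linkS4class{Volume3D}.
#' @param markers marker \linkS4class{LabelVolume}.
#' @param body a \linkS4class{BodyMask} (interface; flooding runs everywhere).
#' @param params a \linkS4class{WatershedParams}.
#' @return watershed \linkS4class{LabelVolume}.
#' @export
watershedSegment <- function(gradmag, markers, body = NULL,
                             params = new("WatershedParams")) {
  stopifnot(is(gradmag, "Volume3D"), is(markers, "LabelVolume"))
  d <- gridDim(gradmag)
  stopifnot(identical(d, gridDim(markers)))
  if (markers@labelCount == 0L)
    return(LabelVolume(array(0L, d), voxelSpacing(gradmag), relabel = FALSE))
  ws <- .watershed_cpp(as.numeric(gradmag@voxels), markers@labels, d,
                       params@connectivity)
  LabelVolume(array(ws, d), voxelSpacing(gradmag), relabel = FALSE)
}

#' Merge watershed fragments into big-metastases candidates
#'
#' Fragments lying in the immaterial cryo-gel region (majority of voxels
#' outside the body) or larger than 10 percent of the mouse body are assigned
#' to background. Each remaining fragment is dilated by 0.12 mm and fragments
#' whose dilations touch are merged into one candidate. The output labels
#' encode the merged groups (binary candidate mask = labels > 0).
#'
#' @param ws watershed \linkS4class{LabelVolume}.
#' @param body a \linkS4class{BodyMask}.
#' @param params a \linkS4class{WatershedParams}.
#' @return candidate \linkS4class{LabelVolume} with one label per merged group.
#' @export
mergeFragments <- function(ws, body, params = new("WatershedParams")) {
  stopifnot(is(ws, "LabelVolume"), is(body, "BodyMask"))
  d <- gridDim(ws)
  sp <- voxelSpacing(ws)
  nlab <- ws@labelCount
  if (nlab == 0L)
    return(LabelVolume(array(0L, d), sp, relabel = FALSE))
  lab <- ws@labels
  sizes <- tabulate(lab[lab > 0L], nlab)
  inbody <- tabulate(lab[lab > 0L & body@mask > 0L], nlab)
  body_vox <- sum(body@mask)
  drop <- which(sizes == 0 | inbody < 0.5 * sizes |
                  sizes > params@bodyFractionLimit * body_vox)
  if (length(drop)) lab[lab %in% drop] <- 0L
  if (!any(lab > 0L))
    return(LabelVolume(array(0L, d), sp, relabel = FALSE))
  ## group fragments whose 0.12 mm dilations touch
  bin <- .asMask((lab > 0L) * 1L)
  dil <- .morph_cpp(bin, d, .ballOffsets(rep(params@mergeDilationUm, 3), sp), TRUE)
  groups <- .cc3d_cpp(dil, d, params@connectivity)
  out <- array(0L, d)
  pos <- lab > 0L
  out[pos] <- groups[pos]
  LabelVolume(out, sp, relabel = TRUE)
}

#' Detect big-metastases candidates
#'
#' Convenience wrapper running \code{\link{makeMarkers}},
#' \code{\link{gradientMagnitude}}, \code{\link{watershedSegment}} and
#' \code{\link{mergeFragments}} on the down-sampled GF volume.
#'
#' @param gfDown down-sampled GF \linkS4class{Volume3D}.
#' @param body a \linkS4class{BodyMask}.
#' @param params a \linkS4class{WatershedParams}.
#' @return candidate \linkS4class{LabelVolume} (down-sampled grid).
#' @export
detectBigCandidates <- function(gfDown, body, params = new("WatershedParams")) {
  mk <- makeMarkers(gfDown, body, params)
  if (mk$markers@labelCount == 0L)
    return(LabelVolume(array(0L, gridDim(gfDown)), voxelSpacing(gfDown),
                       relabel = FALSE))
  gm <- gradientMagnitude(mk$smoothed)
  ws <- watershedSegment(gm, mk$markers, body, params)
  mergeFragments(ws, body, params)
}
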