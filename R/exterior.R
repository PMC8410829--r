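#' Segment the exterior (cryo-gel, skin, fur) and produce the body mask
#'
#' Works on the down-sampled (40 x 40 x 50 um) grid. An intensity threshold
#' of > 110 on the green channel of the color volume captures the bright
#' ivory cryo-gel (and bright interior structures such as bone, which are
#' discarded): after 3D connected components (26-connectivity), only
#' border-touching components at least half the size of the largest
#' border-touching component are kept as gel. The gel mask is dilated with
#' an in-plane disk of radius \code{dilateRadiusVox} voxels (80 um) to absorb
#' skin and fur, and the body is the complement restricted to the region
#' enclosed by the gel (complement components touching the volume border are
#' not body).
#'
#' @param colorDown down-sampled RGB \linkS4class{Volume3D}.
#' @param gfDown down-sampled GF \linkS4class{Volume3D} (kept for interface
#'   symmetry; the mask derives from the color volume).
#' @param greenThreshold green-channel threshold (default 110).
#' @param dilateRadiusVox in-plane dilation radius in voxels (default 2).
#' @return a \linkS4class{BodyMask}.
#' @export
segmentExterior <- function(colorDown, gfDown = NULL, greenThreshold = 110,
                            dilateRadiusVox = 2L) {
  stopifnot(is(colorDown, "Volume3D"), nChannels(colorDown) == 3L)
  d <- gridDim(colorDown)
  green <- colorDown@voxels[, , , 2]
  bright <- .asMask((green > greenThreshold) * 1L)
  cc <- .cc3d_cpp(bright, d, 26L)
  nlab <- attr(cc, "label_count")
  if (nlab == 0L) stop("segmentExterior: no gel found (nothing above threshold)")
  ## which components touch the volume border?
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  touch <- sort(unique(cc[border & cc > 0L]))
  if (length(touch) == 0L) stop("segmentExterior: no gel found (no border component)")
  sizes <- tabulate(cc[cc > 0L], nlab)
  keep <- touch[sizes[touch] >= 0.5 * max(sizes[touch])]
  gel <- .asMask(array(cc %in% keep, d) * 1L)
  gel_dil <- .morph_cpp(gel, d, .diskOffsets(dilateRadiusVox), TRUE)
  ## body = complement components enclosed by the gel (not touching border)
  comp <- .asMask((gel_dil == 0L) * 1L)
  cc2 <- .cc3d_cpp(comp, d, 6L)
  open_labels <- unique(cc2[border & cc2 > 0L])
  body <- array(cc2 > 0L & !(cc2 %in% open_labels), d)
  new("BodyMask", mask = .asMask(body * 1L), spacing = voxelSpacing(colorDown))
}
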