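#' Accessors for volumetric containers
#'
#' \code{voxelSpacing} returns the (sx, sy, sz) spacing in micrometres,
#' \code{gridDim} the voxel grid dimensions, \code{voxelData} the raw array,
#' \code{nChannels} the channel count of a \linkS4class{Volume3D}.
#'
#' @param x a Volume3D, LabelVolume or BodyMask.
#' @return numeric/integer vectors or the underlying array.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))
#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("labelCount", function(x) standardGeneric("labelCount"))

#' @rdname accessors
setMethod("voxelSpacing", "Volume3D", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelSpacing", "LabelVolume", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelSpacing", "BodyMask", function(x) x@spacing)
#' @rdname accessors
setMethod("gridDim", "Volume3D", function(x) dim(x@voxels)[1:3])
#' @rdname accessors
setMethod("gridDim", "LabelVolume", function(x) dim(x@labels))
#' @rdname accessors
setMethod("gridDim", "BodyMask", function(x) dim(x@mask))
#' @rdname accessors
setMethod("voxelData", "Volume3D", function(x) x@voxels)
#' @rdname accessors
setMethod("voxelData", "LabelVolume", function(x) x@labels)
#' @rdname accessors
setMethod("voxelData", "BodyMask", function(x) x@mask)
#' @rdname accessors
setMethod("nChannels", "Volume3D", function(x) {
  d <- dim(x@voxels)
  if (length(d) == 4L) d[4] else 1L
})
#' @rdname accessors
setMethod("labelCount", "LabelVolume", function(x) x@labelCount)

setMethod("show", "Volume3D", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("Volume3D: %s voxels, %d channel(s), spacing (%.3f, %.3f, %.3f) um\n",
              paste(d[1:3], collapse = " x "), nChannels(object),
              object@spacing[1], object@spacing[2], object@spacing[3]))
})

setMethod("show", "LabelVolume", function(object) {
  cat(sprintf("LabelVolume: %s voxels, %d label(s)\n",
              paste(dim(object@labels), collapse = " x "), object@labelCount))
})

setMethod("show", "BodyMask", function(object) {
  cat(sprintf("BodyMask: %s voxels, %.1f%% body\n",
              paste(dim(object@mask), collapse = " x "),
              100 * mean(object@mask)))
})

setMethod("show", "ChunkPlan", function(object) {
  cat(sprintf("ChunkPlan: %d chunk(s) of <= %d slices, overlap %d\n",
              object@nChunks, object@slicesPerChunk, object@overlapSlices))
  for (i in seq_len(object@nChunks))
    cat(sprintf("  [%d, %d)\n", object@ranges[i, 1], object@ranges[i, 2]))
})

setMethod("show", "BurdenReport", function(object) {
  cat("BurdenReport\n")
  cat("  per-organ counts:", paste(names(object@organCounts),
                                   object@organCounts, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  total tumor volume: %.3f mm^3\n", object@totalVolumeMm3))
  if (!is.null(object@growth$cellCount))
    cat(sprintf("  inferred cancer cells: %.3g; doubling time: %s days\n",
                object@growth$cellCount,
                ifelse(is.na(object@growth$doublingTimeDays), "undefined",
                       sprintf("%.2f", object@growth$doublingTimeDays))))
})
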