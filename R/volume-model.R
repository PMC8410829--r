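#' Construct a Volume3D
#'
#' @param voxels 3D array (nx, ny, nz) or 4D array (nx, ny, nz, 3) of
#'   intensities on the 0--255 scale.
#' @param spacing numeric(3) voxel spacing in micrometres.
#' @param origin numeric(3) physical offset in micrometres.
#' @return a \linkS4class{Volume3D}.
#' @export
Volume3D <- function(voxels, spacing, origin = c(0, 0, 0)) {
  storage.mode(voxels) <- "double"
  new("Volume3D", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a LabelVolume
#'
#' @param labels 3D integer array, 0 = background; labels need not be
#'   consecutive on input and are relabeled consecutively.
#' @param spacing numeric(3) in micrometres.
#' @param origin numeric(3) in micrometres.
#' @param relabel relabel nonzero values to consecutive 1..n (default TRUE).
#' @return a \linkS4class{LabelVolume}.
#' @export
LabelVolume <- function(labels, spacing, origin = c(0, 0, 0), relabel = TRUE) {
  storage.mode(labels) <- "integer"
  if (relabel) {
    u <- sort(unique(labels[labels > 0L]))
    if (length(u) && !identical(u, seq_along(u))) {
      map <- integer(max(u))
      map[u] <- seq_along(u)
      pos <- labels > 0L
      labels[pos] <- map[labels[pos]]
    }
    n <- length(u)
  } else {
    n <- length(unique(labels[labels > 0L]))
  }
  new("LabelVolume", labels = labels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), labelCount = as.integer(n))
}

#' Load a per-slice image stack into a Volume3D
#'
#' Slices are stacked along z in the order of \code{paths}. Grayscale TIFFs
#' become single-channel volumes, RGB TIFFs 3-channel volumes. Intensities
#' are rescaled from the [0, 1] convention of \code{tiff::readTIFF} to 0--255.
#'
#' @param paths ordered character vector of slice image paths (TIFF).
#' @param spacing numeric(3) voxel spacing in micrometres.
#' @return a \linkS4class{Volume3D}.
#' @export
loadStack <- function(paths, spacing) {
  if (length(paths) == 0L) stop("loadStack: empty slice list")
  slices <- lapply(paths, tiff::readTIFF)
  dims <- lapply(slices, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("loadStack: slices have mismatched shapes")
  d <- dims[[1]]
  nch <- if (length(d) == 3L) d[3] else 1L
  if (!(nch %in% c(1L, 3L))) stop("loadStack: slices must have 1 or 3 channels")
  nz <- length(paths)
  ## readTIFF returns row-major (y, x[, ch]); transpose to (x, y)
  nx <- d[2]; ny <- d[1]
  if (nch == 1L) {
    vox <- array(0, dim = c(nx, ny, nz))
    for (k in seq_len(nz)) vox[, , k] <- t(slices[[k]]) * 255
  } else {
    vox <- array(0, dim = c(nx, ny, nz, 3L))
    for (k in seq_len(nz))
      for (c in 1:3) vox[, , k, c] <- t(slices[[k]][, , c]) * 255
  }
  Volume3D(vox, spacing)
}

#' Write a Volume3D or LabelVolume as a per-slice TIFF stack
#'
#' @param x a Volume3D (written 8-bit) or LabelVolume (written 16-bit).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the written paths.
#' @export
writeStack <- function(x, dir, prefix = "slice") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- gridDim(x)
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    paths[k] <- file.path(dir, sprintf("%s_%04d.tif", prefix, k))
    if (is(x, "LabelVolume")) {
      sl <- t(x@labels[, , k]) / 65535
      tiff::writeTIFF(sl, paths[k], bits.per.sample = 16L)
    } else {
      v <- x@voxels
      if (length(dim(v)) == 4L) {
        sl <- aperm(v[, , k, , drop = TRUE], c(2, 1, 3)) / 255
      } else {
        sl <- t(v[, , k]) / 255
      }
      tiff::writeTIFF(pmin(pmax(sl, 0), 1), paths[k], bits.per.sample = 8L)
    }
  }
  invisible(paths)
}

#' Calibrate intensities against a cryo-gel reference region
#'
#' Applies a per-channel linear gain so that the mean intensity over the
#' gel region matches the calibration standard: GF 5 for single-channel
#' volumes, R/G/B = 150/120/120 for color volumes. Output is clipped to
#' [0, 255]. Calibration is idempotent.
#'
#' @param volume a \linkS4class{Volume3D}.
#' @param gelRegion integer vector of linear voxel indices (single-channel
#'   grid) of a pure-gel region, or a logical 3D array.
#' @param standard target mean intensities; defaults to the cryo-gel
#'   standard for the channel count.
#' @return the calibrated \linkS4class{Volume3D}.
#' @export
calibrate <- function(volume, gelRegion, standard = NULL) {
  stopifnot(is(volume, "Volume3D"))
  if (is.array(gelRegion)) gelRegion <- which(gelRegion != 0)
  if (length(gelRegion) == 0L) stop("calibrate: empty gel region")
  d <- gridDim(volume)
  if (max(gelRegion) > prod(d) || min(gelRegion) < 1L)
    stop("calibrate: gel region outside the grid")
  nch <- nChannels(volume)
  if (is.null(standard)) standard <- if (nch == 3L) c(150, 120, 120) else 5
  v <- volume@voxels
  if (nch == 1L) {
    m <- mean(v[gelRegion])
    if (m == 0) stop("calibrate: gel mean is zero")
    v <- v * (standard[1] / m)
  } else {
    npx <- prod(d)
    for (c in 1:3) {
      ch <- v[, , , c]
      m <- mean(ch[gelRegion])
      if (m == 0) stop("calibrate: gel mean is zero in channel ", c)
      v[, , , c] <- ch * (standard[c] / m)
    }
    rm(npx)
  }
  v[v > 255] <- 255
  v[v < 0] <- 0
  Volume3D(v, volume@spacing, volume@origin)
}

#' Resample a volume onto a new spacing
#'
#' Output grid dimensions are \code{round(extent / targetSpacing)}. Linear
#' interpolation for intensities, nearest-neighbour for labels and masks.
#'
#' @param volume a \linkS4class{Volume3D} or \linkS4class{LabelVolume}.
#' @param targetSpacing numeric(3) in micrometres.
#' @param mode "linear" or "nearest".
#' @return resampled object of the same class.
#' @export
resampleVolume <- function(volume, targetSpacing, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  if (any(targetSpacing <= 0)) stop("resampleVolume: target spacing must be positive")
  sp <- voxelSpacing(volume)
  d <- gridDim(volume)
  extent <- d * sp
  outdim <- as.integer(round(extent / targetSpacing))
  if (any(outdim <= 0L)) stop("resampleVolume: zero-size output grid")
  ratio <- targetSpacing / sp
  nearest <- mode == "nearest"
  if (is(volume, "LabelVolume")) {
    lab <- .resample3_cpp(as.numeric(volume@labels), dim(volume@labels),
                          outdim, ratio, TRUE)
    out <- array(as.integer(round(lab)), dim = outdim)
    return(LabelVolume(out, targetSpacing, volume@origin, relabel = FALSE))
  }
  nch <- nChannels(volume)
  if (nch == 1L) {
    v <- .resample3_cpp(as.numeric(volume@voxels), d, outdim, ratio, nearest)
    out <- array(v, dim = outdim)
  } else {
    out <- array(0, dim = c(outdim, 3L))
    for (c in 1:3)
      out[, , , c] <- array(.resample3_cpp(as.numeric(volume@voxels[, , , c]), d,
                                           outdim, ratio, nearest), dim = outdim)
  }
  Volume3D(out, targetSpacing, volume@origin)
}

#' Plan overlapping slice chunks
#'
#' Decomposes \code{nSlices} z-slices into chunks of at most
#' \code{slicesPerChunk} slices with adjacent chunks overlapping by exactly
#' \code{overlapSlices}; the last chunk may be shorter. The plan is
#' deterministic and covers every slice.
#'
#' @param nSlices total slice count.
#' @param slicesPerChunk maximum slices per chunk.
#' @param overlapSlices overlap between neighbouring chunks;
#'   \code{slicesPerChunk > overlapSlices >= 0}.
#' @return a \linkS4class{ChunkPlan} with 0-based half-open ranges.
#' @export
planChunks <- function(nSlices, slicesPerChunk, overlapSlices = 12L) {
  if (nSlices <= 0) stop("planChunks: nSlices must be positive")
  if (overlapSlices < 0 || slicesPerChunk <= overlapSlices)
    stop("planChunks: need slicesPerChunk > overlapSlices >= 0")
  if (nSlices <= slicesPerChunk) {
    ranges <- matrix(c(0L, as.integer(nSlices)), nrow = 1)
  } else {
    stride <- slicesPerChunk - overlapSlices
    starts <- 0L
    while (tail(starts, 1) + slicesPerChunk < nSlices)
      starts <- c(starts, tail(starts, 1) + stride)
    ends <- pmin(starts + slicesPerChunk, nSlices)
    ranges <- cbind(as.integer(starts), as.integer(ends))
  }
  new("ChunkPlan", nChunks = nrow(ranges),
      slicesPerChunk = as.integer(slicesPerChunk),
      overlapSlices = as.integer(overlapSlices), ranges = ranges)
}

## ---- internal geometry helpers ----

## odd voxel extent nearest to size_um/spacing (ties round up), minimum 1
.oddExtent <- function(size_um, spacing) {
  v <- size_um / spacing
  lo <- 2 * floor((v - 1) / 2) + 1
  hi <- lo + 2
  ext <- ifelse(abs(v - lo) < abs(v - hi), lo, hi)
  as.integer(pmax(1, ext))
}

## offsets of an ellipsoidal ball with the given *radius* in um per axis
.ballOffsets <- function(radius_um, spacing) {
  r <- pmax(0L, as.integer(round(radius_um / spacing)))
  g <- expand.grid(x = -r[1]:r[1], y = -r[2]:r[2], z = -r[3]:r[3])
  rr <- pmax(r, 1L)  # axis with radius 0 contributes only offset 0
  keep <- (g$x / rr[1])^2 + (g$y / rr[2])^2 + (g$z / rr[3])^2 <= 1 + 1e-9
  keep <- keep & (abs(g$x) <= r[1]) & (abs(g$y) <= r[2]) & (abs(g$z) <= r[3])
  as.matrix(g[keep, , drop = FALSE])
}

## in-plane disk offsets (z untouched)
.diskOffsets <- function(radius_vox) {
  r <- as.integer(radius_vox)
  g <- expand.grid(x = -r:r, y = -r:r, z = 0L)
  keep <- g$x^2 + g$y^2 <= r^2 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

## box offsets for a rectangular structuring element given odd extents
.boxOffsets <- function(extents) {
  h <- (extents - 1L) %/% 2L
  as.matrix(expand.grid(x = -h[1]:h[1], y = -h[2]:h[2], z = -h[3]:h[3]))
}

## the 5-slice spheroidal seed element: per-slice disks at dz = -2..2
.spheroidOffsets <- function(radii) {
  n <- length(radii)
  h <- (n - 1L) %/% 2L
  out <- NULL
  for (i in seq_len(n)) {
    dz <- i - 1L - h
    d <- .diskOffsets(radii[i])
    d[, 3] <- dz
    out <- rbind(out, d)
  }
  out
}

.asMask <- function(x) {
  storage.mode(x) <- "integer"
  x
}

## Otsu threshold of a numeric vector (256-bin histogram); NA when degenerate
.otsuThreshold <- function(v, nbins = 256L) {
  rng <- range(v)
  if (!is.finite(rng[1]) || rng[1] == rng[2]) return(NA_real_)
  h <- tabulate(pmin(nbins, 1L + floor((v - rng[1]) / (rng[2] - rng[1]) * nbins)),
                nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(nbins) - 0.5) * (rng[2] - rng[1]) / nbins
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- -Inf
  k <- which.max(sb2)
  rng[1] + k * (rng[2] - rng[1]) / nbins
}

## Dice coefficient of two binary arrays
.dice <- function(a, b) {
  a <- a != 0; b <- b != 0
  2 * sum(a & b) / (sum(a) + sum(b))
}
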