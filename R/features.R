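#' Grayscale conversion of RGB intensities
#'
#' \code{Gray = 0.2126 R + 0.7152 G + 0.0722 B} (Rec. 709 luma weights).
#'
#' @param r,g,b numeric vectors or arrays of channel intensities in [0, 255].
#' @return grayscale intensities.
#' @export
rgbToGray <- function(r, g, b) 0.2126 * r + 0.7152 * g + 0.0722 * b

#' Extract the multi-scale two-channel patch set of a candidate
#'
#' Three crops centered at the candidate's center of mass with neighbourhood
#' sizes 100x100x12, 200x200x24 and 400x400x48 voxels (resolutions
#' 10x10x50, 20x20x100 and 40x40x200 um); the larger two are block-averaged
#' down by 2x and 4x per axis so every patch is 100 x 100 x 12. Channels are
#' (GF, grayscale anatomy), divided by 255; voxels outside the volume are 0.
#'
#' @param color RGB \linkS4class{Volume3D} (full resolution); alternatively a
#'   precomputed grayscale 3D array via \code{gray=}.
#' @param gf GF \linkS4class{Volume3D} on the same grid.
#' @param centroidVox integer(3), 0-based voxel coordinates of the center.
#' @param gray optional precomputed grayscale array (overrides \code{color}).
#' @return a \linkS4class{PatchSet}.
#' @export
extractPatchSet <- function(color, gf, centroidVox, gray = NULL) {
  stopifnot(is(gf, "Volume3D"))
  d <- gridDim(gf)
  if (is.null(gray)) {
    stopifnot(is(color, "Volume3D"), nChannels(color) == 3L)
    gray <- rgbToGray(color@voxels[, , , 1], color@voxels[, , , 2],
                      color@voxels[, , , 3])
  }
  ctr <- as.integer(round(centroidVox))
  outdim <- c(100L, 100L, 12L)
  patches <- vector("list", 3L)
  for (s in 1:3) {
    blk <- as.integer(rep(2^(s - 1), 3))
    pg <- .blockcrop_cpp(as.numeric(gf@voxels), d, ctr, blk, outdim)
    pa <- .blockcrop_cpp(as.numeric(gray), d, ctr, blk, outdim)
    p <- array(0, c(outdim, 2L))
    p[, , , 1] <- array(pg, outdim) / 255
    p[, , , 2] <- array(pa, outdim) / 255
    p[p < 0] <- 0; p[p > 1] <- 1
    patches[[s]] <- p
  }
  new("PatchSet", patches = patches)
}

#' Mean GF intensity per voxel
#'
#' Ratio of a candidate's mean GF intensity to its volume in voxels; couples
#' brightness and size (big metastases are brighter than small ones).
#'
#' @param meanGf mean GF intensity over the candidate voxels.
#' @param volumeVoxels candidate volume in voxels (> 0).
#' @return the ratio.
#' @export
meanGfPerVoxel <- function(meanGf, volumeVoxels) {
  if (volumeVoxels <= 0) stop("meanGfPerVoxel: volume must be positive")
  meanGf / volumeVoxels
}

## number of grid points inside the 2D convex hull of integer points
.hullFillCount <- function(x, y) {
  n <- length(x)
  if (n <= 2L) return(n)
  pts <- unique(cbind(x, y))
  if (nrow(pts) <= 2L) return(nrow(pts))
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hx <- pts[h, 1]; hy <- pts[h, 2]
  if (length(h) <= 2L) return(nrow(pts))
  cnt <- 0L
  for (yy in min(y):max(y)) {
    ## x-intersections of the hull polygon with row yy
    xs <- c()
    m <- length(hx)
    for (e in seq_len(m)) {
      x1 <- hx[e]; y1 <- hy[e]
      x2 <- hx[e %% m + 1]; y2 <- hy[e %% m + 1]
      if (y1 == y2) {
        if (y1 == yy) xs <- c(xs, x1, x2)
      } else if ((y1 <= yy && yy <= y2) || (y2 <= yy && yy <= y1)) {
        xs <- c(xs, x1 + (yy - y1) * (x2 - x1) / (y2 - y1))
      }
    }
    if (length(xs))
      cnt <- cnt + max(0L, floor(max(xs) + 1e-9) - ceiling(min(xs) - 1e-9) + 1L)
  }
  cnt
}

#' Hand-crafted candidate features
#'
#' The 29 features: normalized (x, y, z) centroid location (3); min, max,
#' mean and standard deviation of the color red, color green and GF
#' intensities over the candidate voxels (12); morphology -- volume,
#' three principal-axis lengths, surface area, three Euler orientation
#' angles (ZYX, radians), extent, solidity, equivalent diameter,
#' bounding-box volume and longest/shortest axis ratio (13); and mean GF
#' per voxel (1). Principal axes come from the eigendecomposition of the
#' physical-coordinate covariance (axis length 2*sqrt(5*lambda), the
#' ellipsoid convention); surface area is face counting scaled by physical
#' face areas; solidity uses per-slice 2D convex hulls.
#'
#' @param voxelIdx integer vector of linear voxel indices of the candidate.
#' @param color RGB \linkS4class{Volume3D}.
#' @param gf GF \linkS4class{Volume3D}.
#' @param mouseDims grid dimensions used for location normalization
#'   (defaults to the GF grid).
#' @return named numeric vector of length 29.
#' @export
handcraftedFeatures <- function(voxelIdx, color, gf, mouseDims = gridDim(gf)) {
  stopifnot(length(voxelIdx) > 0L)
  d <- gridDim(gf)
  sp <- voxelSpacing(gf)
  ai <- arrayInd(voxelIdx, d)
  n <- nrow(ai)
  ## location (normalized voxel-center coordinates)
  loc <- colMeans(ai - 0.5) / mouseDims
  ## intensity stats: color red, color green, GF
  rv <- color@voxels[, , , 1][voxelIdx]
  gv <- color@voxels[, , , 2][voxelIdx]
  fv <- gf@voxels[voxelIdx]
  istat <- function(v) c(min = min(v), max = max(v), mean = mean(v),
                         sd = if (length(v) > 1) sd(v) else 0)
  ## morphology in physical units
  phys <- sweep(ai - 0.5, 2, sp, "*")
  voxvol <- prod(sp)
  volume <- n * voxvol
  if (n > 1) {
    cv <- stats::cov(phys) * (n - 1) / n
    eg <- eigen(cv, symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    axes <- 2 * sqrt(5 * pmax(lam, (min(sp) / 4)^2 / 5))
    V <- eg$vectors
    ## deterministic sign: first nonzero component of each axis positive
    for (j in 1:3) {
      nz <- which(abs(V[, j]) > 1e-12)[1]
      if (!is.na(nz) && V[nz, j] < 0) V[, j] <- -V[, j]
    }
    if (det(V) < 0) V[, 3] <- -V[, 3]
    ## ZYX Euler angles of the rotation taking the grid axes to the PA frame
    eul <- c(atan2(V[2, 1], V[1, 1]),
             atan2(-V[3, 1], sqrt(V[3, 2]^2 + V[3, 3]^2)),
             atan2(V[3, 2], V[3, 3]))
  } else {
    axes <- sort(sp, decreasing = TRUE)  # single voxel: its physical extents
    eul <- c(0, 0, 0)
  }
  ## surface area by face counting
  sub <- sweep(ai, 2, apply(ai, 2, min) - 2L)  # 1-voxel pad on each side
  bd <- apply(sub, 2, max) + 1L
  m <- array(FALSE, bd)
  m[sub] <- TRUE
  faceArea <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  surf <- 0
  for (s in seq_along(shifts)) {
    sh <- shifts[[s]]
    nb <- m[cbind(sub[, 1] + sh[1], sub[, 2] + sh[2], sub[, 3] + sh[3])]
    surf <- surf + sum(!nb) * faceArea[ceiling(s / 2)]
  }
  bbox <- apply(ai, 2, max) - apply(ai, 2, min) + 1L
  extent <- n / prod(bbox)
  ## solidity via per-slice 2D convex hulls
  hull_n <- sum(vapply(split(seq_len(n), ai[, 3]), function(ii)
    .hullFillCount(ai[ii, 1], ai[ii, 2]), 0))
  solidity <- min(1, n / max(hull_n, n))
  eqdiam <- 2 * (3 * volume / (4 * pi))^(1 / 3)
  c(loc_x = unname(loc[1]), loc_y = unname(loc[2]), loc_z = unname(loc[3]),
    setNames(istat(rv), paste0("red_", c("min", "max", "mean", "sd"))),
    setNames(istat(gv), paste0("green_", c("min", "max", "mean", "sd"))),
    setNames(istat(fv), paste0("gf_", c("min", "max", "mean", "sd"))),
    volume_um3 = volume,
    pa1_um = axes[1], pa2_um = axes[2], pa3_um = axes[3],
    surface_um2 = surf,
    euler_z = eul[1], euler_y = eul[2], euler_x = eul[3],
    extent = extent, solidity = solidity,
    eq_diameter_um = eqdiam,
    bbox_volume_um3 = prod(bbox * sp),
    axis_ratio = axes[1] / max(axes[3], 1e-9),
    mean_gf_per_voxel = meanGfPerVoxel(mean(fv), n))
}

#' Feature matrix for a set of candidates
#'
#' @param candidates candidate table from \code{\link{candidateTable}}.
#' @param color,gf full-resolution volumes.
#' @return numeric matrix, one row per candidate, 29 named columns.
#' @export
candidateFeatureMatrix <- function(candidates, color, gf) {
  vs <- attr(candidates, "voxelSets")
  out <- t(vapply(seq_len(nrow(candidates)), function(i)
    handcraftedFeatures(vs[[i]], color, gf), numeric(29)))
  rownames(out) <- candidates$id
  out
}
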