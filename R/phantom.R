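#' Construct a PhantomSpec
#'
#' All arguments default to the prototype values documented in
#' \linkS4class{PhantomSpec}; any slot can be overridden by name.
#'
#' @param ... named slot overrides (e.g. \code{nMetastases = 20}, \code{seed = 7}).
#' @return a validated \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(...) {
  args <- list(...)
  spec <- new("PhantomSpec")
  for (nm in names(args)) {
    val <- args[[nm]]
    if (is(slot(spec, nm), "integer")) val <- as.integer(val)
    slot(spec, nm) <- val
  }
  validObject(spec)
  spec
}

## squared normalized ellipsoid coordinate field for the grid (voxel centers)
.ellipsoidField <- function(gridDim, spacing, center_um, semi_um) {
  fx <- (((seq_len(gridDim[1]) - 0.5) * spacing[1] - center_um[1]) / semi_um[1])^2
  fy <- (((seq_len(gridDim[2]) - 0.5) * spacing[2] - center_um[2]) / semi_um[2])^2
  fz <- (((seq_len(gridDim[3]) - 0.5) * spacing[3] - center_um[3]) / semi_um[3])^2
  outer(outer(fx, fy, "+"), fz, "+")
}

## Radial intensity profile of a fluorescent cell mass of nominal radius r:
## uniform core to 0.9 r, smooth cosine^2 taper to zero at the truncation
## radius 1.25 r (half maximum near 1.07 r). A soft-core Gaussian profile
## would put the half-maximum far inside the nominal radius, so the printed
## minimum-volume filter (4e6 um^3, effective radius ~98 um) would remove
## metastases well above 100 um nominal radius.
.blobProfile <- function(rho, r) {
  w <- numeric(length(rho))
  core <- rho <= 0.9 * r
  taper <- rho > 0.9 * r & rho <= 1.25 * r
  w[core] <- 1
  w[taper] <- cos((pi / 2) * (rho[taper] - 0.9 * r) / (0.35 * r))^2
  w
}

## add a plateau blob (physical units) of nominal radius `radius_um` to
## `vol`; returns the modified volume and the truth voxel index set
.addBlob <- function(vol, gridDim, spacing, center_um, radius_um, amplitude) {
  rmax <- 1.25 * radius_um
  lo <- pmax(1L, as.integer(floor((center_um - rmax) / spacing + 0.5)))
  hi <- pmin(gridDim, as.integer(ceiling((center_um + rmax) / spacing + 0.5)))
  xs <- (lo[1]:hi[1] - 0.5) * spacing[1] - center_um[1]
  ys <- (lo[2]:hi[2] - 0.5) * spacing[2] - center_um[2]
  zs <- (lo[3]:hi[3] - 0.5) * spacing[3] - center_um[3]
  r2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  inside <- r2 <= rmax^2
  add <- amplitude * array(.blobProfile(sqrt(r2), radius_um), dim(r2))
  vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + add
  idx <- array(FALSE, gridDim)
  idx[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- inside
  list(vol = vol, idx = which(idx))
}

#' Generate a synthetic whole-mouse cryo-image phantom
#'
#' Builds co-registered color (RGB) and green-fluorescence (GF) volumes with
#' known metastasis truth labels and organ masks. The gel fills the exterior
#' at the calibration standard; a thin skin/fur shell with mildly elevated
#' auto-fluorescence wraps the body ellipsoid; metastases are isotropic
#' plateau blobs (uniform core, smooth taper to zero at 1.25 times the
#' nominal radius) whose radii are drawn log-uniformly; metastases larger than
#' \code{whiteRadiusUm} also get the white color signature of large tumors.
#' Confounders emulate common auto-fluorescent false-positive sources: a
#' bile-duct-like tube, white bone plates and GI speckles. Identical
#' spec and seed give bit-identical output.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with elements \code{color}, \code{gf} (Volume3D),
#'   \code{truth} (LabelVolume), \code{organMasks} (named list of binary
#'   arrays: lung, liver, brain), \code{bodyTruth} (binary array),
#'   \code{gelTruth} (binary array), and \code{mets} (data.frame of drawn
#'   centers, nominal radii and GF peaks).
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  stopifnot(is(spec, "PhantomSpec"))
  set.seed(spec@seed)
  gd <- spec@gridDim; sp <- spec@spacing
  extent <- gd * sp
  center <- extent / 2
  semi <- spec@bodySemiAxesUm
  body_f <- .ellipsoidField(gd, sp, center, semi)
  skin_f <- .ellipsoidField(gd, sp, center, semi + spec@skinThicknessUm)
  body <- body_f <= 1
  skin <- (skin_f <= 1) & !body
  gel <- skin_f > 1

  gf <- array(spec@bodyGf, gd)
  gf[skin] <- spec@skinGf
  gf[gel] <- spec@gelGf
  col <- array(0, c(gd, 3L))
  for (c in 1:3) {
    ch <- array(spec@bodyRgb[c], gd)
    ch[skin] <- spec@skinRgb[c]
    ch[gel] <- spec@gelRgb[c]
    col[, , , c] <- ch
  }

  ## organ masks: three disjoint ellipsoids inside the body
  organs <- list(
    lung  = .ellipsoidField(gd, sp, center + c(0, 0, 0.45) * semi,
                            c(0.45, 0.45, 0.22) * semi) <= 1,
    liver = .ellipsoidField(gd, sp, center + c(0, 0, -0.05) * semi,
                            c(0.5, 0.5, 0.2) * semi) <= 1,
    brain = .ellipsoidField(gd, sp, center + c(0, 0, 0.82) * semi,
                            c(0.3, 0.3, 0.1) * semi) <= 1)

  ## confounders (auto-fluorescent structures); geometry is recorded so
  ## metastasis placement can stay disjoint from them
  tube_axis <- NULL; tube_r <- 100
  if ("bileduct" %in% spec@confounders) {
    ## tube along z through the liver region with slight in-plane drift
    zr <- seq(center[3] - 0.55 * semi[3], center[3] + 0.15 * semi[3], by = sp[3])
    for (zu in zr) {
      k <- as.integer(round(zu / sp[3] + 0.5))
      if (k < 1 || k > gd[3]) next
      cx <- center[1] + 0.25 * semi[1] + 150 * sin(zu / 900)
      cy <- center[2] - 0.15 * semi[2]
      xs <- (seq_len(gd[1]) - 0.5) * sp[1] - cx
      ys <- (seq_len(gd[2]) - 0.5) * sp[2] - cy
      d2 <- outer(xs^2, ys^2, "+")
      prof <- 50 * exp(-d2 / (2 * (tube_r / 2)^2)) * (d2 <= (2.5 * tube_r / 2)^2)
      gf[, , k] <- gf[, , k] + prof
      tube_axis <- rbind(tube_axis, c(cx, cy, zu))
    }
  }
  plates <- list()
  if ("bone" %in% spec@confounders) {
    ## two thin white plates (spine-like), bright in all color channels
    for (s in c(-1, 1)) {
      pc <- center + s * c(0.45, 0.35, 0) * semi
      half <- c(260, 70, 0.55 * semi[3])
      px <- abs((seq_len(gd[1]) - 0.5) * sp[1] - pc[1]) <= half[1]
      py <- abs((seq_len(gd[2]) - 0.5) * sp[2] - pc[2]) <= half[2]
      pz <- abs((seq_len(gd[3]) - 0.5) * sp[3] - center[3]) <= half[3]
      plate <- outer(outer(px, py, "&"), pz, "&") & body
      gf[plate] <- gf[plate] + 30
      for (c in 1:3) {
        ch <- col[, , , c]
        ch[plate] <- c(220, 215, 210)[c]
        col[, , , c] <- ch
      }
      plates[[length(plates) + 1L]] <- list(center = c(pc[1], pc[2], center[3]),
                                            half = half)
    }
  }
  gi_centers <- NULL; gi_radii <- numeric(0)
  if ("gi" %in% spec@confounders) {
    ## scattered food-remnant speckles in the lower body
    n_gi <- 10L
    for (i in seq_len(n_gi)) {
      repeat {
        u <- c(runif(1, -0.6, 0.6), runif(1, -0.6, 0.6), runif(1, -0.75, -0.35))
        cu <- center + u * semi
        if (sum(u^2) <= 0.7) break
      }
      r <- runif(1, 130, 190)
      b <- .addBlob(gf, gd, sp, cu, r, 50)
      gf <- b$vol
      gi_centers <- rbind(gi_centers, cu)
      gi_radii <- c(gi_radii, r)
    }
  }
  ## TRUE when a metastasis of truncation radius rt at `cu` would touch a
  ## confounder (candidate labels must stay class-unambiguous)
  .nearConfounder <- function(cu, rt) {
    margin <- rt + 250
    if (!is.null(tube_axis)) {
      dd <- sqrt((tube_axis[, 1] - cu[1])^2 + (tube_axis[, 2] - cu[2])^2)
      near_z <- abs(tube_axis[, 3] - cu[3]) <= margin + 1.25 * tube_r
      if (any(near_z & dd <= margin + 1.25 * tube_r)) return(TRUE)
    }
    for (p in plates) {
      if (all(abs(cu - p$center) <= p$half + margin)) return(TRUE)
    }
    if (!is.null(gi_centers)) {
      dd <- sqrt(colSums((t(gi_centers) - cu)^2))
      if (any(dd <= margin + 1.25 * gi_radii)) return(TRUE)
    }
    FALSE
  }

  ## metastases
  truth <- array(0L, gd)
  n <- spec@nMetastases
  mets <- data.frame(label = integer(0), x_um = numeric(0), y_um = numeric(0),
                     z_um = numeric(0), radius_um = numeric(0), peak = numeric(0))
  if (n > 0L) {
    placed <- matrix(numeric(0), ncol = 4)  # x, y, z, radius
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(200L)) {
        r <- exp(runif(1, log(spec@radiusRangeUm[1]), log(spec@radiusRangeUm[2])))
        rt <- 1.25 * r  # truncation radius (2.5 sigma with sigma = r/2)
        shrink <- semi - rt
        if (any(shrink <= 0)) next
        u <- runif(3, -1, 1)
        if (sum(u^2) > 1) next
        cu <- center + u * shrink
        if (.nearConfounder(cu, rt)) next
        ## keep truth blobs disjoint
        if (nrow(placed) > 0) {
          dd <- sqrt(colSums((t(placed[, 1:3, drop = FALSE]) - cu)^2))
          if (any(dd <= pmax(1.25 * (placed[, 4] + r), spec@minSeparationUm))) next
        }
        ok <- TRUE
        break
      }
      if (!ok) stop("generatePhantom: could not place metastasis ", i,
                    " inside the body (spec error)")
      peak <- runif(1, spec@gfPeakRange[1], spec@gfPeakRange[2])
      b <- .addBlob(gf, gd, sp, cu, r, peak)
      gf <- b$vol
      truth[b$idx] <- i
      if (r > spec@whiteRadiusUm) {
        ## white appearance of large metastases on the color image
        lo <- pmax(1L, as.integer(floor((cu - 1.25 * r) / sp + 0.5)))
        hi <- pmin(gd, as.integer(ceiling((cu + 1.25 * r) / sp + 0.5)))
        xs <- (lo[1]:hi[1] - 0.5) * sp[1] - cu[1]
        ys <- (lo[2]:hi[2] - 0.5) * sp[2] - cu[2]
        zs <- (lo[3]:hi[3] - 0.5) * sp[3] - cu[3]
        r2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
        w <- array(.blobProfile(sqrt(r2), r), dim(r2))
        for (c in 1:3) {
          blk <- col[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], c]
          col[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], c] <- blk + (235 - blk) * w
        }
      }
      placed <- rbind(placed, c(cu, r))
      mets <- rbind(mets, data.frame(label = i, x_um = cu[1], y_um = cu[2],
                                     z_um = cu[3], radius_um = r, peak = peak))
    }
  }

  ## additive Gaussian noise, clipped to the 8-bit range
  if (spec@noiseSigma > 0) {
    gf <- gf + array(rnorm(prod(gd), 0, spec@noiseSigma), gd)
    col <- col + array(rnorm(prod(gd) * 3, 0, spec@noiseSigma), c(gd, 3L))
  }
  gf <- pmin(pmax(gf, 0), 255)
  col[col < 0] <- 0
  col[col > 255] <- 255

  list(color = Volume3D(col, sp), gf = Volume3D(array(gf, gd), sp),
       truth = LabelVolume(truth, sp, relabel = FALSE),
       organMasks = lapply(organs, function(m) .asMask(m * 1L)),
       bodyTruth = .asMask(body * 1L), gelTruth = .asMask(gel * 1L),
       mets = mets, spec = spec)
}

#' Per-metastasis truth table
#'
#' One row per nonzero truth label with centroid (micrometres), voxel count,
#' volume (voxel count times voxel volume) and effective sphere radius.
#'
#' @param truth a \linkS4class{LabelVolume}.
#' @param spacing optional spacing override (defaults to the truth spacing).
#' @return data.frame with columns label, x_um, y_um, z_um, voxels,
#'   volume_um3, radius_um.
#' @export
truthTable <- function(truth, spacing = voxelSpacing(truth)) {
  stopifnot(is(truth, "LabelVolume"))
  n <- truth@labelCount
  if (n == 0L)
    return(data.frame(label = integer(0), x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), voxels = numeric(0),
                      volume_um3 = numeric(0), radius_um = numeric(0)))
  st <- .label_stats_cpp(truth@labels, dim(truth@labels), n)
  vv <- prod(spacing)
  data.frame(label = seq_len(n),
             x_um = (st$cx + 0.5) * spacing[1],
             y_um = (st$cy + 0.5) * spacing[2],
             z_um = (st$cz + 0.5) * spacing[3],
             voxels = st$count,
             volume_um3 = st$count * vv,
             radius_um = effectiveRadius(st$count * vv))
}
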