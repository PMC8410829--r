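#' Effective sphere radius of a volume
#'
#' Radius of the sphere with the given volume: \code{(3V / 4 pi)^(1/3)}.
#' The 4e6 um^3 minimum-candidate volume corresponds to a radius of ~98 um.
#'
#' @param volumeUm3 volume(s) in cubic micrometres (> 0).
#' @return radius in micrometres (vectorized).
#' @export
effectiveRadius <- function(volumeUm3) {
  if (any(volumeUm3 <= 0)) stop("effectiveRadius: volume must be positive")
  (3 * volumeUm3 / (4 * pi))^(1 / 3)
}

#' Exponential growth model for the inferred cancer-cell population
#'
#' Assuming a fraction of each tumor is cancer cells (default 10 percent)
#' of diameter 15 um, the cell count is
#' \code{N = fraction * V_total / ((4/3) pi (d/2)^3)}; with \code{n0} cells
#' injected and exponential growth over \code{days}, the doubling time is
#' \code{days * ln 2 / ln(N / n0)}. For the largest observed total burden of
#' 352.25 mm^3 after 20 days this gives ~1.99e7 cells and ~2.62 days.
#'
#' @param totalVolumeMm3 total tumor volume in mm^3.
#' @param cellFraction cancer-cell volume fraction (0.1).
#' @param cellDiameterUm cancer-cell diameter in micrometres (15).
#' @param n0 injected cell count (1e5).
#' @param days elapsed days (20; the 2--3 week window midpoint).
#' @return list with \code{cellCount} and \code{doublingTimeDays}
#'   (NA when the population has not grown beyond \code{n0}).
#' @export
growthModel <- function(totalVolumeMm3, cellFraction = 0.1, cellDiameterUm = 15,
                        n0 = 1e5, days = 20) {
  stopifnot(totalVolumeMm3 > 0, cellFraction > 0, cellDiameterUm > 0,
            n0 > 0, days > 0)
  cellVol <- (4 / 3) * pi * (cellDiameterUm / 2)^3      # um^3
  N <- cellFraction * totalVolumeMm3 * 1e9 / cellVol
  td <- if (N > n0) days * log(2) / log(N / n0) else NA_real_
  list(cellCount = N, doublingTimeDays = td, days = days)
}

#' Tumor-burden report
#'
#' Assigns each metastasis to the organ containing its centroid (mask
#' priority order; otherwise "rest of body"), tabulates per-organ counts and
#' radius histograms (0.5 mm bins), sums the total volume, and appends the
#' growth-model outputs.
#'
#' @param finalLabels the corrected metastasis \linkS4class{LabelVolume}.
#' @param organMasks named list of binary 3D arrays on the same grid
#'   (priority order); may be empty.
#' @param growthParams list of overrides for \code{\link{growthModel}}.
#' @param binWidthMm radius histogram bin width (0.5).
#' @return a \linkS4class{BurdenReport}.
#' @export
burdenReport <- function(finalLabels, organMasks = list(), growthParams = list(),
                         binWidthMm = 0.5) {
  stopifnot(is(finalLabels, "LabelVolume"))
  tab <- truthTable(finalLabels)
  d <- gridDim(finalLabels)
  sp <- voxelSpacing(finalLabels)
  organs <- c(names(organMasks), "rest of body")
  if (length(organMasks)) {
    ## warn on overlapping organ masks (assignment uses priority order)
    tot <- Reduce(`+`, organMasks)
    if (max(tot) > 1L)
      warning("burdenReport: overlapping organ masks; assigning by priority order")
  }
  assign_organ <- function(x, y, z) {
    vox <- pmin(pmax(round(c(x, y, z) / sp + 0.5), 1), d)
    for (nm in names(organMasks)) {
      if (organMasks[[nm]][vox[1], vox[2], vox[3]] > 0L) return(nm)
    }
    "rest of body"
  }
  organ <- character(nrow(tab))
  for (i in seq_len(nrow(tab)))
    organ[i] <- assign_organ(tab$x_um[i], tab$y_um[i], tab$z_um[i])
  tab$organ <- factor(organ, levels = organs)
  tab$radius_mm <- tab$radius_um / 1000
  counts <- table(tab$organ)
  maxr <- if (nrow(tab)) max(tab$radius_mm) else 0
  breaks <- seq(0, binWidthMm * ceiling(maxr / binWidthMm + 1e-9) + binWidthMm,
                by = binWidthMm)
  hist_by_organ <- lapply(setNames(organs, organs), function(o) {
    r <- tab$radius_mm[tab$organ == o]
    counts <- if (length(r)) hist(r, breaks = breaks, plot = FALSE)$counts
              else integer(length(breaks) - 1L)
    data.frame(lower_mm = head(breaks, -1), upper_mm = tail(breaks, -1),
               count = counts)
  })
  totalVol <- sum(tab$volume_um3) * 1e-9
  growth <- if (totalVol > 0) {
    do.call(growthModel, c(list(totalVolumeMm3 = totalVol), growthParams))
  } else list(cellCount = NA_real_, doublingTimeDays = NA_real_, days = NA_real_)
  new("BurdenReport", perMet = tab,
      organCounts = setNames(as.integer(counts), names(counts)),
      radiusHist = hist_by_organ, totalVolumeMm3 = totalVol, growth = growth)
}
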