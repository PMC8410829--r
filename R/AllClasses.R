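#' @import methods
#' @importFrom stats rnorm runif sd quantile setNames predict cov
#' @importFrom graphics hist
#' @importFrom utils head tail
#' @useDynLib CryoMetSeg, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Volume3D: a scalar or RGB voxel grid with physical spacing
#'
#' Container for cryo-image volumes. The voxel array has dims
#' \code{(nx, ny, nz)} for single-channel (green fluorescence, GF, or
#' grayscale) data or \code{(nx, ny, nz, 3)} for RGB color anatomy. Axis
#' order is (x, y, z) with z the section axis; spacing is in micrometres.
#' Intensities are on the 8-bit 0--255 scale, stored as doubles so that
#' calibration and filtering do not quantize.
#'
#' @slot voxels numeric array of intensities.
#' @slot spacing numeric(3), voxel spacing (sx, sy, sz) in micrometres.
#' @slot origin numeric(3), physical offset of the grid in micrometres.
#' @export
setClass("Volume3D", representation(voxels = "array", spacing = "numeric",
                                    origin = "numeric"))

setValidity("Volume3D", function(object) {
  d <- dim(object@voxels)
  if (!(length(d) %in% c(3L, 4L))) return("voxels must be a 3D or 4D (RGB) array")
  if (length(d) == 4L && d[4] != 3L) return("4D voxel arrays must have 3 channels")
  if (any(d[1:3] <= 0L)) return("grid dimensions must be positive")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three strictly positive values")
  if (length(object@origin) != 3L) return("origin must have length 3")
  TRUE
})

#' LabelVolume: integer-labeled connected components on a voxel grid
#'
#' Labels are consecutive nonnegative integers with 0 meaning background;
#' shares grid geometry with its source \linkS4class{Volume3D}.
#'
#' @slot labels integer array (nx, ny, nz).
#' @slot spacing numeric(3) in micrometres.
#' @slot origin numeric(3) in micrometres.
#' @slot labelCount number of distinct nonzero labels.
#' @export
setClass("LabelVolume", representation(labels = "array", spacing = "numeric",
                                       origin = "numeric", labelCount = "integer"))

setValidity("LabelVolume", function(object) {
  if (length(dim(object@labels)) != 3L) return("labels must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three strictly positive values")
  if (object@labelCount < 0L) return("labelCount must be nonnegative")
  TRUE
})

#' BodyMask: binary mouse-body mask on the down-sampled grid
#'
#' 1 = mouse body, 0 = immaterial (cryo-gel, skin, fur, outside).
#'
#' @slot mask integer array with values in {0, 1}.
#' @slot spacing numeric(3) in micrometres.
#' @export
setClass("BodyMask", representation(mask = "array", spacing = "numeric"))

setValidity("BodyMask", function(object) {
  if (length(dim(object@mask)) != 3L) return("mask must be a 3D array")
  if (!all(object@mask %in% c(0L, 1L))) return("mask values must be 0 or 1")
  TRUE
})

#' ChunkPlan: slice-range decomposition of a volume for chunked processing
#'
#' Half-open 0-based slice ranges whose union covers all slices, with
#' adjacent ranges overlapping by exactly \code{overlapSlices}.
#'
#' @slot nChunks number of chunks.
#' @slot slicesPerChunk maximum slices per chunk.
#' @slot overlapSlices overlap between neighbouring chunks.
#' @slot ranges integer matrix (nChunks x 2) of half-open [start, end) ranges.
#' @export
setClass("ChunkPlan", representation(nChunks = "integer", slicesPerChunk = "integer",
                                     overlapSlices = "integer", ranges = "matrix"))

#' WatershedParams: parameters of the big-metastases candidate stage
#'
#' Defaults follow the breast-cancer model; \code{gfThreshold} has a
#' pancreatic override of 60.
#'
#' @slot gaussianSigmaUm Gaussian smoothing sigma in micrometres (160).
#' @slot gfThreshold GF intensity threshold applied after smoothing (20).
#' @slot holefillDiameterUm ball diameter for morphological hole filling (400).
#' @slot minMarkerVolumeMm3 minimum connected-component volume in mm^3 (0.8).
#' @slot erosionDiameterUm ball diameter for marker erosion (120).
#' @slot connectivity neighbourhood connectivity (26).
#' @slot mergeDilationUm fragment merge dilation radius in micrometres (120).
#' @slot bodyFractionLimit fragments above this fraction of the body are
#'   background (0.10).
#' @export
setClass("WatershedParams", representation(
  gaussianSigmaUm = "numeric", gfThreshold = "numeric", holefillDiameterUm = "numeric",
  minMarkerVolumeMm3 = "numeric", erosionDiameterUm = "numeric", connectivity = "integer",
  mergeDilationUm = "numeric", bodyFractionLimit = "numeric"),
  prototype(gaussianSigmaUm = 160, gfThreshold = 20, holefillDiameterUm = 400,
            minMarkerVolumeMm3 = 0.8, erosionDiameterUm = 120, connectivity = 26L,
            mergeDilationUm = 120, bodyFractionLimit = 0.10))

setValidity("WatershedParams", function(object) {
  if (any(c(object@gaussianSigmaUm, object@holefillDiameterUm, object@minMarkerVolumeMm3,
            object@erosionDiameterUm, object@mergeDilationUm) <= 0))
    return("all lengths and volumes must be positive")
  if (object@bodyFractionLimit <= 0 || object@bodyFractionLimit >= 1)
    return("bodyFractionLimit must be in (0, 1)")
  TRUE
})

#' SmallParams: parameters of the small-metastases candidate stage
#'
#' @slot logSigmas LoG scales in in-plane voxels, ascending (2,4,6,8,10).
#' @slot seedThreshold seed threshold T1 on the maximal scale-normalized LoG
#'   response (10 for the breast model; 8 for the pancreatic model).
#' @slot seedDilationRadii per-slice disk radii (voxels) of the 5-slice
#'   spheroidal seed dilation element (3,7,12,7,3).
#' @slot closingSizeUm closing element size (x, y, z) in micrometres
#'   (40, 40, 200).
#' @slot minVolumeUm3 minimum candidate volume in cubic micrometres (4e6).
#' @export
setClass("SmallParams", representation(
  logSigmas = "numeric", seedThreshold = "numeric", seedDilationRadii = "numeric",
  closingSizeUm = "numeric", minVolumeUm3 = "numeric"),
  prototype(logSigmas = c(2, 4, 6, 8, 10), seedThreshold = 10.0,
            seedDilationRadii = c(3, 7, 12, 7, 3), closingSizeUm = c(40, 40, 200),
            minVolumeUm3 = 4e6))

setValidity("SmallParams", function(object) {
  if (any(object@logSigmas <= 0) || is.unsorted(object@logSigmas, strictly = TRUE))
    return("logSigmas must be positive and strictly ascending")
  if (object@seedThreshold <= 0) return("seedThreshold must be positive")
  if (object@minVolumeUm3 <= 0) return("minVolumeUm3 must be positive")
  if (length(object@seedDilationRadii) %% 2 != 1)
    return("seedDilationRadii must have odd length (centered element)")
  TRUE
})

#' PhantomSpec: specification of the synthetic whole-mouse phantom
#'
#' The phantom emulates calibrated cryo-image data: an ivory cryo-gel
#' background at the calibration standard (GF 5, RGB 150/120/120), a mouse
#' body ellipsoid wrapped in a thin skin/fur shell, bright metastasis blobs
#' with known truth labels, auto-fluorescent confounders (bile-duct-like
#' tube, white bone plates, GI speckles) and additive Gaussian noise.
#'
#' @slot gridDim integer(3) voxel grid, default 256 x 256 x 120.
#' @slot spacing numeric(3) micrometres, default (10.472, 10.472, 50).
#' @slot bodySemiAxesUm body ellipsoid semi-axes in micrometres.
#' @slot skinThicknessUm skin/fur shell thickness (80).
#' @slot gelGf,gelRgb gel calibration intensities (5; 150/120/120).
#' @slot bodyRgb,bodyGf interior tissue color and GF baseline.
#' @slot skinRgb,skinGf skin shell color and GF.
#' @slot nMetastases number of metastases (12).
#' @slot radiusRangeUm log-uniform radius range in micrometres (50, 1500).
#' @slot minSeparationUm extra minimum center-to-center distance between
#'   metastases (0 = only the truth-disjointness rule).
#' @slot gfPeakRange metastasis GF peak amplitude range (120, 220).
#' @slot whiteRadiusUm metastases larger than this get the white color
#'   signature (500).
#' @slot confounders character vector among "bileduct", "bone", "gi".
#' @slot noiseSigma additive Gaussian noise sigma in intensity units (2).
#' @slot seed integer seed fixing all randomness.
#' @export
setClass("PhantomSpec", representation(
  gridDim = "integer", spacing = "numeric", bodySemiAxesUm = "numeric",
  skinThicknessUm = "numeric", gelGf = "numeric", gelRgb = "numeric",
  bodyRgb = "numeric", bodyGf = "numeric", skinRgb = "numeric", skinGf = "numeric",
  nMetastases = "integer", radiusRangeUm = "numeric",
  minSeparationUm = "numeric", gfPeakRange = "numeric",
  whiteRadiusUm = "numeric", confounders = "character", noiseSigma = "numeric",
  seed = "integer"),
  prototype(gridDim = c(256L, 256L, 120L), spacing = c(10.472, 10.472, 50),
            bodySemiAxesUm = c(1200, 1200, 2700), skinThicknessUm = 80,
            gelGf = 5, gelRgb = c(150, 120, 120), bodyRgb = c(135, 80, 95),
            bodyGf = 6, skinRgb = c(140, 105, 100), skinGf = 15,
            nMetastases = 12L, radiusRangeUm = c(50, 1500),
            minSeparationUm = 0,
            gfPeakRange = c(120, 220), whiteRadiusUm = 500,
            confounders = c("bileduct", "bone", "gi"), noiseSigma = 2,
            seed = 1L))

setValidity("PhantomSpec", function(object) {
  ints <- c(object@gelGf, object@gelRgb, object@bodyRgb, object@bodyGf,
            object@skinRgb, object@skinGf, object@gfPeakRange)
  if (any(ints < 0) || any(ints > 255)) return("intensity parameters must be in [0, 255]")
  if (any(object@radiusRangeUm <= 0)) return("radii must be positive")
  if (object@nMetastases < 0L) return("nMetastases must be nonnegative")
  if (any(object@spacing <= 0)) return("spacing must be positive")
  TRUE
})

#' CnnArchitecture: layer specification of the per-scale 3D CNN
#'
#' A valid architecture takes a 100 x 100 x 12 x 2 input, has a 256-wide
#' penultimate (feature) dense layer, a 2-class softmax output, and a
#' theoretical receptive field of 64 x 64 x 48 voxels.
#'
#' @slot layers list of layer descriptors (type "conv" with kernel/out,
#'   "pool" with size, "gap", "dense" with out).
#' @slot inputDim integer(4), (100, 100, 12, 2).
#' @slot featureWidth penultimate feature width (256).
#' @export
setClass("CnnArchitecture", representation(layers = "list", inputDim = "integer",
                                           featureWidth = "integer"))

#' TrainingConfig: CNN training configuration
#'
#' Defaults are the optimized settings for the full-scale data: batch size 8,
#' learning rate 1e-5, positive class weight 20 (searched over 5--30 step 5),
#' at most 100 epochs with early stopping after 10 epochs without
#' improvement of the validation loss; 2D augmentation ranges zoom 0.9--1.1,
#' rotation -90..90 degrees, flips, brightness 0.8--1.2; batch-level positive
#' oversampling to at least 25 percent.
#'
#' @slot batchSize,learningRate,posWeight,maxEpochs,patience scalars.
#' @slot zoomRange,rotationRange,brightnessRange augmentation ranges.
#' @slot flips logical, enable horizontal/vertical flips.
#' @slot oversample logical, batch-level positive oversampling.
#' @slot minPosFraction minimum positive fraction per batch (0.25).
#' @slot seed integer seed.
#' @export
setClass("TrainingConfig", representation(
  batchSize = "integer", learningRate = "numeric", posWeight = "numeric",
  maxEpochs = "integer", patience = "integer", zoomRange = "numeric",
  rotationRange = "numeric", brightnessRange = "numeric", flips = "logical",
  oversample = "logical", minPosFraction = "numeric", seed = "integer"),
  prototype(batchSize = 8L, learningRate = 1e-5, posWeight = 20,
            maxEpochs = 100L, patience = 10L, zoomRange = c(0.9, 1.1),
            rotationRange = c(-90, 90), brightnessRange = c(0.8, 1.2),
            flips = TRUE, oversample = TRUE, minPosFraction = 0.25, seed = 1L))

setValidity("TrainingConfig", function(object) {
  if (object@patience >= object@maxEpochs) return("patience must be < maxEpochs")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  TRUE
})

#' RfConfig: random-forest configuration
#'
#' Defaults are the optimized hyperparameters reported for the full-scale
#' data; search ranges are those used by the hyperparameter optimization.
#'
#' @slot nTrees number of decision trees (752; range 50--1000).
#' @slot maxDepth max tree depth (50; range 1--100).
#' @slot maxFeaturesPerSplit features tried per split (4; range 1--500).
#' @slot minSamplesLeaf minimum samples at a leaf (32; range 5--150).
#' @slot minSamplesSplit minimum samples to split a node (135; range 5--150).
#' @slot posWeight positive class weight (50; range 10--1000).
#' @slot seed integer seed.
#' @export
setClass("RfConfig", representation(
  nTrees = "integer", maxDepth = "integer", maxFeaturesPerSplit = "integer",
  minSamplesLeaf = "integer", minSamplesSplit = "integer", posWeight = "numeric",
  seed = "integer"),
  prototype(nTrees = 752L, maxDepth = 50L, maxFeaturesPerSplit = 4L,
            minSamplesLeaf = 32L, minSamplesSplit = 135L, posWeight = 50,
            seed = 1L))

#' PatchSet: the three multi-scale two-channel patches of one candidate
#'
#' Three centered crops at neighbourhood sizes 100x100x12, 200x200x24 and
#' 400x400x48 voxels, the larger two block-averaged down to 100x100x12, with
#' channels (GF, grayscale anatomy), normalized to [0, 1]; voxels outside the
#' volume are zero.
#'
#' @slot patches list of three arrays 100 x 100 x 12 x 2.
#' @export
setClass("PatchSet", representation(patches = "list"))

setValidity("PatchSet", function(object) {
  if (length(object@patches) != 3L) return("a PatchSet holds exactly three patches")
  for (p in object@patches) {
    if (!identical(dim(p), c(100L, 100L, 12L, 2L)))
      return("every patch must be 100 x 100 x 12 x 2")
    if (min(p) < 0 || max(p) > 1) return("patch intensities must lie in [0, 1]")
  }
  TRUE
})

#' ScoreEval: score-based evaluation of candidate classification
#'
#' @slot roc data.frame of (threshold, sensitivity, specificity).
#' @slot prc data.frame of (threshold, recall, precision).
#' @slot aucRoc,aucPrc areas under the ROC and precision-recall curves.
#' @slot threshold operating threshold (may be NA).
#' @slot confusion named numeric (TP, FP, TN, FN) at the operating threshold.
#' @export
setClass("ScoreEval", representation(roc = "data.frame", prc = "data.frame",
                                     aucRoc = "numeric", aucPrc = "numeric",
                                     threshold = "numeric", confusion = "numeric"))

#' BurdenReport: per-organ tumor burden and growth-model outputs
#'
#' @slot perMet data.frame, one row per metastasis (label, organ, centroid,
#'   volume, effective radius).
#' @slot organCounts named integer vector of per-organ metastasis counts.
#' @slot radiusHist list of per-organ radius histograms (0.5 mm bins).
#' @slot totalVolumeMm3 total tumor volume in mm^3.
#' @slot growth list with cell count N, doubling time, elapsed days.
#' @export
setClass("BurdenReport", representation(perMet = "data.frame", organCounts = "integer",
                                        radiusHist = "list", totalVolumeMm3 = "numeric",
                                        growth = "list"))
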