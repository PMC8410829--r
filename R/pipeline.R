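#' PipelineConfig: one reproducible configuration for a full run
#'
#' Bundles every stage's parameter block, the model selection, chunking and
#' seeding. Serializes losslessly to JSON (\code{saveConfig} /
#' \code{loadConfig}); every \code{runPipeline} call writes its resolved
#' configuration next to its outputs.
#'
#' @slot targetSpacingUm down-sampled spacing (40, 40, 50).
#' @slot watershed a \linkS4class{WatershedParams}.
#' @slot small a \linkS4class{SmallParams}.
#' @slot training a \linkS4class{TrainingConfig}.
#' @slot rf an \linkS4class{RfConfig}.
#' @slot mode "rf" (random forest on CNN + hand-crafted features) or "cnn"
#'   (fused multi-scale CNN probabilities).
#' @slot cnnWidths channel widths of the CNN blocks.
#' @slot scoreThreshold operating probability threshold (0.5).
#' @slot slicesPerChunk chunk height for small-candidate detection
#'   (NA = one chunk).
#' @slot overlapSlices chunk overlap (12).
#' @slot seed master seed.
#' @export
setClass("PipelineConfig", representation(
  targetSpacingUm = "numeric", watershed = "WatershedParams",
  small = "SmallParams", training = "TrainingConfig", rf = "RfConfig",
  mode = "character", cnnWidths = "integer", scoreThreshold = "numeric",
  slicesPerChunk = "numeric", overlapSlices = "integer", seed = "integer"),
  prototype(targetSpacingUm = c(40, 40, 50), watershed = new("WatershedParams"),
            small = new("SmallParams"), training = new("TrainingConfig"),
            rf = new("RfConfig"), mode = "rf", cnnWidths = c(32L, 64L, 128L),
            scoreThreshold = 0.5, slicesPerChunk = NA_real_,
            overlapSlices = 12L, seed = 1L))

#' Construct a PipelineConfig
#'
#' @param ... named slot overrides; nested parameter objects can be passed
#'   directly (e.g. \code{small = new("SmallParams", seedThreshold = 8)}).
#' @return a \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(...) {
  args <- list(...)
  cfg <- new("PipelineConfig")
  for (nm in names(args)) {
    val <- args[[nm]]
    if (is(slot(cfg, nm), "integer")) val <- as.integer(val)
    slot(cfg, nm) <- val
  }
  validObject(cfg)
  cfg
}

.s4ToList <- function(x) {
  out <- lapply(slotNames(class(x)), function(nm) {
    v <- slot(x, nm)
    if (isVirtualClass(class(v)) || is(v, "WatershedParams") ||
        is(v, "SmallParams") || is(v, "TrainingConfig") || is(v, "RfConfig"))
      .s4ToList(v) else v
  })
  names(out) <- slotNames(class(x))
  out
}

.listToS4 <- function(lst, class) {
  obj <- new(class)
  for (nm in names(lst)) {
    v <- lst[[nm]]
    cur <- slot(obj, nm)
    if (is.null(v) && is.atomic(cur)) v <- cur[NA]  # JSON null: typed NA
    if (is(cur, "WatershedParams")) v <- .listToS4(v, "WatershedParams")
    else if (is(cur, "SmallParams")) v <- .listToS4(v, "SmallParams")
    else if (is(cur, "TrainingConfig")) v <- .listToS4(v, "TrainingConfig")
    else if (is(cur, "RfConfig")) v <- .listToS4(v, "RfConfig")
    else if (is.integer(cur)) v <- as.integer(v)
    else if (is.logical(cur)) v <- as.logical(v)
    else if (is.double(cur)) v <- as.double(v)
    else if (is.character(cur)) v <- as.character(v)
    slot(obj, nm) <- v
  }
  obj
}

#' Save / load a pipeline configuration as JSON
#'
#' \code{loadConfig(saveConfig(cfg))} reproduces the configuration exactly.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param path JSON file path.
#' @return \code{saveConfig}: the path, invisibly. \code{loadConfig}: the
#'   \linkS4class{PipelineConfig}.
#' @export
saveConfig <- function(config, path) {
  jsonlite::write_json(.s4ToList(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname saveConfig
#' @export
loadConfig <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  .listToS4(lst, "PipelineConfig")
}

.stageCache <- function(outDir, name, compute) {
  if (is.null(outDir)) return(compute())
  f <- file.path(outDir, paste0(name, ".rds"))
  if (file.exists(f)) return(readRDS(f))
  val <- compute()
  saveRDS(val, f)
  val
}

#' Run the candidate-generation and quantification pipeline on one dataset
#'
#' Executes exterior masking, big-candidate watershed, chunked
#' small-candidate detection, candidate tabulation, truth assignment (when
#' annotations are given), patch and hand-crafted feature extraction, and --
#' when trained models are supplied -- classification, thresholding and the
#' tumor-burden report. Stage outputs are cached in \code{outDir} (when
#' given) and reruns resume from the cache; the resolved configuration is
#' written next to the outputs. Stage timings and counts are logged via
#' \code{message}.
#'
#' @param color,gf full-resolution \linkS4class{Volume3D} pair.
#' @param config a \linkS4class{PipelineConfig}.
#' @param annotations optional manual-annotation \linkS4class{LabelVolume}
#'   (full grid) for truth labeling.
#' @param organMasks optional named list of binary organ masks (full grid).
#' @param models optional list(cnn = list of 3, rf = rf model) for scoring.
#' @param outDir optional cache/output directory.
#' @return list with \code{body}, \code{big}, \code{candidates}
#'   (LabelVolume), \code{table}, \code{patchSets}, \code{handcrafted} and,
#'   when scored, \code{scores}, \code{kept}, \code{corrected}, \code{burden}.
#' @export
runPipeline <- function(color, gf, config = pipelineConfig(),
                        annotations = NULL, organMasks = NULL,
                        models = NULL, outDir = NULL) {
  stopifnot(is(color, "Volume3D"), is(gf, "Volume3D"))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    saveConfig(config, file.path(outDir, "config.json"))
    writeLines(as.character(utils::packageVersion("CryoMetSeg")),
               file.path(outDir, "VERSION"))
  }
  t0 <- proc.time()[3]
  stage <- function(name, compute) {
    val <- .stageCache(outDir, name, compute)
    message(sprintf("[%s] done at %.1fs", name, proc.time()[3] - t0))
    val
  }
  down <- stage("downsample", function() list(
    color = resampleVolume(color, config@targetSpacingUm, "linear"),
    gf = resampleVolume(gf, config@targetSpacingUm, "linear")))
  body <- stage("exterior", function() segmentExterior(down$color, down$gf))
  big <- stage("big", function() detectBigCandidates(down$gf, body, config@watershed))
  cand <- stage("candidates", function() {
    spc <- config@slicesPerChunk
    detectSmallCandidates(gf, body, big, config@small,
                          slicesPerChunk = if (is.na(spc)) NULL else as.integer(spc),
                          overlapSlices = config@overlapSlices)
  })
  tab <- stage("table", function() {
    tb <- candidateTable(cand)
    if (!is.null(annotations)) tb <- assignTruth(tb, annotations)
    tb
  })
  message(sprintf("candidates: %d", nrow(tab)))
  feats <- stage("features", function() {
    gray <- rgbToGray(color@voxels[, , , 1], color@voxels[, , , 2],
                      color@voxels[, , , 3])
    d <- gridDim(gf)
    sp <- voxelSpacing(gf)
    ps <- lapply(seq_len(nrow(tab)), function(i) {
      ctr <- c(tab$x_um[i], tab$y_um[i], tab$z_um[i]) / sp - 0.5
      extractPatchSet(NULL, gf, ctr, gray = gray)
    })
    hc <- if (nrow(tab)) candidateFeatureMatrix(tab, color, gf) else
      matrix(0, 0, 29)
    list(patchSets = ps, handcrafted = hc)
  })
  out <- list(body = body, big = big, candidates = cand, table = tab,
              patchSets = feats$patchSets, handcrafted = feats$handcrafted,
              config = config)
  if (!is.null(models) && nrow(tab) > 0L) {
    scores <- stage("scores", function()
      classifyCandidates(feats$patchSets, feats$handcrafted, models$cnn,
                         models$rf, config@mode))
    kept <- which(scores >= config@scoreThreshold)
    corrected <- stage("corrected", function()
      applyCorrections(cand, removals = setdiff(tab$id, kept)))
    burden <- stage("burden", function()
      burdenReport(corrected, if (is.null(organMasks)) list() else organMasks))
    out <- c(out, list(scores = scores, kept = kept, corrected = corrected,
                       burden = burden))
  }
  out
}
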