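#' Run configuration
#'
#' Collects the experiment knobs of the pipeline, validates every field
#' against its enumeration, and is echoed verbatim into all result files.
#' Defaults mirror the reference settings: mock backbone on the pool5-style
#' path, MMSP frame features with true-mean coefficients, TPMM temporal
#' pooling, appearance stream only, 1 fps sampling, SVM cost 1,
#' per-stream normalisation before fusion.
#'
#' @param backboneProvider `"mock"` or `"vgg16"`.
#' @param backboneLayer `"pool5"` or `"fc7"`.
#' @param frameFeature `"mmsp"`, `"fc7"`, or `"fvpool5"` (stacked pool5
#'   baseline). `"fc7"` forces `backboneLayer = "fc7"`.
#' @param spatialMode `"true_mean"` or `"ninth"` (see [regionMean()]).
#' @param temporalPooling `"tpmm"`, `"max"`, or `"mean"`.
#' @param streams `"appearance"`, `"motion"`, or `"both"`.
#' @param fusion `"clip"` (pool each stream, concatenate clip vectors) or
#'   `"frame"` (concatenate per-frame descriptors before pooling).
#' @param targetFps frame sampling rate (1 or 10 are the studied choices).
#' @param samplingOffset 0-based offset of the sampling anchor.
#' @param svmCost SVM misclassification cost C.
#' @param normalization `"per_stream"` (normalise each modality, fuse,
#'   renormalise) or `"after_fuse"` (single normalisation of the fused
#'   vector).
#' @param flowNorm,flowCap flow-image magnitude normalisation
#'   (see [flowToImage()]).
#' @param seed pipeline seed; `backboneSeed` defaults to it.
#' @param backboneSeed seed of the backbone provider parameters.
#' @param skipBadFolds passed to [lopoEvaluate()].
#' @return a validated named list of class `"egopoolConfig"`.
#' @export
runConfig <- function(backboneProvider = "mock", backboneLayer = "pool5",
                      frameFeature = "mmsp", spatialMode = "true_mean",
                      temporalPooling = "tpmm", streams = "appearance",
                      fusion = "clip", targetFps = 1, samplingOffset = 0,
                      svmCost = 1, normalization = "per_stream",
                      flowNorm = "per_frame", flowCap = NULL, seed = 1,
                      backboneSeed = seed, skipBadFolds = FALSE) {
  cfg <- list(
    backboneProvider = match.arg(backboneProvider, c("mock", "vgg16")),
    backboneLayer = match.arg(backboneLayer, c("pool5", "fc7")),
    frameFeature = match.arg(frameFeature, c("mmsp", "fc7", "fvpool5")),
    spatialMode = match.arg(spatialMode, c("true_mean", "ninth")),
    temporalPooling = match.arg(temporalPooling, c("tpmm", "max", "mean")),
    streams = match.arg(streams, c("appearance", "motion", "both")),
    fusion = match.arg(fusion, c("clip", "frame")),
    targetFps = targetFps, samplingOffset = samplingOffset,
    svmCost = svmCost,
    normalization = match.arg(normalization, c("per_stream", "after_fuse")),
    flowNorm = match.arg(flowNorm, c("per_frame", "fixed")),
    flowCap = flowCap, seed = seed, backboneSeed = backboneSeed,
    skipBadFolds = isTRUE(skipBadFolds))
  if (cfg$frameFeature == "fc7") cfg$backboneLayer <- "fc7"
  if (!is.numeric(cfg$targetFps) || cfg$targetFps <= 0)
    stop("targetFps must be positive", call. = FALSE)
  if (!is.numeric(cfg$svmCost) || cfg$svmCost <= 0)
    stop("svmCost must be positive", call. = FALSE)
  class(cfg) <- "egopoolConfig"
  cfg
}

#' Read a run configuration from a YAML or key:value file
#'
#' Unknown keys raise a schema error naming the key; values are validated
#' by [runConfig()].
#'
#' @param path YAML file of `key: value` pairs.
#' @return a validated configuration (see [runConfig()]).
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path, call. = FALSE)
  vals <- if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::read_yaml(path)
  } else {
    lines <- grep(":", readLines(path), value = TRUE)
    kv <- strsplit(lines, ":", fixed = TRUE)
    stats::setNames(lapply(kv, function(p) {
      v <- trimws(paste(p[-1], collapse = ":"))
      if (grepl("^-?[0-9.]+$", v)) as.numeric(v) else v
    }), trimws(vapply(kv, `[`, "", 1)))
  }
  known <- names(formals(runConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(runConfig, vals)
}
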