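# Pipeline orchestration: frames -> backbone -> spatial pooling -> cache ->
# temporal pooling -> fusion -> LOPO.

make_backbone <- function(config) {
  if (config$backboneProvider == "mock") mockBackbone(seed = config$backboneSeed)
  else vgg16Backbone(seed = config$backboneSeed)
}

frame_descriptor <- function(backbone, image, config) {
  if (config$frameFeature == "fc7") {
    img <- if (backbone@provider == "vgg16") preprocessFrame(image) else image
    return(extractFc7(backbone, img))
  }
  img <- if (backbone@provider == "vgg16") preprocessFrame(image) else image
  stack <- extractPool5(backbone, img)
  if (config$frameFeature == "fvpool5") stackPool5(stack)
  else mmsp(stack, mode = config$spatialMode)
}

# Per-clip, per-stream frame-descriptor matrices (d x N), computed from
# frames on disk.
extract_clip <- function(record, config, backbone) {
  frames <- readFrames(record$path)
  sampled <- sampleFrames(frames, record$native_fps, config$targetFps,
                          config$samplingOffset)
  describe_all <- function(imgs) {
    cols <- lapply(imgs, function(f) frame_descriptor(backbone, f, config))
    do.call(cbind, cols)
  }
  out <- list()
  if (config$streams %in% c("appearance", "both"))
    out$appearance <- describe_all(sampled)
  if (config$streams %in% c("motion", "both"))
    out$motion <- describe_all(
      motionImageSequence(sampled, magnitudeNorm = config$flowNorm,
                          cap = config$flowCap))
  out
}

#' Extract and cache frame descriptors for every clip
#'
#' Runs the backbone + spatial pooling over all clips of a manifest and
#' stores the per-clip, per-stream frame-descriptor matrices in the cache.
#' Clips whose needed streams are already cached are skipped, so re-runs
#' are idempotent. Per-clip failures are logged and the run continues; the
#' returned summary reports them.
#'
#' @param manifest a [DatasetManifest-class].
#' @param config a configuration from [runConfig()].
#' @param cache a `FeatureCache` from [featureCache()].
#' @return data.frame summary: clip_id, status ("cached", "extracted",
#'   "failed"), message.
#' @export
extractFeatures <- function(manifest, config, cache) {
  stopifnot(is(manifest, "DatasetManifest"), is(cache, "FeatureCache"))
  backbone <- make_backbone(config)
  records <- manifest@records
  needed <- switch(config$streams, appearance = "appearance",
                   motion = "motion", both = c("appearance", "motion"))
  status <- character(nrow(records)); msg <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    if (all(vapply(needed, function(s) cacheHas(cache, rec$clip_id, s), logical(1)))) {
      status[i] <- "cached"; msg[i] <- ""
      next
    }
    res <- tryCatch({
      feats <- extract_clip(rec, config, backbone)
      for (s in needed) cachePut(cache, rec$clip_id, s, feats[[s]])
      list(status = "extracted", msg = "")
    }, error = function(e) list(status = "failed", msg = conditionMessage(e)))
    status[i] <- res$status; msg[i] <- res$msg
  }
  failed <- sum(status == "failed")
  if (failed > 0)
    message("extraction finished with ", failed, " failed clip(s)")
  data.frame(clip_id = records$clip_id, status = status, message = msg,
             stringsAsFactors = FALSE)
}

# One clip's final descriptor vector from cached frame descriptors.
clip_descriptor <- function(cache, clipId, config) {
  get_stream <- function(s) {
    m <- cacheGet(cache, clipId, s)
    if (is.null(m)) stop("no cached ", s, " descriptors for clip ", clipId,
                         call. = FALSE)
    as.matrix(m)
  }
  pool <- function(m) switch(config$temporalPooling,
                             tpmm = tpmm(m), max = temporalMax(m),
                             mean = temporalMean(m))
  if (config$streams == "appearance") return(l2Normalize(pool(get_stream("appearance"))))
  if (config$streams == "motion") return(l2Normalize(pool(get_stream("motion"))))
  app <- get_stream("appearance"); mot <- get_stream("motion")
  if (config$fusion == "frame")
    return(l2Normalize(pool(fuseFrameFeatures(app, mot))))
  if (config$normalization == "per_stream")
    l2Normalize(c(l2Normalize(pool(app)), l2Normalize(pool(mot))))
  else
    l2Normalize(c(pool(app), pool(mot)))
}

#' Pool cached frame descriptors into the clip-descriptor matrix
#'
#' @inheritParams extractFeatures
#' @return n x d numeric matrix, row i the L2-normalised descriptor of
#'   clip i of `clipRecords(manifest)`.
#' @export
clipDescriptors <- function(manifest, config, cache) {
  stopifnot(is(manifest, "DatasetManifest"), is(cache, "FeatureCache"))
  ids <- manifest@records$clip_id
  rows <- lapply(ids, function(id) clip_descriptor(cache, id, config))
  do.call(rbind, rows)
}

#' Run the full evaluation pipeline on a manifest
#'
#' Extracts (or reuses cached) frame descriptors, pools them into clip
#' descriptors, fuses streams as configured, and evaluates with
#' leave-one-person-out cross-validation. The configuration, seeds, and
#' backbone identifier are echoed into the result.
#'
#' @inheritParams extractFeatures
#' @param cache a `FeatureCache`; defaults to a fresh temporary cache.
#' @return an [EvaluationResult-class].
#' @export
evaluateManifest <- function(manifest, config = runConfig(),
                             cache = featureCache(tempfile("egopool-cache-"))) {
  summary <- extractFeatures(manifest, config, cache)
  bad <- summary$clip_id[summary$status == "failed"]
  if (length(bad))
    stop("cannot evaluate: extraction failed for clip(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  desc <- clipDescriptors(manifest, config, cache)
  meta <- unclass(config)
  meta$backboneIdentifier <- backboneIdentifier(make_backbone(config))
  lopoEvaluate(manifest, desc, cost = config$svmCost, config = meta,
               skipBadFolds = config$skipBadFolds)
}
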