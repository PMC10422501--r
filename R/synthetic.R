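# Seeded synthetic fixtures.
#
# Two generators make every pipeline stage testable without downloads:
# feature-map stacks whose class signal is an additive bump localised in
# one of the MMSP pooling regions (so the spatial-pooling stage is what
# makes classes separable), and short RGB clips of a textured square moving
# over a textured background with recorded ground-truth shifts (so the flow
# branch can be checked against construction). All generators are pure
# functions of (spec, seed): re-running yields bit-identical output.

#' SyntheticSpec: study conditions for the fixture generators
#'
#' @slot seed base seed all per-clip seeds derive from.
#' @slot nSubjects,nClasses,clipsPerSubjectClass dataset layout counts.
#' @slot nFrames frames per clip.
#' @slot frameSize frame side length in pixels.
#' @slot nativeFps nominal frame rate written to the manifest.
#' @slot signalRegions region name per class (see [regionSpecs()]).
#' @slot signalStrength additive activation offset of the class bump.
#' @slot noiseSd activation noise scale.
#' @slot motionProfile "static", "translate", or "class_dependent".
#' @slot shift per-interval (dx, dy) pixel shift for "translate".
#' @export
setClass("SyntheticSpec",
  representation(seed = "numeric", nSubjects = "integer", nClasses = "integer",
                 clipsPerSubjectClass = "integer", nFrames = "integer",
                 frameSize = "integer", nativeFps = "numeric",
                 signalRegions = "character", signalStrength = "numeric",
                 noiseSd = "numeric", motionProfile = "character",
                 shift = "numeric"),
  validity = function(object) {
    if (any(c(object@nSubjects, object@nClasses, object@clipsPerSubjectClass,
              object@nFrames, object@frameSize) < 1))
      return("all counts must be positive")
    if (length(object@signalRegions) != object@nClasses)
      return("one signal region per class required")
    if (!all(object@signalRegions %in% names(regionSpecs())))
      return("unknown signal region name")
    if (!object@motionProfile %in% c("static", "translate", "class_dependent"))
      return("motionProfile must be static, translate or class_dependent")
    if (object@frameSize < 4 * 4)
      return("frameSize too small for the moving shape")
    TRUE
  })

#' Build a synthetic-data specification
#'
#' Defaults are the package's reference study conditions: 3 subjects, 2
#' classes, 2 clips per subject and class, 9 frames per 64 px clip at a
#' nominal 3 fps, class bump of 3 activation units against noise of SD 0.5
#' (a separable margin: strength exceeds three noise SDs), and a (5, 0) px
#' per-interval shift when motion is enabled. The `"separable"` preset is
#' exactly these defaults; `"noise"` zeroes the class signal so chance-level
#' behaviour can be measured.
#'
#' @param preset `"custom"` (use the arguments as given), `"separable"`, or
#'   `"noise"`.
#' @param seed base seed.
#' @param nSubjects,nClasses,clipsPerSubjectClass,nFrames,frameSize,nativeFps
#'   dataset layout.
#' @param signalRegions region name per class; `NULL` assigns
#'   top_left, bottom_right, top_right, bottom_left, center cyclically.
#' @param signalStrength,noiseSd class bump height and noise scale.
#' @param motionProfile,shift motion of the textured square in video clips.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(preset = c("custom", "separable", "noise"), seed = 1,
                          nSubjects = 3, nClasses = 2, clipsPerSubjectClass = 2,
                          nFrames = 9, frameSize = 64, nativeFps = 3,
                          signalRegions = NULL, signalStrength = 3,
                          noiseSd = 0.5,
                          motionProfile = c("static", "translate",
                                            "class_dependent"),
                          shift = c(5, 0)) {
  preset <- match.arg(preset)
  motionProfile <- match.arg(motionProfile)
  if (preset == "noise") signalStrength <- 0
  if (preset == "separable" && signalStrength <= 3 * noiseSd)
    stop("separable preset requires signalStrength > 3 * noiseSd", call. = FALSE)
  if (is.null(signalRegions)) {
    pool <- c("top_left", "bottom_right", "top_right", "bottom_left", "center")
    signalRegions <- rep(pool, length.out = nClasses)
  }
  new("SyntheticSpec", seed = seed, nSubjects = as.integer(nSubjects),
      nClasses = as.integer(nClasses),
      clipsPerSubjectClass = as.integer(clipsPerSubjectClass),
      nFrames = as.integer(nFrames), frameSize = as.integer(frameSize),
      nativeFps = nativeFps, signalRegions = signalRegions,
      signalStrength = signalStrength, noiseSd = noiseSd,
      motionProfile = motionProfile, shift = shift)
}

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %d subjects x %d classes x %d clips, %d frames/clip\n",
              object@nSubjects, object@nClasses, object@clipsPerSubjectClass,
              object@nFrames))
  cat(sprintf("  signal %.2g (noise sd %.2g) in regions: %s; motion %s\n",
              object@signalStrength, object@noiseSd,
              paste(object@signalRegions, collapse = ", "), object@motionProfile))
})

# 64 seeded signal channels per class, a pure function of (spec seed, class).
signal_channels <- function(spec, classId, nchan = 512L) {
  with_seed(spec@seed * 131 + classId, sample.int(nchan, 64L))
}

#' Generate one synthetic feature-map stack
#'
#' Baseline activations are N(1, noiseSd) draws over a 7 x 7 x 512 grid;
#' the class signal is an additive bump of `signalStrength` placed in the
#' class's pooling region across a seeded 64-channel subset (fixed per
#' class). With `noiseSd = 0` the output is exactly baseline-plus-bump.
#'
#' @param spec a [SyntheticSpec-class].
#' @param classId class index in 1..nClasses.
#' @param seed per-draw seed.
#' @return a 7 x 7 x 512 [FeatureMapStack-class].
#' @export
genFeatureStack <- function(spec, classId, seed) {
  stopifnot(is(spec, "SyntheticSpec"))
  if (classId < 1 || classId > spec@nClasses)
    stop("unknown class id ", classId, call. = FALSE)
  vals <- with_seed(seed,
    array(stats::rnorm(7 * 7 * 512, mean = 1, sd = spec@noiseSd), c(7, 7, 512)))
  rg <- regionSpecs()[[spec@signalRegions[classId]]]
  ch <- signal_channels(spec, classId)
  vals[rg$rows[1]:rg$rows[2], rg$cols[1]:rg$cols[2], ch] <-
    vals[rg$rows[1]:rg$rows[2], rg$cols[1]:rg$cols[2], ch] + spec@signalStrength
  FeatureMapStack(vals)
}

# Map a pooling region to a top-left pixel position for the square so the
# shape sits inside the class's region of the image.
region_anchor <- function(regionName, frameSize, shapeSize) {
  rg <- regionSpecs()[[regionName]]
  centre_r <- mean(rg$rows) / 7 * frameSize
  centre_c <- mean(rg$cols) / 7 * frameSize
  c(round(centre_r - shapeSize / 2), round(centre_c - shapeSize / 2))
}

class_shift <- function(spec, classId) {
  if (spec@motionProfile == "static") return(c(0, 0))
  if (spec@motionProfile == "translate") return(spec@shift)
  dirs <- list(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  d <- dirs[[(classId - 1) %% 4 + 1]]
  d * sqrt(sum(spec@shift^2))
}

#' Generate one synthetic video clip with motion ground truth
#'
#' Frames show a smooth-textured square over a lower-contrast textured
#' static background. The square is anchored in the class's pooling region
#' and moves per the motion profile in integer pixel steps, so translation
#' between consecutive frames is exact; positions are clamped at the frame
#' border and the *applied* per-interval shift is recorded, giving the flow
#' branch its ground truth.
#'
#' @inheritParams genFeatureStack
#' @return list with `frames` (list of H x W x 3 arrays), `shifts`
#'   ((nFrames - 1) x 2 matrix of applied (dx, dy)), and `positions`
#'   (nFrames x 2 top-left (row, col) of the square).
#' @export
genVideo <- function(spec, classId, seed) {
  stopifnot(is(spec, "SyntheticSpec"))
  if (classId < 1 || classId > spec@nClasses)
    stop("unknown class id ", classId, call. = FALSE)
  S <- spec@frameSize
  s <- max(4L, S %/% 4L)
  if (s >= S) stop("frameSize too small for the moving shape", call. = FALSE)
  shift <- round(class_shift(spec, classId))   # (dx, dy) = (cols, rows)
  tex <- with_seed(seed, list(
    bg = lapply(1:3, function(i)
      0.2 + 0.3 * gaussian_blur(matrix(stats::runif(S * S), S, S), 2) /
        max(gaussian_blur(matrix(1, S, S), 2))),
    sq = lapply(1:3, function(i) {
      m <- gaussian_blur(matrix(stats::runif(s * s), s, s), 1)
      0.5 + 0.5 * (m - min(m)) / max(max(m) - min(m), 1e-12)
    })))
  anchor <- region_anchor(spec@signalRegions[classId], S, s)
  # start so the motion path stays inside the frame where possible
  pos <- c(
    min(max(anchor[1] - shift[2] * (spec@nFrames - 1) / 2, 1), S - s),
    min(max(anchor[2] - shift[1] * (spec@nFrames - 1) / 2, 1), S - s))
  pos <- round(pos)
  frames <- vector("list", spec@nFrames)
  positions <- matrix(0L, spec@nFrames, 2)
  for (t in seq_len(spec@nFrames)) {
    canvas <- array(0, c(S, S, 3))
    for (ch in 1:3) canvas[, , ch] <- tex$bg[[ch]]
    rr <- pos[1]:(pos[1] + s - 1L); cc <- pos[2]:(pos[2] + s - 1L)
    for (ch in 1:3) canvas[rr, cc, ch] <- tex$sq[[ch]]
    frames[[t]] <- pmin(pmax(canvas, 0), 1)
    positions[t, ] <- as.integer(pos)
    nxt <- c(min(max(pos[1] + shift[2], 1), S - s),
             min(max(pos[2] + shift[1], 1), S - s))
    pos <- nxt
  }
  shifts <- cbind(dx = diff(positions[, 2]), dy = diff(positions[, 1]))
  if (spec@nFrames == 1L) shifts <- matrix(0, 0, 2, dimnames = list(NULL, c("dx", "dy")))
  list(frames = frames, shifts = shifts, positions = positions)
}

#' Generate a complete synthetic dataset
#'
#' Writes a balanced manifest (`manifest.csv`) under `dir` plus, depending
#' on `form`, either per-clip PNG frame directories (`clips/<clip_id>/`,
#' the full-pipeline route) or a pre-populated frame-descriptor cache
#' (`cache/`, the pooling-only route: per-frame MMSP descriptors of
#' generated feature stacks for both streams, the motion stream carrying
#' the class bump at half strength).
#'
#' @param spec a [SyntheticSpec-class].
#' @param dir output directory (created if needed).
#' @param form `"features"` (default) or `"frames"`.
#' @param spatialMode MMSP mean convention used when `form = "features"`.
#' @param shuffleLabels if `TRUE`, randomly permute the manifest labels
#'   within each subject (seeded) -- the stratified chance-level control,
#'   which keeps every LOPO fold balanced.
#' @return list with `manifest` (a [DatasetManifest-class]), `dir`, and
#'   `cache` (a `FeatureCache` or `NULL`).
#' @export
genDataset <- function(spec, dir = tempfile("egopool-synth-"),
                       form = c("features", "frames"),
                       spatialMode = "true_mean", shuffleLabels = FALSE) {
  stopifnot(is(spec, "SyntheticSpec"))
  form <- match.arg(form)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create dataset directory: ", dir, call. = FALSE)
  records <- expand.grid(rep = seq_len(spec@clipsPerSubjectClass),
                         class = seq_len(spec@nClasses),
                         subject = seq_len(spec@nSubjects))
  records <- records[, c("subject", "class", "rep")]
  clip_id <- sprintf("s%02d_c%02d_r%02d", records$subject, records$class,
                     records$rep)
  df <- data.frame(
    clip_id = clip_id,
    path = file.path(dir, "clips", clip_id),
    subject_id = sprintf("subj%02d", records$subject),
    label = sprintf("act%02d", records$class),
    native_fps = spec@nativeFps,
    stringsAsFactors = FALSE)
  cache <- NULL
  if (form == "features") {
    cache <- featureCache(file.path(dir, "cache"))
    for (i in seq_len(nrow(df))) {
      clip_seed <- spec@seed * 100000 + i
      app <- sapply(seq_len(spec@nFrames), function(t)
        mmsp(genFeatureStack(spec, records$class[i], clip_seed + t),
             mode = spatialMode))
      mot_spec <- spec
      mot_spec@signalStrength <- spec@signalStrength / 2
      mot <- sapply(seq_len(spec@nFrames), function(t)
        mmsp(genFeatureStack(mot_spec, records$class[i],
                             clip_seed + 5000 + t), mode = spatialMode))
      cachePut(cache, df$clip_id[i], "appearance", app)
      cachePut(cache, df$clip_id[i], "motion", mot)
    }
  } else {
    for (i in seq_len(nrow(df))) {
      clip_seed <- spec@seed * 100000 + i
      vid <- genVideo(spec, records$class[i], clip_seed)
      if (!dir.create(df$path[i], recursive = TRUE, showWarnings = FALSE))
        stop("cannot create clip directory: ", df$path[i], call. = FALSE)
      for (t in seq_along(vid$frames))
        png::writePNG(vid$frames[[t]],
                      file.path(df$path[i], sprintf("frame_%04d.png", t)))
    }
  }
  if (shuffleLabels) {
    # Stratified (within-subject) permutation: every subject keeps its
    # label counts, so LOPO training folds stay balanced and the chance
    # level matches the binomial null. An unstratified shuffle leaves
    # per-fold imbalance that a majority-leaning classifier anti-predicts,
    # biasing accuracy below chance.
    df$label <- with_seed(spec@seed * 7 + 3, {
      out <- df$label
      for (s in unique(df$subject_id)) {
        idx <- which(df$subject_id == s)
        out[idx] <- sample(out[idx])
      }
      out
    })
  }
  manifest <- DatasetManifest(df)
  writeManifest(manifest, file.path(dir, "manifest.csv"))
  list(manifest = manifest, dir = dir, cache = cache)
}
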