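#' Read a dataset manifest
#'
#' Loads a CSV manifest with header
#' \code{clip_id,path,subject_id,label,native_fps}, validates it, and
#' returns a [DatasetManifest-class]. Row order is preserved. Paths may be
#' relative; they are kept verbatim.
#'
#' @param path path to the manifest CSV.
#' @return A [DatasetManifest-class].
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("clip_id,path,subject_id,label,native_fps",
#'              "c1,/tmp/c1,s1,eat,30", "c2,/tmp/c2,s2,read,30"), tf)
#' readManifest(tf)
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest file does not exist: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("clip_id", "path", "subject_id", "label", "native_fps")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("manifest is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) stop("manifest is empty", call. = FALSE)
  if (anyDuplicated(df$clip_id))
    stop("duplicate clip_id in manifest: ",
         paste(unique(df$clip_id[duplicated(df$clip_id)]), collapse = ", "),
         call. = FALSE)
  fps <- suppressWarnings(as.numeric(df$native_fps))
  if (any(!is.finite(fps)) || any(fps <= 0))
    stop("native_fps must be a positive number for every clip", call. = FALSE)
  df$native_fps <- fps
  DatasetManifest(df)
}

#' Write a dataset manifest
#'
#' Inverse of [readManifest()]: writes the record table as CSV with the
#' canonical header. Round-tripping through write/read is the identity on
#' all fields.
#'
#' @param manifest a [DatasetManifest-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  stopifnot(is(manifest, "DatasetManifest"))
  cols <- c("clip_id", "path", "subject_id", "label", "native_fps")
  utils::write.csv(manifest@records[, cols], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read the frames of one clip
#'
#' Reads a directory of PNG frame images in lexicographic filename order and
#' returns them as a list of H x W x 3 arrays with values in [0, 1].
#' Grayscale PNGs are expanded to three identical channels; alpha channels
#' are dropped. All frames of a clip must share the same height and width.
#' Video containers (mp4/avi) are not decodable here and raise an error
#' asking for an extracted frame directory instead.
#'
#' @param path frame directory (or a ClipRecord row's `path` field).
#' @return list of H x W x 3 numeric arrays, in temporal order.
#' @export
readFrames <- function(path) {
  if (length(path) == 1 && is.character(path) &&
      grepl("\\.(mp4|avi|mov|mkv)$", tolower(path))) {
    stop("video containers are not supported; extract frames to a PNG ",
         "directory first: ", path, call. = FALSE)
  }
  if (!dir.exists(path))
    stop("clip path is not a readable directory: ", path, call. = FALSE)
  files <- sort(list.files(path, pattern = "\\.png$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0)
    stop("no decodable frames found in ", path, call. = FALSE)
  frames <- lapply(files, function(f) {
    img <- tryCatch(png::readPNG(f),
                    error = function(e) stop("failed to decode frame ", f, ": ",
                                             conditionMessage(e), call. = FALSE))
    if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3))
    if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
    img
  })
  dims <- vapply(frames, function(f) dim(f)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frames in ", path, " do not share a common height/width", call. = FALSE)
  frames
}

#' Temporally sub-sample a frame sequence
#'
#' Keeps every k-th frame with stride \code{k = round(native_fps /
#' target_fps)} (never below 1), starting at the first frame (an optional
#' `offset` shifts the anchor). The output is never empty: a one-frame clip
#' yields that frame. Rounding of half-strides follows R's round-half-to-even.
#'
#' @param frames list (or vector) of frames in temporal order.
#' @param nativeFps the clip's native frame rate (frames/second, > 0).
#' @param targetFps the desired rate; must satisfy targetFps <= nativeFps.
#' @param offset 0-based index of the first retained frame within the first
#'   stride window (default 0).
#' @return the sub-sampled sequence, same container type as `frames`.
#' @examples
#' length(sampleFrames(as.list(1:90), 30, 1))   # 3 (frames 1, 31, 61)
#' length(sampleFrames(as.list(1:90), 30, 10))  # 30
#' @export
sampleFrames <- function(frames, nativeFps, targetFps, offset = 0) {
  if (targetFps <= 0) stop("targetFps must be > 0", call. = FALSE)
  if (targetFps > nativeFps)
    stop("targetFps (", targetFps, ") exceeds nativeFps (", nativeFps, ")",
         call. = FALSE)
  n <- length(frames)
  if (n == 0) stop("empty frame sequence", call. = FALSE)
  k <- max(1L, as.integer(round(nativeFps / targetFps)))
  start <- min(1L + as.integer(offset), n)
  frames[seq.int(start, n, by = k)]
}
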