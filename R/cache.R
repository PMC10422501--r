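#' On-disk feature cache
#'
#' A directory-backed store for per-clip, per-stream frame-descriptor
#' arrays, so that expensive backbone passes run once. Each entry is one
#' file (R native serialisation) holding a named list with a mandatory
#' \code{format_version} field and the numeric array under \code{values};
#' the layout is documented in the README. Get-after-put returns
#' bit-identical content; a missing entry is reported as `NULL`, which is
#' distinguishable from a stored empty array.
#'
#' @param dir cache directory; created (recursively) if absent.
#' @return A `FeatureCache` object.
#' @examples
#' fc <- featureCache(file.path(tempdir(), "egopool-cache"))
#' cachePut(fc, "clip1", "appearance", matrix(1:6, 2))
#' cacheGet(fc, "clip1", "appearance")
#' @export
featureCache <- function(dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, mode = 2) != 0)
    stop("cache directory is not writable: ", dir, call. = FALSE)
  new("FeatureCache", dir = normalizePath(dir))
}

#' @rdname featureCache
#' @export
setClass("FeatureCache", representation(dir = "character"))

setMethod("show", "FeatureCache", function(object) {
  n <- length(list.files(object@dir, pattern = "\\.rds$"))
  cat(sprintf("FeatureCache at %s (%d entr%s)\n", object@dir, n,
              if (n == 1) "y" else "ies"))
})

cache_file <- function(cache, clipId, streamTag) {
  streamTag <- match.arg(streamTag, c("appearance", "motion"))
  safe <- gsub("[^A-Za-z0-9._-]", "_", clipId)
  file.path(cache@dir, paste0(safe, "__", streamTag, ".rds"))
}

#' Store a descriptor array in the cache
#'
#' Writing twice under the same (clip, stream) key overwrites; the second
#' write wins and a message is emitted.
#'
#' @param cache a `FeatureCache` from [featureCache()].
#' @param clipId clip identifier.
#' @param streamTag `"appearance"` or `"motion"`.
#' @param values finite numeric array/matrix of frame descriptors.
#' @return the entry's file path, invisibly.
#' @export
cachePut <- function(cache, clipId, streamTag, values) {
  assert_finite(values, "cached descriptor array")
  f <- cache_file(cache, clipId, streamTag)
  if (file.exists(f))
    message("cache: overwriting existing entry for ", clipId, "/", streamTag)
  payload <- list(format_version = 1L, clip_id = clipId,
                  stream = streamTag, values = values)
  tryCatch(saveRDS(payload, f),
           error = function(e) stop("cache write failed: ", conditionMessage(e),
                                    call. = FALSE))
  invisible(f)
}

#' Retrieve a descriptor array from the cache
#'
#' @inheritParams cachePut
#' @return the stored array, or `NULL` on a miss.
#' @export
cacheGet <- function(cache, clipId, streamTag) {
  f <- cache_file(cache, clipId, streamTag)
  if (!file.exists(f)) return(NULL)
  payload <- readRDS(f)
  if (is.null(payload$format_version) || payload$format_version != 1L)
    stop("unrecognised cache format version in ", f, call. = FALSE)
  payload$values
}

#' @describeIn cacheGet test whether an entry exists without reading it
#' @export
cacheHas <- function(cache, clipId, streamTag) {
  file.exists(cache_file(cache, clipId, streamTag))
}
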