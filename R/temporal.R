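# Temporal aggregation of per-frame descriptors into a single clip vector.
#
# Frame descriptors are held as a d x N matrix (one column per sampled
# frame, in temporal order). The two-level temporal pyramid (TPMM) takes
# the element-wise max over the whole clip, then the element-wise mean of
# the first and second halves; plain max and mean pooling are the
# single-level baselines.

as_frame_matrix <- function(frames) {
  if (is.list(frames)) frames <- do.call(cbind, frames)
  if (is.vector(frames) && is.numeric(frames)) frames <- matrix(frames, nrow = 1)
  if (!is.matrix(frames) || ncol(frames) < 1)
    stop("a non-empty descriptor sequence is required", call. = FALSE)
  assert_finite(frames, "frame descriptor sequence")
  frames
}

#' Element-wise temporal max pooling
#'
#' @param frames d x N matrix of frame descriptors (columns = frames), a
#'   list of numeric vectors, or a plain numeric vector of N scalar frames.
#' @return numeric vector of length d: the element-wise maximum over frames.
#' @examples
#' temporalMax(c(1, 2, 3, 4))   # 4
#' @export
temporalMax <- function(frames) {
  m <- as_frame_matrix(frames)
  do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

#' Element-wise temporal mean pooling
#'
#' @inheritParams temporalMax
#' @return numeric vector of length d: the element-wise mean over frames.
#' @examples
#' temporalMean(c(1, 2, 3, 4))  # 2.5
#' @export
temporalMean <- function(frames) {
  rowMeans(as_frame_matrix(frames))
}

#' Two-level temporal pyramid max/mean pooling (TPMM)
#'
#' Level one takes the element-wise max over the whole clip; level two
#' splits the clip into two halves -- frames 1..floor(N/2) and
#' floor(N/2)+1..N -- and takes the element-wise mean of each, every mean
#' dividing by its own half's actual frame count (so odd N never rescales
#' incorrectly). The three blocks are concatenated in the order
#' [max, first-half mean, second-half mean], giving a vector of length 3d.
#' A single-frame clip reuses its one frame for both halves.
#'
#' @inheritParams temporalMax
#' @return numeric vector of length `3 * d`.
#' @examples
#' tpmm(c(1, 2, 3, 4))   # c(4, 1.5, 3.5)
#' @export
tpmm <- function(frames) {
  m <- as_frame_matrix(frames)
  n <- ncol(m)
  if (n == 1L) {
    h1 <- h2 <- 1L
  } else {
    h1 <- seq_len(n %/% 2L)
    h2 <- seq.int(n %/% 2L + 1L, n)
  }
  c(temporalMax(m),
    rowMeans(m[, h1, drop = FALSE]),
    rowMeans(m[, h2, drop = FALSE]))
}

#' L2 (Euclidean) normalisation
#'
#' Scales a vector to unit Euclidean norm. A zero vector cannot be
#' normalised and is returned unchanged with a warning.
#'
#' @param v finite numeric vector.
#' @return vector with Euclidean norm 1 (or the zero vector).
#' @examples
#' l2Normalize(c(3, 4))   # c(0.6, 0.8)
#' @export
l2Normalize <- function(v) {
  assert_finite(v, "vector to normalise")
  n <- sqrt(sum(v^2))
  if (n == 0) {
    warning("zero vector cannot be L2-normalised; returned unchanged")
    return(v)
  }
  v / n
}

#' Pool a clip's frame descriptors into a ClipDescriptor
#'
#' Applies the selected temporal pooling operator and (by default)
#' L2-normalises the result, returning a tagged [ClipDescriptor-class].
#'
#' @inheritParams temporalMax
#' @param pooling `"tpmm"` (default), `"max"`, or `"mean"`.
#' @param modality `"appearance"` or `"motion"`.
#' @param normalize L2-normalise the pooled vector (default `TRUE`).
#' @return a [ClipDescriptor-class].
#' @export
poolClip <- function(frames, pooling = c("tpmm", "max", "mean"),
                     modality = c("appearance", "motion"), normalize = TRUE) {
  pooling <- match.arg(pooling)
  modality <- match.arg(modality)
  m <- as_frame_matrix(frames)
  v <- switch(pooling, tpmm = tpmm(m), max = temporalMax(m),
              mean = temporalMean(m))
  if (normalize) v <- l2Normalize(v)
  new("ClipDescriptor", values = v, poolingTag = pooling,
      modalityTag = modality, nFrames = ncol(m))
}

#' Early fusion of appearance and motion clip descriptors
#'
#' Concatenates the two streams' clip vectors ([appearance, motion]) and
#' re-normalises, doubling the descriptor length. Both inputs must carry
#' the same pooling tag.
#'
#' @param appearance,motion [ClipDescriptor-class] objects with matching
#'   pooling tags.
#' @param renormalize L2-normalise the fused vector (default `TRUE`).
#' @return a fused [ClipDescriptor-class] of doubled length.
#' @export
fuseClips <- function(appearance, motion, renormalize = TRUE) {
  stopifnot(is(appearance, "ClipDescriptor"), is(motion, "ClipDescriptor"))
  if (appearance@poolingTag != motion@poolingTag)
    stop("cannot fuse descriptors with different pooling tags: ",
         appearance@poolingTag, " vs ", motion@poolingTag, call. = FALSE)
  v <- c(appearance@values, motion@values)
  if (renormalize) v <- l2Normalize(v)
  new("ClipDescriptor", values = v, poolingTag = appearance@poolingTag,
      modalityTag = "fused", nFrames = appearance@nFrames)
}

#' Frame-level fusion of two descriptor sequences
#'
#' Concatenates per-frame appearance and motion descriptors column-wise
#' aligned in time, producing one d_a + d_m dimensional descriptor per
#' frame (12,288 for two MMSP streams). Both sequences must have equal
#' length, which the motion branch guarantees by padding.
#'
#' @param appearance,motion d x N frame-descriptor matrices.
#' @return (d_a + d_m) x N matrix.
#' @export
fuseFrameFeatures <- function(appearance, motion) {
  a <- as_frame_matrix(appearance); m <- as_frame_matrix(motion)
  if (ncol(a) != ncol(m))
    stop("appearance and motion sequences differ in length (", ncol(a),
         " vs ", ncol(m), ")", call. = FALSE)
  rbind(a, m)
}
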