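# Dense optical flow and its colour rendering.
#
# Flow is estimated coarse-to-fine with a pyramidal Lucas-Kanade scheme:
# Gaussian image pyramid, and at each level a few warp/solve iterations of
# the locally constant-flow normal equations with Gaussian window weights
# and Tikhonov-regularised 2x2 solves. Identical frames yield an exactly
# zero field. The field is rendered as an image with hue encoding flow
# direction (full hue circle) and saturation encoding magnitude.

# Bilinearly sample matrix m at (row + v, col + u); coordinates clamped.
warp_bilinear <- function(m, u, v) {
  h <- nrow(m); w <- ncol(m)
  rows <- matrix(seq_len(h), h, w) + v
  cols <- matrix(seq_len(w), h, w, byrow = TRUE) + u
  rows <- pmin(pmax(rows, 1), h); cols <- pmin(pmax(cols, 1), w)
  r0 <- floor(rows); c0 <- floor(cols)
  r1 <- pmin(r0 + 1, h); c1 <- pmin(c0 + 1, w)
  fr <- rows - r0; fc <- cols - c0
  at <- function(r, c) matrix(m[cbind(as.vector(r), as.vector(c))], h, w)
  (1 - fr) * (1 - fc) * at(r0, c0) + (1 - fr) * fc * at(r0, c1) +
    fr * (1 - fc) * at(r1, c0) + fr * fc * at(r1, c1)
}

lk_refine <- function(a, b, u, v, iterations, window_sigma, lambda) {
  for (it in seq_len(iterations)) {
    bw <- warp_bilinear(b, u, v)
    avg <- (a + bw) / 2
    h <- nrow(a); w <- ncol(a)
    ix <- (avg[, c(2:w, w)] - avg[, c(1, 1:(w - 1))]) / 2
    iy <- (avg[c(2:h, h), ] - avg[c(1, 1:(h - 1)), ]) / 2
    it_ <- bw - a
    k <- gaussian_kernel1d(window_sigma)
    a11 <- conv_sep(ix * ix, k) + lambda
    a12 <- conv_sep(ix * iy, k)
    a22 <- conv_sep(iy * iy, k) + lambda
    b1 <- conv_sep(ix * it_, k)
    b2 <- conv_sep(iy * it_, k)
    det <- a11 * a22 - a12 * a12
    du <- -(a22 * b1 - a12 * b2) / det
    dv <- -(a11 * b2 - a12 * b1) / det
    u <- gaussian_blur(u + du, 1)
    v <- gaussian_blur(v + dv, 1)
  }
  list(u = u, v = v)
}

#' Estimate dense optical flow between two frames
#'
#' Returns the per-pixel displacement that maps `frameA` onto `frameB`
#' (u positive rightwards, v positive downwards, in pixels per frame
#' interval). Frames are converted to grayscale internally and must share
#' dimensions. The estimate is deterministic for fixed parameters, and
#' exactly zero when the two frames are identical.
#'
#' @param frameA,frameB RGB arrays or grayscale matrices of equal size.
#' @param levels number of pyramid levels; `NULL` (default) picks
#'   `floor(log2(min(h, w) / 16)) + 1`, at least 1.
#' @param iterations warp/solve iterations per level (default 5).
#' @param windowSigma Gaussian window scale of the local solve, in pixels
#'   (default 3).
#' @param lambda Tikhonov regulariser added to the structure tensor
#'   diagonal (default 1e-3); keeps textureless pixels at zero flow.
#' @return a [FlowField-class].
#' @export
estimateFlow <- function(frameA, frameB, levels = NULL, iterations = 5,
                         windowSigma = 3, lambda = 1e-3) {
  a <- to_gray(frameA); b <- to_gray(frameB)
  if (!identical(dim(a), dim(b)))
    stop("frames differ in shape: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  if (is.null(levels))
    levels <- max(1L, as.integer(floor(log2(min(dim(a)) / 16))) + 1L)
  pyr_a <- list(a); pyr_b <- list(b)
  for (l in seq_len(levels - 1L)) {
    prev_a <- pyr_a[[l]]; prev_b <- pyr_b[[l]]
    nh <- max(2L, nrow(prev_a) %/% 2L); nw <- max(2L, ncol(prev_a) %/% 2L)
    pyr_a[[l + 1L]] <- bilinear_resize(gaussian_blur(prev_a, 1), nh, nw)
    pyr_b[[l + 1L]] <- bilinear_resize(gaussian_blur(prev_b, 1), nh, nw)
  }
  u <- matrix(0, nrow(pyr_a[[levels]]), ncol(pyr_a[[levels]]))
  v <- u
  for (l in rev(seq_len(levels))) {
    if (l < levels) {
      nh <- nrow(pyr_a[[l]]); nw <- ncol(pyr_a[[l]])
      u <- bilinear_resize(u, nh, nw) * (nw / ncol(pyr_a[[l + 1L]]))
      v <- bilinear_resize(v, nh, nw) * (nh / nrow(pyr_a[[l + 1L]]))
    }
    fl <- lk_refine(pyr_a[[l]], pyr_b[[l]], u, v, iterations, windowSigma, lambda)
    u <- fl$u; v <- fl$v
  }
  FlowField(u, v)
}

#' Render a flow field as a colour motion image
#'
#' Maps flow direction linearly onto the full hue circle (rightward motion
#' = hue 0) and flow magnitude onto saturation; the value (brightness)
#' channel is held at maximum, so zero-magnitude flow renders white (zero
#' saturation). With `magnitudeNorm = "per_frame"` the saturation is
#' min-max scaled to the frame's own maximum magnitude, making the image
#' invariant to a global rescaling of the field; `"fixed"` divides by `cap`
#' (saturating above it) for cross-clip comparability.
#'
#' @param flow a [FlowField-class].
#' @param magnitudeNorm `"per_frame"` (default) or `"fixed"`.
#' @param cap positive magnitude cap, required for `"fixed"`.
#' @return H x W x 3 RGB array in [0, 1].
#' @export
flowToImage <- function(flow, magnitudeNorm = c("per_frame", "fixed"), cap = NULL) {
  magnitudeNorm <- match.arg(magnitudeNorm)
  stopifnot(is(flow, "FlowField"))
  u <- flow@u; v <- flow@v
  if (!all(is.finite(u)) || !all(is.finite(v)))
    stop("flow field contains non-finite values", call. = FALSE)
  mag <- sqrt(u^2 + v^2)
  hue <- (atan2(v, u) %% (2 * pi)) / (2 * pi)
  sat <- if (magnitudeNorm == "per_frame") {
    m <- max(mag)
    if (m > 0) mag / m else mag
  } else {
    if (is.null(cap) || cap <= 0)
      stop("magnitudeNorm = 'fixed' requires a positive cap", call. = FALSE)
    pmin(mag / cap, 1)
  }
  hsv_to_rgb(hue, sat, matrix(1, nrow(u), ncol(u)))
}

#' Motion-image sequence aligned with a frame sequence
#'
#' Computes flow between consecutive sampled frames and renders each field
#' as a motion image. The final motion image is duplicated so the motion
#' sequence has exactly the same length as the frame sequence and the two
#' streams pool over identical temporal supports. A single-frame clip
#' yields one zero-flow (uniform, zero-saturation) image.
#'
#' @param frames non-empty list of RGB frames.
#' @param ... passed to [estimateFlow()].
#' @param magnitudeNorm,cap see [flowToImage()].
#' @return list of H x W x 3 motion images, same length as `frames`.
#' @export
motionImageSequence <- function(frames, magnitudeNorm = "per_frame",
                                cap = NULL, ...) {
  if (length(frames) == 0) stop("empty frame sequence", call. = FALSE)
  if (length(frames) == 1L) {
    g <- to_gray(frames[[1]])
    zero <- FlowField(matrix(0, nrow(g), ncol(g)), matrix(0, nrow(g), ncol(g)))
    return(list(flowToImage(zero, magnitudeNorm, cap)))
  }
  imgs <- vector("list", length(frames))
  for (i in seq_len(length(frames) - 1L)) {
    fl <- estimateFlow(frames[[i]], frames[[i + 1L]], ...)
    imgs[[i]] <- flowToImage(fl, magnitudeNorm, cap)
  }
  imgs[[length(frames)]] <- imgs[[length(frames) - 1L]]
  imgs
}

#' Write a motion image (or any [0,1] RGB array) as PNG for inspection
#'
#' @param image H x W x 3 array in [0, 1].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
writeImagePNG <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
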