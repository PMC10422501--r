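# Internal numeric helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All package randomness goes through this.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Bilinear resize of a numeric matrix to nh x nw, pixel-centre aligned,
# edges clamped (replicate).
bilinear_resize <- function(m, nh, nw) {
  h <- nrow(m); w <- ncol(m)
  if (nh == h && nw == w) return(m)
  sy <- (seq_len(nh) - 0.5) * h / nh + 0.5
  sx <- (seq_len(nw) - 0.5) * w / nw + 0.5
  y0 <- pmin(pmax(floor(sy), 1), h); x0 <- pmin(pmax(floor(sx), 1), w)
  y1 <- pmin(y0 + 1, h); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(sy - y0, 0), 1); fx <- pmin(pmax(sx - x0, 0), 1)
  outer(1 - fy, 1 - fx) * m[y0, x0, drop = FALSE] +
    outer(1 - fy, fx) * m[y0, x1, drop = FALSE] +
    outer(fy, 1 - fx) * m[y1, x0, drop = FALSE] +
    outer(fy, fx) * m[y1, x1, drop = FALSE]
}

# Area (block-mean) reduction of a matrix onto an nh x nw grid: every
# source pixel contributes to exactly one output cell.
block_mean_reduce <- function(m, nh, nw) {
  ri <- ceiling(seq_len(nrow(m)) * nh / nrow(m))
  ci <- ceiling(seq_len(ncol(m)) * nw / ncol(m))
  sums <- rowsum(t(rowsum(m, ri)), ci)
  counts <- tabulate(ri, nh) %o% tabulate(ci, nw)
  t(sums) / counts
}

# Resize an H x W x C array channel by channel.
resize_image <- function(img, nh, nw) {
  out <- array(0, c(nh, nw, dim(img)[3]))
  for (ch in seq_len(dim(img)[3])) out[, , ch] <- bilinear_resize(img[, , ch], nh, nw)
  out
}

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution with replicate border handling.
conv_sep <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  # rows
  idx <- function(i, n) pmin(pmax(i, 1L), n)
  out <- matrix(0, h, w)
  for (o in seq_along(k)) out <- out + k[o] * m[idx(seq_len(h) + o - r - 1L, h), , drop = FALSE]
  m <- out
  out <- matrix(0, h, w)
  for (o in seq_along(k)) out <- out + k[o] * m[, idx(seq_len(w) + o - r - 1L, w), drop = FALSE]
  out
}

gaussian_blur <- function(m, sigma) conv_sep(m, gaussian_kernel1d(sigma))

# Vectorised HSV -> RGB over same-shaped arrays, all components in [0, 1].
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  out <- array(0, c(dim(as.matrix(h)), 3))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}

# Luma conversion for flow estimation; accepts H x W or H x W x 3.
to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

assert_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}
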