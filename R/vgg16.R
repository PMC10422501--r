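# Plain-R VGG16 forward pass.
#
# Thirteen 3x3 stride-1 zero-padded convolutions with ReLU, arranged in
# five blocks of widths 64-64 / 128-128 / 256-256-256 / 512-512-512 /
# 512-512-512, each block followed by 2x2 stride-2 max pooling; a 224x224x3
# input therefore reaches pool5 as 7x7x512. fc6 (25088 -> 4096) and fc7
# (4096 -> 4096), both ReLU, complete the descriptor path. Convolutions run
# as im2col + one BLAS matmul per layer.
#
# Weight layout: each conv layer is a (9 * C_in) x C_out matrix whose rows
# are ordered channel-fastest within each of the nine (di, dj) kernel
# offsets, offsets in column-major (di fastest) order over the 3x3 window;
# biases are length-C_out vectors. fc weights are ordinary in x out
# matrices acting on the stackPool5() flattening. Architecture-only
# instantiation draws every weight from He-scaled normals under the
# backbone seed; biases are zero.

vgg_conv_widths <- list(c(64L, 64L), c(128L, 128L), c(256L, 256L, 256L),
                        c(512L, 512L, 512L), c(512L, 512L, 512L))

# 3x3 zero-padded convolution + ReLU via im2col.
conv3x3_relu <- function(x, W2, b) {
  d <- dim(x); h <- d[1]; w <- d[2]; cin <- d[3]
  xp <- array(0, c(h + 2L, w + 2L, cin))
  xp[2:(h + 1L), 2:(w + 1L), ] <- x
  cols <- matrix(0, h * w, 9L * cin)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    cols[, ((k - 1L) * cin + 1L):(k * cin)] <-
      matrix(xp[(1L + di):(h + di), (1L + dj):(w + dj), ], h * w, cin)
  }
  out <- cols %*% W2
  out <- sweep(out, 2L, b, "+")
  out[out < 0] <- 0
  array(out, c(h, w, ncol(W2)))
}

maxpool2 <- function(x) {
  d <- dim(x)
  ri <- seq(1L, d[1] - 1L, by = 2L); ci <- seq(1L, d[2] - 1L, by = 2L)
  pmax(x[ri, ci, , drop = FALSE], x[ri + 1L, ci, , drop = FALSE],
       x[ri, ci + 1L, , drop = FALSE], x[ri + 1L, ci + 1L, , drop = FALSE])
}

vgg_conv_weights <- function(backbone) {
  env <- backbone@env
  if (!is.null(env$user_weights)) return(env$user_weights$conv)
  if (is.null(env$conv)) {
    with_seed(backbone@seed, {
      cin <- 3L
      env$conv <- lapply(unlist(vgg_conv_widths), function(cout) {
        fanin <- 9L * cin
        W2 <- matrix(stats::rnorm(fanin * cout, sd = sqrt(2 / fanin)), fanin, cout)
        layer <- list(W = W2, b = numeric(cout))
        cin <<- cout
        layer
      })
    })
  }
  env$conv
}

vgg_fc_weights <- function(backbone) {
  env <- backbone@env
  if (!is.null(env$user_weights)) return(env$user_weights$fc)
  if (is.null(env$fc)) {
    # fc weights are ~120M parameters; built only when fc7 is requested.
    with_seed(backbone@seed + 1, {
      env$fc <- list(
        fc6 = list(W = matrix(stats::rnorm(25088 * 4096, sd = sqrt(2 / 25088)),
                              25088, 4096), b = numeric(4096)),
        fc7 = list(W = matrix(stats::rnorm(4096 * 4096, sd = sqrt(2 / 4096)),
                              4096, 4096), b = numeric(4096)))
    })
  }
  env$fc
}

#' VGG16 forward pass to pool5 or fc7
#'
#' Runs the convolutional stack (and, for `layer = "fc7"`, the first two
#' fully connected layers) on one preprocessed 224 x 224 x 3 frame. See the
#' source header for the exact weight layout accepted from
#' [vgg16Backbone()]'s `weights` argument.
#'
#' @param backbone a `Backbone` with provider `"vgg16"`.
#' @param image preprocessed 224 x 224 x 3 array ([preprocessFrame()]).
#' @param layer `"pool5"` (7 x 7 x 512 array) or `"fc7"` (length-4096
#'   vector).
#' @return array or vector as per `layer`.
#' @export
vggForward <- function(backbone, image, layer = c("pool5", "fc7")) {
  layer <- match.arg(layer)
  if (backbone@provider != "vgg16")
    stop("vggForward requires a vgg16 backbone", call. = FALSE)
  if (!identical(dim(image), c(224L, 224L, 3L)))
    stop("vgg16 expects a preprocessed 224 x 224 x 3 input; got ",
         paste(dim(image), collapse = "x"), call. = FALSE)
  conv <- vgg_conv_weights(backbone)
  x <- image
  li <- 0L
  for (block in vgg_conv_widths) {
    for (unused in block) {
      li <- li + 1L
      x <- conv3x3_relu(x, conv[[li]]$W, conv[[li]]$b)
    }
    x <- maxpool2(x)
  }
  if (layer == "pool5") return(x)
  fc <- vgg_fc_weights(backbone)
  v <- as.vector(stackPool5(x) %*% fc$fc6$W) + fc$fc6$b
  v[v < 0] <- 0
  v <- as.vector(v %*% fc$fc7$W) + fc$fc7$b
  v[v < 0] <- 0
  v
}
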