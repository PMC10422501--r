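#' Backbone: per-frame visual feature extraction providers
#'
#' A `Backbone` encapsulates one of two interchangeable per-frame feature
#' extractors:
#' \describe{
#'   \item{`mock`}{a deterministic, content-preserving extractor for tests
#'     and offline pipelines: the frame is block-averaged onto the 7 x 7
#'     cell grid and each cell's RGB value is expanded to 512 non-negative
#'     channels through a seeded random mixing matrix. Output is a pure
#'     function of (seed, image content) -- no model weights involved.}
#'   \item{`vgg16`}{a full VGG16 forward pass (thirteen 3 x 3
#'     zero-padded convolutions in five blocks with 2 x 2 max pooling,
#'     then fc6/fc7), instantiated architecture-only with seeded
#'     He-initialised weights unless a weight list is supplied. The pool5
#'     output is a 7 x 7 x 512 stack; fc7 is a 4096-vector. With random
#'     weights the representation is untrained; its shapes, determinism and
#'     non-negativity contracts are the ones relied upon here.}
#' }
#' Identical inputs always yield identical outputs (no stochastic layers at
#' inference); output shapes are provider-declared constants checked at
#' runtime.
#'
#' @slot provider `"mock"` or `"vgg16"`.
#' @slot seed integer seed the provider's parameters derive from.
#' @slot env environment holding lazily built provider parameters.
#' @name Backbone-class
#' @export
setClass("Backbone",
  representation(provider = "character", seed = "numeric", env = "environment"),
  validity = function(object) {
    if (!object@provider %in% c("mock", "vgg16"))
      return("provider must be 'mock' or 'vgg16'")
    TRUE
  })

setMethod("show", "Backbone", function(object) {
  cat(sprintf("Backbone provider '%s' (seed %d)\n", object@provider,
              as.integer(object@seed)))
  cat("  identifier:", backboneIdentifier(object), "\n")
})

#' @describeIn Backbone-class deterministic mock provider
#' @param seed integer seed for the provider's fixed random parameters.
#' @export
mockBackbone <- function(seed = 1) {
  new("Backbone", provider = "mock", seed = seed, env = new.env(parent = emptyenv()))
}

#' @describeIn Backbone-class VGG16 provider (architecture-only by default)
#' @param weights optional list of conv/fc weight matrices in the layout
#'   described in [vggForward()]; `NULL` (default) draws seeded
#'   He-initialised weights, i.e. an architecture-only instantiation.
#' @export
vgg16Backbone <- function(seed = 1, weights = NULL) {
  env <- new.env(parent = emptyenv())
  if (!is.null(weights)) env$user_weights <- weights
  new("Backbone", provider = "vgg16", seed = seed, env = env)
}

#' @describeIn Backbone-class a string identifying the provider and its
#'   weight provenance, recorded in run metadata.
#' @param backbone a `Backbone`.
#' @export
backboneIdentifier <- function(backbone) {
  if (backbone@provider == "mock")
    return(sprintf("mock-content-v1(seed=%d)", as.integer(backbone@seed)))
  if (!is.null(backbone@env$user_weights)) "vgg16(user-supplied weights)"
  else sprintf("vgg16-architecture-only(he-init, seed=%d)", as.integer(backbone@seed))
}

#' Prepare a frame for the VGG16 input contract
#'
#' Bilinearly resizes an RGB frame directly to 224 x 224 (no centre crop)
#' and standardises each channel with the ImageNet per-channel mean and
#' standard deviation (RGB order). Values above 1.5 are assumed to be on a
#' 0-255 scale and are rescaled first. Deterministic.
#'
#' @param image H x W x 3 numeric array.
#' @param size output side length (default 224).
#' @param mean,sd per-channel normalisation constants (RGB order).
#' @return size x size x 3 numeric array.
#' @export
preprocessFrame <- function(image, size = 224,
                            mean = c(0.485, 0.456, 0.406),
                            sd = c(0.229, 0.224, 0.225)) {
  if (is.matrix(image) || length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("preprocessFrame requires an RGB image (H x W x 3)", call. = FALSE)
  if (any(dim(image)[1:2] < 1)) stop("image has non-positive dimensions", call. = FALSE)
  if (max(image) > 1.5) image <- image / 255
  out <- resize_image(image, size, size)
  for (ch in 1:3) out[, , ch] <- (out[, , ch] - mean[ch]) / sd[ch]
  out
}

#' Extract the pool5 feature-map stack for one frame
#'
#' @param backbone a `Backbone`.
#' @param image for the `vgg16` provider, a preprocessed 224 x 224 x 3
#'   array (see [preprocessFrame()]); the `mock` provider accepts any RGB
#'   frame directly (values clamped to [0, 1]).
#' @return a 7 x 7 x 512 [FeatureMapStack-class], non-negative.
#' @export
setGeneric("extractPool5", function(backbone, image) standardGeneric("extractPool5"))

#' Extract the fc7 descriptor for one frame
#'
#' @inheritParams extractPool5
#' @return numeric vector of length 4096 (L2-normalise before
#'   classification use).
#' @export
setGeneric("extractFc7", function(backbone, image) standardGeneric("extractFc7"))

mock_params <- function(backbone) {
  if (is.null(backbone@env$mix)) {
    with_seed(backbone@seed, {
      backbone@env$mix <- matrix(abs(stats::rnorm(3 * 512)), 3, 512)
      backbone@env$proj <- matrix(stats::rnorm(1024 * 4096, sd = 1 / 32), 1024, 4096)
    })
  }
  backbone@env
}

check_rgb <- function(image) {
  if (is.matrix(image) || length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("an RGB image (H x W x 3) is required", call. = FALSE)
  image
}

#' @rdname extractPool5
setMethod("extractPool5", "Backbone", function(backbone, image) {
  check_rgb(image)
  if (backbone@provider == "mock") {
    p <- mock_params(backbone)
    img <- pmin(pmax(image, 0), 1)
    grid <- array(0, c(7, 7, 3))                    # 7 x 7 x 3 block means
    for (ch in 1:3) grid[, , ch] <- block_mean_reduce(img[, , ch], 7, 7)
    flat <- matrix(grid, 49, 3) %*% p$mix           # 49 x 512, non-negative
    out <- FeatureMapStack(array(flat, c(7, 7, 512)))
  } else {
    out <- FeatureMapStack(vggForward(backbone, image, layer = "pool5"))
  }
  d <- dim(out)
  if (!identical(d, c(7L, 7L, 512L)))
    stop("provider emitted an unexpected stack shape: ",
         paste(d, collapse = "x"), call. = FALSE)
  out
})

#' @rdname extractFc7
setMethod("extractFc7", "Backbone", function(backbone, image) {
  check_rgb(image)
  if (backbone@provider == "mock") {
    p <- mock_params(backbone)
    gray <- to_gray(pmin(pmax(image, 0), 1))
    g <- as.vector(bilinear_resize(gray, 32, 32))
    v <- as.vector(g %*% p$proj)
  } else {
    v <- vggForward(backbone, image, layer = "fc7")
  }
  if (length(v) != 4096)
    stop("provider emitted an fc7 vector of unexpected length ", length(v),
         call. = FALSE)
  v
})
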