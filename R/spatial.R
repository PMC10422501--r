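# Regional mean/max spatial pooling of convolutional feature maps (MMSP).
#
# The 7 x 7 activation grid is summarised over six fixed regions -- the
# whole grid, a 3 x 3 centre, and four 4 x 4 quadrants that deliberately
# overlap on row/column 4. Per-channel mean and max over each region give
# twelve pooled vectors, concatenated into one frame descriptor.

#' The six canonical pooling regions
#'
#' Returns the named region list used by the MMSP frame descriptor, as
#' inclusive 1-based (rows, cols) index ranges over a 7 x 7 cell grid:
#' whole = rows 1-7 x cols 1-7, center = 3-5 x 3-5, top_left = 1-4 x 1-4,
#' top_right = 1-4 x 4-7, bottom_left = 4-7 x 1-4, bottom_right = 4-7 x
#' 4-7. The four quadrants overlap on row/column 4 by construction.
#'
#' @return named list; each element has integer fields `rows` and `cols`
#'   (c(first, last), inclusive).
#' @examples
#' regionSpecs()$top_left
#' @export
regionSpecs <- function() {
  list(
    whole        = list(rows = c(1L, 7L), cols = c(1L, 7L)),
    center       = list(rows = c(3L, 5L), cols = c(3L, 5L)),
    top_left     = list(rows = c(1L, 4L), cols = c(1L, 4L)),
    top_right    = list(rows = c(1L, 4L), cols = c(4L, 7L)),
    bottom_left  = list(rows = c(4L, 7L), cols = c(1L, 4L)),
    bottom_right = list(rows = c(4L, 7L), cols = c(4L, 7L))
  )
}

# Accept either a plain 3-d array or a FeatureMapStack.
as_stack_array <- function(stack) {
  if (is(stack, "FeatureMapStack")) stack <- stack@.Data
  if (!is.array(stack) || length(dim(stack)) != 3)
    stop("expected a 3-d activation array (rows, cols, channels)", call. = FALSE)
  stack
}

resolve_region <- function(region, d) {
  if (is.character(region)) {
    specs <- regionSpecs()
    if (!region %in% names(specs))
      stop("unknown region name: ", region, call. = FALSE)
    region <- specs[[region]]
  }
  r <- as.integer(region$rows); cc <- as.integer(region$cols)
  if (r[1] < 1 || cc[1] < 1 || r[2] > d[1] || cc[2] > d[2] ||
      r[1] > r[2] || cc[1] > cc[2])
    stop("region [", r[1], ",", r[2], "]x[", cc[1], ",", cc[2],
         "] is out of bounds for a ", d[1], "x", d[2], " grid", call. = FALSE)
  list(rows = r, cols = cc)
}

region_submatrix <- function(stack, region) {
  stack <- as_stack_array(stack)
  d <- dim(stack)
  rg <- resolve_region(region, d)
  sub <- stack[rg$rows[1]:rg$rows[2], rg$cols[1]:rg$cols[2], , drop = FALSE]
  ncells <- dim(sub)[1] * dim(sub)[2]
  list(mat = matrix(sub, ncells, d[3]), ncells = ncells)
}

#' Per-channel regional mean pooling
#'
#' Averages the activation vectors of all cells in a region, element-wise
#' per channel. Two coefficient conventions are supported: `"true_mean"`
#' divides by the region's actual cell count (1/49 whole, 1/9 centre, 1/16
#' quadrants); `"ninth"` keeps a constant 1/9 coefficient for every
#' sub-region (1/49 for the whole grid), reproducing the alternative
#' printed-arithmetic convention for the 16-cell quadrants.
#'
#' @param stack a [FeatureMapStack-class] or 3-d array (rows, cols, channels).
#' @param region a region name from [regionSpecs()] or a list with `rows`
#'   and `cols` inclusive 1-based ranges.
#' @param mode `"true_mean"` (default) or `"ninth"`.
#' @return numeric vector of length `nChannels(stack)`.
#' @examples
#' st <- array(0, c(7, 7, 2)); st[1, 1, 1] <- 5
#' regionMean(st, "top_left")            # 5/16 in channel 1
#' regionMean(st, "top_left", "ninth")   # 5/9 in channel 1
#' @export
regionMean <- function(stack, region, mode = c("true_mean", "ninth")) {
  mode <- match.arg(mode)
  arr <- as_stack_array(stack)
  sub <- region_submatrix(arr, region)
  coef <- if (mode == "true_mean") 1 / sub$ncells
          else if (sub$ncells == prod(dim(arr)[1:2])) 1 / sub$ncells else 1 / 9
  colSums(sub$mat) * coef
}

#' Per-channel regional max pooling
#'
#' Element-wise maximum of the activation vectors over the region's cells.
#'
#' @inheritParams regionMean
#' @return numeric vector of length `nChannels(stack)`.
#' @export
regionMax <- function(stack, region) {
  sub <- region_submatrix(stack, region)
  do.call(pmax, lapply(seq_len(sub$ncells), function(i) sub$mat[i, ]))
}

#' MMSP frame descriptor
#'
#' Mean and max spatial pooling: the six regional means followed by the six
#' regional maxima, each region in the fixed order whole, center, top_left,
#' top_right, bottom_left, bottom_right. The descriptor length is 12 times
#' the channel count -- 6144 for a 7 x 7 x 512 stack.
#'
#' @inheritParams regionMean
#' @return numeric vector of length `12 * nChannels(stack)`, ordered as
#'   twelve channel-length blocks (six means then six maxima).
#' @examples
#' st <- array(runif(7 * 7 * 512), c(7, 7, 512))
#' length(mmsp(st))   # 6144
#' @export
mmsp <- function(stack, mode = c("true_mean", "ninth")) {
  mode <- match.arg(mode)
  regions <- names(regionSpecs())
  means <- lapply(regions, function(r) regionMean(stack, r, mode))
  maxes <- lapply(regions, function(r) regionMax(stack, r))
  c(unlist(means, use.names = FALSE), unlist(maxes, use.names = FALSE))
}

#' Stacked pool5 baseline descriptor
#'
#' Flattens every cell's channel vector into one long vector without any
#' pooling: cells are traversed in row-major order (row 1 left-to-right,
#' then row 2, ...), with the channel index varying fastest within a cell.
#' The value of cell (i, j), channel c lands at flat index
#' `((i - 1) * W + (j - 1)) * C + c`. Length is H x W x C = 25,088 for a
#' 7 x 7 x 512 stack.
#'
#' @param stack a [FeatureMapStack-class] or 3-d array.
#' @return numeric vector of length `prod(dim(stack))`.
#' @export
stackPool5 <- function(stack) {
  as.vector(aperm(as_stack_array(stack), c(3L, 2L, 1L)))
}
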