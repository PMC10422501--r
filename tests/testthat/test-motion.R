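test_that("identical frames give an exactly zero flow field", {
  img <- random_rgb(1, 48, 48)
  fl <- estimateFlow(img, img)
  expect_s4_class(fl, "FlowField")
  expect_lte(max(abs(flowU(fl))), 0.1)
  expect_lte(max(abs(flowV(fl))), 0.1)
})

test_that("flow recovers a known synthetic translation within one pixel", {
  spec <- syntheticSpec(preset = "separable", motionProfile = "translate",
                        shift = c(5, 0), nFrames = 3)
  vid <- genVideo(spec, 1, seed = 42)
  expect_equal(unname(vid$shifts[1, ]), c(5, 0))
  fl <- estimateFlow(vid$frames[[1]], vid$frames[[2]])
  s <- max(4, spec@frameSize %/% 4)
  pos <- vid$positions[1, ]
  rr <- pos[1]:(pos[1] + s - 1); cc <- pos[2]:(pos[2] + s - 1)
  expect_lt(abs(median(flowU(fl)[rr, cc]) - 5), 1)
  expect_lt(abs(median(flowV(fl)[rr, cc]) - 0), 1)
})

test_that("flow estimation rejects mismatched shapes", {
  expect_error(estimateFlow(random_rgb(1, 32, 32), random_rgb(1, 32, 40)),
               "differ in shape")
})

test_that("flow rendering maps direction to hue and magnitude to saturation", {
  # zero field: uniform image with zero saturation (white at full value)
  zero <- FlowField(matrix(0, 8, 8), matrix(0, 8, 8))
  img <- flowToImage(zero)
  expect_equal(dim(img), c(8, 8, 3))
  expect_true(all(img == 1))

  # uniform rightward flow: angle 0 -> hue 0 (pure red), uniform saturation
  right <- FlowField(matrix(2, 8, 8), matrix(0, 8, 8))
  ri <- flowToImage(right)
  expect_true(all(ri[, , 1] == 1))
  expect_equal(sd(ri[, , 2]), 0)
  expect_equal(sd(ri[, , 3]), 0)
  expect_lt(max(ri[, , 2]), 1e-12)  # full saturation kills green/blue

  # per-frame normalisation: global magnitude rescaling leaves the image
  set.seed(9)
  u <- matrix(rnorm(64), 8); v <- matrix(rnorm(64), 8)
  expect_equal(flowToImage(FlowField(u, v)),
               flowToImage(FlowField(3 * u, 3 * v)), tolerance = 1e-12)

  # fixed cap saturates and requires a cap
  capd <- flowToImage(FlowField(u, v), magnitudeNorm = "fixed", cap = 0.1)
  expect_true(all(capd >= 0 & capd <= 1))
  expect_error(flowToImage(FlowField(u, v), magnitudeNorm = "fixed"), "cap")
})

test_that("rotating every flow vector shifts hue by the matching fraction", {
  set.seed(10)
  u <- matrix(runif(36, 0.5, 1), 6); v <- matrix(0, 6, 6)
  for (theta in c(pi / 2, pi, 4)) {
    rot_u <- u * cos(theta) - v * sin(theta)
    rot_v <- u * sin(theta) + v * cos(theta)
    # recover hue from the rendered images via the hue of max channel math:
    # instead compare against a directly constructed expectation
    base_hue <- (atan2(v, u) %% (2 * pi)) / (2 * pi)
    rot_hue <- (atan2(rot_v, rot_u) %% (2 * pi)) / (2 * pi)
    expect_equal((base_hue + theta / (2 * pi)) %% 1, rot_hue, tolerance = 1e-9)
    # and the rendered image of the rotated field equals rendering with
    # shifted hue input
    expect_equal(flowToImage(FlowField(rot_u, rot_v)),
                 egopool:::hsv_to_rgb((base_hue + theta / (2 * pi)) %% 1,
                                      sqrt(u^2 + v^2) / max(sqrt(u^2 + v^2)),
                                      matrix(1, 6, 6)),
                 tolerance = 1e-9)
  }
})

test_that("motion sequences align with frame sequences", {
  spec <- syntheticSpec(preset = "separable", motionProfile = "translate",
                        shift = c(3, 0), nFrames = 5, frameSize = 32)
  vid <- genVideo(spec, 1, seed = 5)
  seq5 <- motionImageSequence(vid$frames)
  expect_length(seq5, 5)
  expect_identical(seq5[[5]], seq5[[4]])  # padded by duplication

  # single frame: one zero-saturation image
  seq1 <- motionImageSequence(vid$frames[1])
  expect_length(seq1, 1)
  expect_true(all(seq1[[1]] == 1))

  # static clip: all motion images ~ zero saturation (white)
  static_spec <- syntheticSpec(preset = "separable", motionProfile = "static",
                               nFrames = 3, frameSize = 32)
  svid <- genVideo(static_spec, 1, seed = 6)
  sseq <- motionImageSequence(svid$frames)
  for (im in sseq) expect_true(all(abs(im - 1) < 1e-8))

  expect_error(motionImageSequence(list()), "empty")
})
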