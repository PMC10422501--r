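test_that("regional means follow both coefficient conventions", {
  ones <- array(1, c(7, 7, 3))
  expect_equal(regionMean(ones, "whole"), rep(1, 3))

  # spike of 5 at cell (1,1) in channel 1
  st <- array(0, c(7, 7, 4)); st[1, 1, 1] <- 5
  expect_equal(regionMean(st, "whole")[1], 5 / 49)
  expect_equal(regionMean(st, "top_left")[1], 5 / 16)
  expect_equal(regionMean(st, "center")[1], 0)
  expect_equal(regionMean(st, "top_left", mode = "ninth")[1], 5 / 9)
  expect_equal(regionMean(st, "whole", mode = "ninth")[1], 5 / 49)
  expect_equal(regionMean(st, "center", mode = "ninth")[1], 0)

  expect_error(regionMean(st, list(rows = c(1, 9), cols = c(1, 7))), "out of bounds")
  expect_error(regionMean(st, "nowhere"), "unknown region")
})

test_that("regional max pools the element-wise maximum per channel", {
  st <- array(0, c(7, 7, 4)); st[1, 1, 2] <- 5
  expect_equal(regionMax(st, "whole")[2], 5)
  expect_equal(regionMax(st, "top_left")[2], 5)
  expect_equal(regionMax(st, "center")[2], 0)
  expect_equal(regionMax(st, "bottom_right")[2], 0)

  # permutation of cells within a region leaves the max unchanged
  set.seed(7)
  a <- array(rnorm(7 * 7 * 8), c(7, 7, 8))
  b <- a
  perm <- sample(16)
  cells <- expand.grid(i = 1:4, j = 1:4)
  for (ch in 1:8) {
    vals <- apply(cells, 1, function(cl) a[cl[1], cl[2], ch])
    for (k in seq_len(16)) b[cells$i[k], cells$j[k], ch] <- vals[perm[k]]
  }
  expect_equal(regionMax(b, "top_left"), regionMax(a, "top_left"))
})

test_that("quadrant regions overlap on row/column 4 as defined", {
  specs <- regionSpecs()
  expect_named(specs, c("whole", "center", "top_left", "top_right",
                        "bottom_left", "bottom_right"))
  expect_equal(specs$top_left$rows[2], 4)
  expect_equal(specs$bottom_right$rows[1], 4)
  # a value at (4, 4) reaches all four quadrants and the centre
  st <- array(0, c(7, 7, 1)); st[4, 4, 1] <- 9
  for (r in c("top_left", "top_right", "bottom_left", "bottom_right", "center"))
    expect_equal(regionMax(st, r), 9)
})

test_that("mmsp matches the brute-force oracle in both modes", {
  for (seed in 1:20) {
    st <- random_stack(seed, channels = 16)
    expect_equal(mmsp(st), oracle_mmsp(st, "true_mean"), tolerance = 1e-12)
    expect_equal(mmsp(st, "ninth"), oracle_mmsp(st, "ninth"), tolerance = 1e-12)
  }
})

test_that("mmsp satisfies its structural contracts", {
  st <- random_stack(1)
  v <- mmsp(st)
  expect_length(v, 12 * 512)

  # constant stack: every entry equals the constant
  const <- array(2.5, c(7, 7, 6))
  expect_equal(mmsp(const), rep(2.5, 72))

  # block order: six means then six maxima, each a channel-length block
  st2 <- array(0, c(7, 7, 2)); st2[1, 1, 1] <- 5
  v2 <- mmsp(st2)
  expect_equal(v2[1], 5 / 49)              # whole mean, channel 1
  expect_equal(v2[2 * 2 + 1], 5 / 16)      # third block: top_left mean
  expect_equal(v2[6 * 2 + 1], 5)           # seventh block: whole max

  # positive homogeneity: mmsp(lambda * x) = lambda * mmsp(x), lambda >= 0
  expect_equal(mmsp(st * 3.5), 3.5 * v, tolerance = 1e-12)

  # max dominates true mean per channel in every region
  for (r in names(regionSpecs()))
    expect_true(all(regionMax(st, r) >= regionMean(st, r) - 1e-12))
})

test_that("stacked pool5 flattening is a documented bijection", {
  st <- random_stack(3, channels = 512)
  flat <- stackPool5(st)
  expect_length(flat, 25088)

  # documented index: cell (i, j) channel c at ((i-1)*W + (j-1))*C + c
  sp <- array(0, c(7, 7, 512)); sp[2, 3, 10] <- 1
  expect_equal(which(stackPool5(sp) != 0), ((2 - 1) * 7 + (3 - 1)) * 512 + 10)

  # flatten then reshape recovers the stack
  back <- aperm(array(flat, c(512, 7, 7)), c(3, 2, 1))
  expect_equal(back, st)
})
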