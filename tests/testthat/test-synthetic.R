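test_that("synthetic generators are pure functions of (spec, seed)", {
  spec <- syntheticSpec(preset = "separable")
  s1 <- genFeatureStack(spec, 1, 99)
  s2 <- genFeatureStack(spec, 1, 99)
  expect_identical(s1@.Data, s2@.Data)
  expect_false(identical(genFeatureStack(spec, 1, 100)@.Data, s1@.Data))

  v1 <- genVideo(spec, 2, 7)
  v2 <- genVideo(spec, 2, 7)
  expect_identical(v1$frames, v2$frames)
  expect_identical(v1$shifts, v2$shifts)

  d1 <- genDataset(syntheticSpec(seed = 5), form = "features")
  d2 <- genDataset(syntheticSpec(seed = 5), form = "features")
  expect_equal(clipRecords(d1$manifest)$clip_id, clipRecords(d2$manifest)$clip_id)
  expect_identical(cacheGet(d1$cache, "s01_c01_r01", "appearance"),
                   cacheGet(d2$cache, "s01_c01_r01", "appearance"))
})

test_that("noise-free stacks are exactly baseline plus bump", {
  spec <- syntheticSpec(noiseSd = 0, signalStrength = 2)
  st <- genFeatureStack(spec, 1, 1)
  expect_true(all(st@.Data %in% c(1, 3)))
  # bump confined to the class region
  rg <- regionSpecs()[[spec@signalRegions[1]]]
  outside <- st@.Data[setdiff(1:7, rg$rows[1]:rg$rows[2]), , ]
  expect_true(all(outside == 1))
  expect_error(genFeatureStack(spec, 9, 1), "unknown class")
})

test_that("the class bump height matches its specification on average", {
  spec <- syntheticSpec(preset = "separable")   # strength 3, noise 0.5
  rg <- regionSpecs()[[spec@signalRegions[1]]]
  ch <- egopool:::signal_channels(spec, 1)
  diffs <- vapply(1:100, function(s) {
    st <- genFeatureStack(spec, 1, 1000 + s)@.Data
    inside <- mean(st[rg$rows[1]:rg$rows[2], rg$cols[1]:rg$cols[2], ch])
    outside <- mean(st[, , setdiff(1:512, ch)])
    inside - outside
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - spec@signalStrength), 3 * se + 0.02)
})

test_that("synthetic videos honour their motion profile", {
  static <- syntheticSpec(motionProfile = "static", nFrames = 4, frameSize = 32)
  vs <- genVideo(static, 1, 3)
  for (t in 2:4) expect_identical(vs$frames[[t]], vs$frames[[1]])
  expect_true(all(vs$shifts == 0))

  mov <- syntheticSpec(motionProfile = "translate", shift = c(5, 0),
                       nFrames = 4)
  vm <- genVideo(mov, 1, 3)
  expect_equal(unname(vm$shifts[, "dx"]), rep(5, 3))
  expect_equal(unname(vm$shifts[, "dy"]), rep(0, 3))

  # class-dependent motion differs between classes
  cd <- syntheticSpec(motionProfile = "class_dependent", nClasses = 2,
                      nFrames = 3)
  expect_false(identical(genVideo(cd, 1, 3)$shifts, genVideo(cd, 2, 3)$shifts))

  expect_error(syntheticSpec(frameSize = 8), "frameSize")
})

test_that("generated datasets are balanced and loadable", {
  spec <- syntheticSpec(nSubjects = 3, nClasses = 2, clipsPerSubjectClass = 2)
  ds <- genDataset(spec, form = "features")
  expect_equal(length(ds$manifest), 12)                    # 3 * 2 * 2
  expect_length(subjectIds(ds$manifest), 3)
  expect_length(classLabels(ds$manifest), 2)
  expect_equal(as.integer(table(clipRecords(ds$manifest)$label)), c(6L, 6L))

  # written manifest reloads identically
  reloaded <- readManifest(file.path(ds$dir, "manifest.csv"))
  expect_equal(clipRecords(reloaded), clipRecords(ds$manifest))

  # frames form writes decodable clips
  spec2 <- syntheticSpec(nSubjects = 2, nClasses = 2, clipsPerSubjectClass = 1,
                         nFrames = 3, frameSize = 32)
  ds2 <- genDataset(spec2, form = "frames")
  rec <- clipRecords(ds2$manifest)
  frames <- readFrames(rec$path[1])
  expect_length(frames, 3)
  expect_equal(dim(frames[[1]]), c(32, 32, 3))
})
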