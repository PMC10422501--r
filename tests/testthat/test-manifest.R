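test_that("manifest loading validates schema and content", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("clip_id,path,subject_id,label,native_fps",
               "c1,/tmp/a,s1,eat,30", "c2,/tmp/b,s1,read,30",
               "c3,/tmp/c,s2,eat,30", "c4,/tmp/d,s2,read,30"), tf)
  m <- readManifest(tf)
  expect_s4_class(m, "DatasetManifest")
  expect_equal(nrow(clipRecords(m)), 4)
  expect_equal(subjectIds(m), c("s1", "s2"))
  expect_equal(classLabels(m), c("eat", "read"))  # sorted distinct labels

  # missing column named in the error
  tf2 <- tempfile(fileext = ".csv")
  writeLines(c("clip_id,path,label,native_fps", "c1,/tmp/a,eat,30"), tf2)
  expect_error(readManifest(tf2), "subject_id")

  # duplicate clip_id rejected
  tf3 <- tempfile(fileext = ".csv")
  writeLines(c("clip_id,path,subject_id,label,native_fps",
               "c1,/tmp/a,s1,eat,30", "c1,/tmp/b,s2,read,30"), tf3)
  expect_error(readManifest(tf3), "duplicate")

  # empty file rejected
  tf4 <- tempfile(fileext = ".csv")
  writeLines("clip_id,path,subject_id,label,native_fps", tf4)
  expect_error(readManifest(tf4), "empty")

  expect_error(readManifest(tempfile()), "exist")
})

test_that("manifest write/read round-trip is the identity on all fields", {
  spec <- syntheticSpec(seed = 11)
  ds <- genDataset(spec, form = "features")
  tf <- tempfile(fileext = ".csv")
  writeManifest(ds$manifest, tf)
  back <- readManifest(tf)
  expect_equal(clipRecords(back), clipRecords(ds$manifest))
  expect_equal(classLabels(back), classLabels(ds$manifest))
  expect_equal(subjectIds(back), subjectIds(ds$manifest))
})

test_that("frame reading returns ordered, shape-consistent RGB frames", {
  d <- tempfile("frames-")
  dir.create(d)
  for (t in 1:5) {
    img <- array(t / 10, c(8, 6, 3))
    png::writePNG(img, file.path(d, sprintf("frame_%03d.png", t)))
  }
  frames <- readFrames(d)
  expect_length(frames, 5)
  # filename order preserved: frame t has constant intensity t/10
  vals <- vapply(frames, function(f) f[1, 1, 1], numeric(1))
  expect_equal(vals, (1:5) / 10, tolerance = 1e-2)
  expect_true(all(vapply(frames, function(f) all(dim(f) == c(8, 6, 3)), logical(1))))

  # corrupt file -> I/O error
  writeLines("not a png", file.path(d, "frame_000.png"))
  expect_error(readFrames(d), "decode")

  # empty directory -> empty-clip error
  d2 <- tempfile("frames-"); dir.create(d2)
  expect_error(readFrames(d2), "no decodable frames")

  # video container -> unsupported
  expect_error(readFrames("clip.mp4"), "not supported")
})

test_that("frame sampling follows stride arithmetic", {
  frames <- as.list(1:90)
  s1 <- sampleFrames(frames, 30, 1)
  expect_equal(unlist(s1), c(1, 31, 61))           # indices 0, 30, 60 (0-based)
  expect_length(sampleFrames(frames, 30, 10), 30)
  expect_equal(unlist(sampleFrames(list("only"), 1, 1)), "only")
  expect_error(sampleFrames(frames, 30, 60), "exceeds")
  expect_error(sampleFrames(frames, 30, 0), "targetFps")

  # property: output length is ceil(n / k) for stride k
  set.seed(42)
  for (case in 1:25) {
    n <- sample(1:200, 1)
    native <- sample(c(10, 24, 25, 30, 60), 1)
    target <- sample(c(1, 2, 5, 10), 1)
    if (target > native) next
    k <- max(1, round(native / target))
    expect_length(sampleFrames(as.list(seq_len(n)), native, target),
                  ceiling(n / k))
  }
})

test_that("feature cache round-trips bit-exactly and reports misses", {
  fc <- featureCache(tempfile("cache-"))
  m <- matrix(rnorm(60), 6)
  cachePut(fc, "clip/1", "appearance", m)
  expect_identical(cacheGet(fc, "clip/1", "appearance"), m)
  expect_true(cacheHas(fc, "clip/1", "appearance"))

  # miss is NULL, not an error, and distinct from a stored empty array
  expect_null(cacheGet(fc, "unknown", "appearance"))
  cachePut(fc, "empty", "motion", matrix(numeric(0), 0, 0))
  expect_false(is.null(cacheGet(fc, "empty", "motion")))

  # second write wins, with a message
  expect_message(cachePut(fc, "clip/1", "appearance", m * 2), "overwriting")
  expect_identical(cacheGet(fc, "clip/1", "appearance"), m * 2)

  expect_error(cachePut(fc, "bad", "appearance", matrix(NaN, 1)), "non-finite")
})
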