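test_that("confusion-matrix metrics match hand-worked values", {
  # rows = truth: C = [[3, 1], [2, 4]]
  cm <- matrix(c(3, 2, 1, 4), 2, dimnames = list(truth = c("a", "b"),
                                                 predicted = c("a", "b")))
  expect_equal(accuracy(cm), 70)
  expect_equal(unname(classPrecision(cm)), c(60, 80))
  expect_equal(averagePrecision(cm), 70)

  expect_equal(accuracy(diag(5) * 3), 100)
  expect_equal(accuracy(matrix(c(0, 5, 5, 0), 2)), 0)
  expect_equal(unname(classPrecision(diag(2))), c(100, 100))

  # never-predicted class contributes 0 by convention, with a note
  cm0 <- matrix(c(3, 2, 0, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_message(p <- classPrecision(cm0), "never predicted")
  expect_equal(unname(p), c(60, 0))

  # AP is invariant to a consistent permutation of classes
  set.seed(3)
  big <- matrix(rpois(16, 5), 4)
  perm <- sample(4)
  expect_equal(suppressMessages(averagePrecision(big[perm, perm])),
               suppressMessages(averagePrecision(big)))
})

test_that("confusion matrix accumulates truth rows and prediction columns", {
  cm <- confusionMatrix(c("a", "a", "b"), c("a", "b", "b"), classes = c("a", "b"))
  expect_equal(unname(cm), matrix(c(1, 0, 1, 1), 2))
  expect_equal(sum(cm), 3)
  expect_error(confusionMatrix("a", c("a", "b")), "length")
})

test_that("one-vs-all SVM separates constructed blobs and predicts deterministically", {
  blobs <- separable_blobs(1)
  model <- trainOvr(blobs$x, blobs$y, cost = 1)
  expect_s4_class(model, "OvRModel")
  expect_equal(modelClasses(model), c("a", "b"))
  expect_equal(predict(model, blobs$x), blobs$y)  # 100% training accuracy

  # duplicating every training row leaves the decision function unchanged
  model2 <- trainOvr(rbind(blobs$x, blobs$x), c(blobs$y, blobs$y), cost = 1)
  d1 <- predict(model, blobs$x, decisionValues = TRUE)
  d2 <- predict(model2, blobs$x, decisionValues = TRUE)
  expect_equal(d1, d2, tolerance = 1e-3)

  # contract errors
  expect_error(trainOvr(blobs$x, rep("a", nrow(blobs$x))), "at least 2 classes")
  xx <- blobs$x; xx[1, 1] <- NaN
  expect_error(trainOvr(xx, blobs$y), "non-finite")
  expect_error(predict(model, matrix(0, 1, 3)), "dimension")

  # exact ties break towards the first class in order
  sym <- new("OvRModel", weights = matrix(0, 4, 2), bias = c(0, 0),
             classes = c("a", "b"), cost = 1)
  expect_equal(predict(sym, rep(0, 4)), "a")
})

test_that("three-class one-vs-all assigns argmax labels on separated blobs", {
  set.seed(11)
  centres <- rbind(c(5, 0, 0), c(0, 5, 0), c(0, 0, 5))
  x <- do.call(rbind, lapply(1:3, function(k)
    matrix(rnorm(8 * 3, sd = 0.4), 8, 3) + rep(centres[k, ], each = 8)))
  y <- rep(c("x", "y", "z"), each = 8)
  model <- trainOvr(x, y)
  expect_equal(predict(model, x), y)
})

test_that("LOPO produces one fold per subject with no leakage and pooled metrics", {
  spec <- syntheticSpec(preset = "separable", seed = 21)
  ds <- genDataset(spec, form = "features")
  cfg <- runConfig(streams = "appearance")
  desc <- clipDescriptors(ds$manifest, cfg, ds$cache)
  res <- lopoEvaluate(ds$manifest, desc)

  fl <- foldLog(res)
  expect_equal(nrow(fl), length(subjectIds(ds$manifest)))  # one fold/subject
  expect_equal(sum(fl$nTest), length(ds$manifest))         # each clip once
  expect_equal(sum(confusionCounts(res)), length(ds$manifest))
  n <- length(ds$manifest)
  expect_true(all(fl$nTrain + fl$nTest == n))
  expect_equal(res@accuracy, 100 * sum(diag(confusionCounts(res))) / n)

  # separable construction reaches perfect accuracy
  expect_equal(res@accuracy, 100)
  expect_equal(res@averagePrecision, 100)
})

test_that("LOPO rejects degenerate designs", {
  rec <- toy_records(n_subjects = 1)
  m1 <- DatasetManifest(rec)
  expect_error(lopoEvaluate(m1, matrix(rnorm(nrow(rec) * 4), ncol = 4)),
               "2 subjects")
  rec2 <- toy_records()
  m2 <- DatasetManifest(rec2)
  expect_error(lopoEvaluate(m2, matrix(0, 3, 4)), "match")
  # single-class training fold: error by default, skippable when allowed
  rec3 <- toy_records(n_subjects = 2, n_classes = 2)
  rec3$label[rec3$subject_id == "subj1"] <- "act1"
  rec3$label[rec3$subject_id == "subj2"] <- "act2"
  m3 <- DatasetManifest(rec3)
  x3 <- matrix(rnorm(nrow(rec3) * 4), ncol = 4)
  expect_error(lopoEvaluate(m3, x3), "single class")
  # both folds are single-class, so two skip warnings are emitted
  expect_warning(expect_warning(
    r3 <- lopoEvaluate(m3, x3, skipBadFolds = TRUE), "skipped"), "skipped")
  expect_equal(nrow(foldLog(r3)), 0)
})

test_that("label-shuffled signal-free data scores at chance level", {
  spec <- syntheticSpec(preset = "noise", nSubjects = 5,
                        clipsPerSubjectClass = 4, seed = 2)
  ds <- genDataset(spec, form = "features", shuffleLabels = TRUE)
  cfg <- runConfig(streams = "appearance")
  res <- lopoEvaluate(ds$manifest, clipDescriptors(ds$manifest, cfg, ds$cache))
  n <- sum(confusionCounts(res))
  # central 95% binomial interval around chance (2 classes)
  lo <- 100 * qbinom(0.025, n, 0.5) / n
  hi <- 100 * qbinom(0.975, n, 0.5) / n
  expect_gte(res@accuracy, lo)
  expect_lte(res@accuracy, hi)
})

test_that("evaluation results serialise to JSON and CSV", {
  spec <- syntheticSpec(preset = "separable", seed = 31)
  ds <- genDataset(spec, form = "features")
  cfg <- runConfig(streams = "appearance")
  res <- lopoEvaluate(ds$manifest, clipDescriptors(ds$manifest, cfg, ds$cache),
                      config = unclass(cfg))
  prefix <- tempfile("result-")
  paths <- writeEvaluationResult(res, prefix)
  parsed <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(parsed$accuracy, 100)
  expect_equal(parsed$config$svmCost, 1)       # config echoed
  expect_equal(parsed$config$seed, 1)          # seeds recorded
  conf_csv <- read.csv(paste0(prefix, "_confusion.csv"), row.names = 1)
  expect_equal(sum(conf_csv), length(ds$manifest))
})
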