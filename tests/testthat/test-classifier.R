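test_that("softmax outputs are normalized for every input", {
  cfg <- testClassifierConfig()
  model <- buildClassifier(cfg, seed = 1L)
  withr::with_seed(2, {
    x <- array(runif(48 * 48 * 1 * 5), dim = c(48, 48, 1, 5))
  })
  p <- predictClassifier(model, x)
  expect_equal(dim(p), c(5L, 2L))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("builds with the same seed give identical initial predictions", {
  cfg <- testClassifierConfig()
  img <- makeChamberImage(SceneParams(nCells = 5L, seed = 1L))$image
  p1 <- predictClassifier(buildClassifier(cfg, seed = 5L), img)
  p2 <- predictClassifier(buildClassifier(cfg, seed = 5L), img)
  p3 <- predictClassifier(buildClassifier(cfg, seed = 6L), img)
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
})

test_that("the full-size default architecture forward-passes correctly", {
  # paper-scale config: 256x256x3 input, 256/128 conv filters, 128-128-64-2
  model <- buildClassifier(ClassifierConfig(), seed = 1L)
  expect_identical(dim(model$params$conv1W), c(2L * 2L * 3L, 256L))
  expect_identical(dim(model$params$conv2W), c(2L * 2L * 256L, 128L))
  expect_identical(ncol(model$params$dense4W), 2L)
  withr::with_seed(1, x <- array(runif(256 * 256 * 3), dim = c(256, 256, 3, 1)))
  p <- predictClassifier(model, x)
  expect_equal(sum(p), 1, tolerance = 1e-6)
})

test_that("training requires both classes and records one row per epoch", {
  cfg <- testClassifierConfig()
  model <- buildClassifier(cfg, seed = 1L)
  ds <- makeTrainingSet(5, 5, seed = 1L)
  oneClass <- list(images = ds$images[ds$labels == 1L],
                   labels = ds$labels[ds$labels == 1L])
  expect_error(trainClassifier(model, oneClass, TrainConfig()), "both classes")
  fit <- trainClassifier(model, ds, TrainConfig(epochs = 3L, batchSize = 4L,
                                                seed = 2L))
  expect_identical(nrow(fit$history), 3L)
  expect_named(fit$history, c("epoch", "trainLoss", "trainAccuracy",
                              "valAccuracy"))
})

test_that("a trained model separates chamber from clutter crops", {
  hist <- getTestModelHistory()
  expect_gte(utils::tail(hist$valAccuracy, 1), 0.9)
  model <- getTestModel()
  roi <- makeChamberImage(SceneParams(seed = 91L))$image[51:250, 51:250]
  non <- makeClutterImage(c(200L, 200L), clutterLevel = 0.8, seed = 91L)
  p <- predictClassifier(model, list(roi, non))
  expect_gt(p[1, "ROI"], 0.5)
  expect_lt(p[2, "ROI"], 0.5)
})

test_that("ROI-ness is invariant to horizontal flips", {
  model <- getTestModel()
  crops <- list(makeChamberImage(SceneParams(seed = 92L))$image,
                makeChamberImage(SceneParams(seed = 93L))$image[1:150, 1:150],
                makeClutterImage(c(300L, 300L), 0.7, seed = 92L))
  flipped <- lapply(crops, function(m) m[, ncol(m):1])
  p <- predictClassifier(model, crops)
  pf <- predictClassifier(model, flipped)
  expect_identical(p[, "ROI"] >= 0.5, pf[, "ROI"] >= 0.5)
})

test_that("models survive a save/load round trip with identical predictions", {
  model <- getTestModel()
  img <- makeChamberImage(SceneParams(seed = 94L))$image
  path <- withr::local_tempfile(fileext = ".rds")
  saveClassifier(model, path, TrainConfig(seed = 11L))
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$train_config$epochs, 10)
  expect_equal(side$train_config$batch_size, 32)
  reloaded <- loadClassifier(path)
  expect_identical(predictClassifier(model, img),
                   predictClassifier(reloaded, img))
})

test_that("training is reproducible under a fixed seed", {
  cfg <- testClassifierConfig()
  ds <- makeTrainingSet(30, 30, seed = 4L)
  tc <- TrainConfig(epochs = 2L, batchSize = 16L, seed = 9L)
  f1 <- trainClassifier(buildClassifier(cfg, seed = 9L), ds, tc)
  f2 <- trainClassifier(buildClassifier(cfg, seed = 9L), ds, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})
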