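# Reduced-size classifier used throughout the tests: the full-size default
# (256 px, 256/128 filters) is exercised for its structural contracts only,
# while behavioural tests train this configuration, which keeps grid and
# cell texture visible after downscaling yet trains in seconds.
testClassifierConfig <- function() {
  ClassifierConfig(inputSize = c(48L, 48L), channels = 1L,
                   convFilters = c(32L, 16L),
                   denseUnits = c(64L, 64L, 32L, 2L))
}

.modelCache <- new.env(parent = emptyenv())

# one trained model shared across test files
getTestModel <- function() {
  if (is.null(.modelCache$model)) {
    ds <- makeTrainingSet(200, 200, seed = 11L)
    fit <- trainClassifier(buildClassifier(testClassifierConfig(), seed = 11L),
                           ds, TrainConfig(seed = 11L))
    .modelCache$model <- fit$model
    .modelCache$history <- fit$history
  }
  .modelCache$model
}

getTestModelHistory <- function() {
  getTestModel()
  .modelCache$history
}
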