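# The published two-class performance table for the ROI classifier is
# reproduced by the confusion matrix (Non-ROI: 41 correct / 2 misclassified,
# ROI: 15 / 0); its raw ratios are asserted unrounded, the display values
# after two-decimal rounding.
table1Counts <- rbind(c(41, 2), c(0, 15))

test_that("per-class metrics reproduce the published table values", {
  cm <- confusionMatrix2(table1Counts)
  pc <- classMetrics(cm)
  roi <- pc[pc$class == "ROI", ]
  expect_equal(roi$precision, 15 / 17)
  expect_equal(roi$recall, 1)
  expect_equal(roi$f1, 2 * (15 / 17) / (15 / 17 + 1))
  expect_equal(round(c(roi$precision, roi$recall, roi$f1), 2), c(0.88, 1, 0.94))
  expect_identical(roi$support, 15)
  non <- pc[pc$class == "Non-ROI", ]
  expect_equal(non$precision, 1)
  expect_equal(non$recall, 41 / 43)
  expect_equal(round(c(non$precision, non$recall, non$f1), 2), c(1, 0.95, 0.98))
  expect_identical(non$support, 43)
})

test_that("aggregate metrics reproduce accuracy, macro and weighted rows", {
  rep <- aggregateMetrics(confusionMatrix2(table1Counts))
  expect_equal(rep@accuracy, 56 / 58)
  expect_equal(round(rep@accuracy, 2), 0.97)
  expect_equal(rep@macroRecall, (41 / 43 + 1) / 2)
  expect_equal(round(c(rep@macroPrecision, rep@macroRecall, rep@macroF1), 2),
               c(0.94, 0.98, 0.96))
  expect_equal(round(c(rep@weightedPrecision, rep@weightedRecall,
                       rep@weightedF1), 2), c(0.97, 0.97, 0.97))
  expect_identical(rep@total, 58L)
})

test_that("confusion matrices tally raw label/prediction pairs", {
  withr::with_seed(55, {
    labels <- rbinom(20, 1, 0.4)
    preds <- rbinom(20, 1, 0.5)
  })
  cm <- confusionFrom(labels, preds)
  hand <- matrix(0, 2, 2)
  for (i in seq_along(labels))
    hand[labels[i] + 1, preds[i] + 1] <- hand[labels[i] + 1, preds[i] + 1] + 1
  expect_equal(cm@counts, hand)
  expect_equal(sum(cm@counts), 20)
  # perfect predictions: zero off-diagonal
  perfect <- confusionFrom(labels, labels)
  expect_equal(sum(perfect@counts) - sum(diag(perfect@counts)), 0)
  # all-ROI predictions leave no true negatives for the ROI-positive framing
  allRoi <- confusionFrom(labels, rep(1, 20))
  expect_equal(allRoi@counts[1, 1], 0)
  expect_error(confusionFrom(c(0, 1), c(0)), "equal length")
  expect_error(confusionFrom(c(0, 2), c(0, 1)), "0 .* or 1")
})

test_that("zero-denominator metrics follow the documented convention", {
  cm <- confusionMatrix2(rbind(c(5, 0), c(3, 0)))  # nothing predicted ROI
  expect_warning(pc <- classMetrics(cm), "precision")
  expect_equal(pc$precision[pc$class == "ROI"], 0)
  single <- confusionMatrix2(rbind(c(7, 0), c(0, 0)))  # one class, all correct
  w <- capture_warnings(rep <- aggregateMetrics(single))
  expect_gte(length(w), 1)
  expect_equal(rep@accuracy, 1)
})

test_that("metrics agree with an independent reference implementation", {
  skip_if_not_installed("caret")
  withr::with_seed(99, {
    for (i in 1:100) {
      counts <- matrix(rpois(4, 10) + 1, 2, 2)
      cm <- confusionMatrix2(counts)
      rep <- aggregateMetrics(cm)
      truth <- factor(rep(c(0, 0, 1, 1), counts[cbind(c(1, 1, 2, 2),
                                                      c(1, 2, 1, 2))]),
                      levels = c(0, 1))
      pred <- factor(rep(c(0, 1, 0, 1), counts[cbind(c(1, 1, 2, 2),
                                                     c(1, 2, 1, 2))]),
                     levels = c(0, 1))
      ref <- caret::confusionMatrix(pred, truth, positive = "1")
      expect_equal(rep@accuracy, unname(ref$overall["Accuracy"]))
      roi <- rep@perClass[rep@perClass$class == "ROI", ]
      expect_equal(roi$recall, unname(ref$byClass["Sensitivity"]))
      expect_equal(roi$precision, unname(ref$byClass["Pos Pred Value"]))
      non <- rep@perClass[rep@perClass$class == "Non-ROI", ]
      expect_equal(non$recall, unname(ref$byClass["Specificity"]))
    }
  })
})

test_that("weighted recall equals accuracy and balanced supports collapse", {
  withr::with_seed(123, {
    for (i in 1:25) {
      counts <- matrix(rpois(4, 8) + 1, 2, 2)
      rep <- aggregateMetrics(confusionMatrix2(counts))
      expect_equal(rep@weightedRecall, rep@accuracy)
    }
  })
  bal <- aggregateMetrics(confusionMatrix2(rbind(c(8, 2), c(3, 7))))
  expect_equal(bal@macroPrecision, bal@weightedPrecision)
  expect_equal(bal@macroRecall, bal@weightedRecall)
})

test_that("counting accuracy implements measured/actual x 100", {
  expect_equal(countingAccuracy(100, 100),
               c(accuracy = 100, error = 0))
  expect_equal(countingAccuracy(99, 100), c(accuracy = 99, error = 1))
  expect_equal(unname(countingAccuracy(246, 250)["accuracy"]), 98.4)
  # overcounts are penalized symmetrically
  expect_equal(unname(countingAccuracy(104, 100)["error"]), 4)
  expect_error(countingAccuracy(10, 0), "positive")
})

test_that("the plain-text table mirrors the published layout", {
  lines <- formatMetricsTable(aggregateMetrics(confusionMatrix2(table1Counts)))
  expect_length(lines, 6)
  expect_match(lines[1], "Precision\\s+Recall\\s+F1-score\\s+Support")
  expect_match(lines[2], "NON-ROI\\s+1.00\\s+0.95\\s+0.98\\s+43")
  expect_match(lines[3], "ROI\\s+0.88\\s+1.00\\s+0.94\\s+15")
  expect_match(lines[4], "Accuracy\\s+-\\s+-\\s+0.97\\s+58")
})
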