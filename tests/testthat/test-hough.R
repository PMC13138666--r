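test_that("a blank image yields no circles", {
  out <- houghCircles(matrix(0, 50, 50), HoughParams())
  expect_identical(nrow(out), 0L)
})

test_that("single-circle detection matches the exhaustive accumulator oracle", {
  edges <- drawRing(matrix(0, 100, 100), cx = 50, cy = 50, r = 10)
  p <- HoughParams(param1 = 50, param2 = 20, minRadius = 5, maxRadius = 15,
                   minCenterDist = 10)
  det <- houghCircles(edges, p)
  ora <- oracleHoughCircles(edges, 5, 15, minCenterDist = 10)
  expect_identical(nrow(det), 1L)
  expect_gte(nrow(ora), 1L)
  expect_lte(abs(det$a[1] - ora$a[1]), 2)
  expect_lte(abs(det$b[1] - ora$b[1]), 2)
  expect_lte(abs(det$r[1] - ora$r[1]), 2)
  expect_lte(abs(det$a[1] - 50), 2)
  expect_lte(abs(det$r[1] - 10), 2)
})

test_that("two separated circles are both recovered, matching the oracle", {
  edges <- matrix(0, 100, 100)
  edges <- drawRing(edges, cx = 30, cy = 50, r = 8)
  edges <- drawRing(edges, cx = 70, cy = 50, r = 8)
  p <- HoughParams(param1 = 50, param2 = 18, minRadius = 5, maxRadius = 12,
                   minCenterDist = 15)
  det <- houghCircles(edges, p)
  ora <- oracleHoughCircles(edges, 5, 12, minCenterDist = 15)
  expect_identical(nrow(det), 2L)
  expect_identical(nrow(ora), 2L)
  det <- det[order(det$a), ]; ora <- ora[order(ora$a), ]
  expect_true(all(abs(det$a - ora$a) <= 2))
  expect_true(all(abs(det$b - ora$b) <= 2))
  expect_true(all(abs(det$r - ora$r) <= 2))
  expect_true(all(abs(det$a - c(30, 70)) <= 2))
})

test_that("raising param2 filters detections monotonically (subset property)", {
  sc <- makeChamberImage(SceneParams(nCells = 30L, seed = 13L))
  prev <- NULL
  for (p2 in c(10, 18, 30, 45)) {
    det <- houghCircles(sc$image, HoughParams(param2 = p2))
    keys <- paste(det$a, det$b, det$r)
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("detected radii stay inside the configured band", {
  sc <- makeChamberImage(SceneParams(seed = 21L))
  det <- houghCircles(sc$image, HoughParams(minRadius = 4, maxRadius = 12))
  expect_true(all(det$r >= 4 & det$r <= 12))
  d <- as.matrix(dist(det[, c("a", "b")]))
  diag(d) <- Inf
  expect_true(all(d >= HoughParams()@minCenterDist))
})

test_that("perimeter verification scores support and filters accordingly", {
  edges <- drawRing(matrix(0, 60, 60), cx = 30, cy = 30, r = 10)
  onRing <- data.frame(a = 30, b = 30, r = 10)
  v <- verifyPerimeter(onRing, edges, supportThreshold = 0.3)
  expect_gte(v$support, 0.95)
  expect_true(v$accepted)
  offRing <- data.frame(a = 12, b = 45, r = 5)
  v2 <- verifyPerimeter(offRing, edges, supportThreshold = 0.3)
  expect_identical(v2$support, 0)
  expect_false(v2$accepted)
  expect_true(verifyPerimeter(offRing, edges, supportThreshold = 0)$accepted)
})

test_that("raising the support threshold never accepts more circles", {
  sc <- makeChamberImage(SceneParams(seed = 31L))
  cfgs <- lapply(c(0, 0.3, 0.6, 0.9), function(th)
    CounterConfig(supportThreshold = th))
  counts <- vapply(cfgs, function(cf) nCells(countChamber(sc$image, cf)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("Hough parameters are validated", {
  expect_error(HoughParams(param2 = 0), "param")
  expect_error(HoughParams(minRadius = 8, maxRadius = 4), "radius")
  expect_error(HoughParams(accumulatorResolution = 0.5), "accumulatorResolution")
})
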