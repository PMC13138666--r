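test_that("empty scene contains only grid and noise", {
  sc <- makeChamberImage(SceneParams(nCells = 0L, seed = 1L))
  expect_identical(nCells(sc$truth), 0L)
  expect_identical(nrow(sc$truth@cells), 0L)
  expect_equal(dim(sc$image), c(400L, 400L))
  expect_true(all(sc$image >= 0 & sc$image <= 255))
})

test_that("the generator is a pure function of its parameters", {
  p <- SceneParams(nCells = 20L, seed = 7L)
  a <- makeChamberImage(p)
  b <- makeChamberImage(p)
  expect_identical(a$image, b$image)
  expect_identical(a$truth@cells, b$truth@cells)
  c <- makeChamberImage(SceneParams(nCells = 20L, seed = 8L))
  expect_false(identical(a$image, c$image))
  # generation does not disturb the global RNG stream
  set.seed(42); before <- runif(3)
  set.seed(42); invisible(makeChamberImage(p)); after <- runif(3)
  expect_identical(before, after)
})

test_that("cell placement honors the minimum center separation exactly", {
  p <- SceneParams(nCells = 50L, minCenterSeparation = 20, seed = 7L)
  sc <- makeChamberImage(p)
  expect_identical(nCells(sc$truth), 50L)
  cells <- sc$truth@cells
  d <- as.matrix(dist(cells[, c("x", "y")]))
  diag(d) <- Inf
  expect_true(all(d >= 20))
  expect_true(all(cells$r >= 6 & cells$r <= 10))
})

test_that("impossible placements raise an explicit error", {
  p <- SceneParams(imageSize = c(60L, 60L), nCells = 40L,
                   minCenterSeparation = 20, seed = 1L)
  expect_error(makeChamberImage(p), class = "hemocount_placementError")
})

test_that("phone scenes paste the chamber verbatim at the recorded box", {
  p <- SceneParams(nCells = 15L, seed = 3L)
  ph <- makePhoneImage(p, clutterLevel = 0.5)
  box <- roiBox(ph$truth)
  expect_s4_class(box, "RegionBox")
  chamber <- makeChamberImage(p)
  inside <- ph$image[(box@y0 + 1):box@y1, (box@x0 + 1):box@x1]
  expect_identical(inside, chamber$image)
  # truth cells are inside the box, in canvas coordinates
  cells <- ph$truth@cells
  expect_true(all(cells$x >= box@x0 & cells$x < box@x1))
  expect_true(all(cells$y >= box@y0 & cells$y < box@y1))
  # reproducible
  ph2 <- makePhoneImage(p, clutterLevel = 0.5)
  expect_identical(ph$image, ph2$image)
})

test_that("zero clutter leaves a uniform background outside the box", {
  p <- SceneParams(nCells = 5L, seed = 9L)
  ph <- makePhoneImage(p, clutterLevel = 0)
  box <- roiBox(ph$truth)
  outside <- ph$image
  outside[(box@y0 + 1):box@y1, (box@x0 + 1):box@x1] <- NA
  expect_identical(unique(as.vector(outside[!is.na(outside)])), 90)
})

test_that("oversized chambers are rejected", {
  expect_error(makePhoneImage(SceneParams(seed = 1L), canvasSize = c(300L, 300L)),
               "canvas")
})

test_that("training sets have the requested class composition", {
  ds <- makeTrainingSet(15, 43, seed = 2L)
  expect_length(ds$images, 58)
  expect_identical(sum(ds$labels == 1L), 15L)
  expect_identical(sum(ds$labels == 0L), 43L)
  ds2 <- makeTrainingSet(15, 43, seed = 2L)
  expect_identical(ds$images, ds2$images)
  tiny <- makeTrainingSet(1, 1, seed = 1L)
  expect_setequal(tiny$labels, c(0L, 1L))
  expect_error(makeTrainingSet(0, 5))
})

test_that("scene files round-trip through the JSON sidecar", {
  dir <- withr::local_tempdir()
  sc <- makePhoneImage(SceneParams(nCells = 8L, seed = 5L))
  png <- file.path(dir, "s.png"); js <- file.path(dir, "s.json")
  writeScene(sc, png, js)
  expect_true(file.exists(png) && file.exists(js))
  truth <- readSceneTruth(js)
  expect_equal(truth@count, sc$truth@count)
  expect_equal(truth@cells$x, sc$truth@cells$x)
  expect_equal(truth@roiBox@x0, sc$truth@roiBox@x0)
  # chamber scene: null roi_box
  ch <- makeChamberImage(SceneParams(nCells = 2L, seed = 5L))
  writeScene(ch, png, js)
  expect_null(readSceneTruth(js)@roiBox)
})
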