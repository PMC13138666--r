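test_that("grayscale conversion uses BT.601 luminance", {
  rgb <- array(0, c(4, 4, 3))
  rgb[, , 1] <- 120; rgb[, , 2] <- 120; rgb[, , 3] <- 120
  expect_equal(toGrayscale(rgb), matrix(120, 4, 4))
  red <- array(0, c(2, 2, 3)); red[, , 1] <- 255
  expect_true(all(abs(toGrayscale(red) - 76) <= 1))  # 0.299 * 255
  expect_true(all(toGrayscale(red) >= 0 & toGrayscale(red) <= 255))
  expect_error(toGrayscale(array(0, c(3, 3, 2))), "planes")
})

test_that("an empty chamber and a grid-only crop both count zero", {
  empty <- makeChamberImage(SceneParams(nCells = 0L, seed = 1L))
  expect_identical(nCells(countChamber(empty$image)), 0L)
  # grid lines must not be mistaken for cells
  gridOnly <- makeChamberImage(SceneParams(nCells = 0L, seed = 17L,
                                           noiseSd = 8, gridLineWidth = 3L))
  expect_identical(nCells(countChamber(gridOnly$image)), 0L)
})

test_that("a 50-cell chamber is counted within 5 percent", {
  sc <- makeChamberImage(SceneParams(seed = 5L))
  cc <- countChamber(sc$image)
  expect_lte(abs(nCells(cc) - 50) / 50, 0.05)
  expect_identical(nCells(cc), nrow(circles(cc)))
  expect_true(all(circles(cc)$support >= CounterConfig()@supportThreshold))
  # detected centers line up with true cells: every detection near a truth cell
  truthXY <- sc$truth@cells
  d <- sqrt(outer(circles(cc)$a, truthXY$x, "-")^2 +
            outer(circles(cc)$b, truthXY$y, "-")^2)
  expect_lte(max(apply(d, 1, min)), 3)
})

test_that("counting works on RGB crops too", {
  sc <- makeChamberImage(SceneParams(nCells = 12L, seed = 23L))
  rgb <- array(rep(sc$image, 3), dim = c(dim(sc$image), 3))
  expect_equal(nCells(countChamber(rgb)), nCells(countChamber(sc$image)))
})

test_that("aggregation implements mean x dilution x 1e4 cells/mL", {
  fakeChamber <- function(i, n) {
    circ <- data.frame(a = seq_len(n), b = seq_len(n), r = rep(6, n),
                       support = rep(1, n))
    if (n == 0) circ <- circ[0, ]
    hemocount:::ChamberCount(i, circ)
  }
  chs <- lapply(0:3, fakeChamber, n = 200)
  rep1 <- aggregateReport(chs, dilutionFactor = 1)
  expect_equal(concentration(rep1), 2e6)
  expect_identical(nCells(rep1), 800L)
  expect_equal(rep1@meanPerChamber, 200)
  zero <- aggregateReport(lapply(0:3, fakeChamber, n = 0), 1)
  expect_equal(concentration(zero), 0)
  rep2 <- aggregateReport(chs, dilutionFactor = 2)
  expect_equal(concentration(rep2), 2 * concentration(rep1))
  expect_error(aggregateReport(chs[1:3], 1), "4 chambers")
  part <- aggregateReport(chs[1:2], 1, allowPartial = TRUE)
  expect_equal(concentration(part), 2e6)
  expect_error(aggregateReport(chs, 0), "dilutionFactor")
})

test_that("count reports serialize with the documented schema", {
  sc <- makeChamberImage(SceneParams(nCells = 10L, seed = 2L))
  ch <- countChamber(sc$image)
  reps <- lapply(0:3, function(i) { x <- ch; x@chamberIndex <- i; x })
  report <- aggregateReport(reps, 1.5, cellType = "PC3")
  path <- withr::local_tempfile(fileext = ".json")
  writeCountReport(report, path)
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_named(js, c("cell_type", "chambers", "total", "mean", "dilution",
                     "concentration_cells_per_ml"))
  expect_length(js$chambers, 4)
  expect_equal(js$total, report@total)
  expect_equal(js$concentration_cells_per_ml, concentration(report))
  expect_length(js$chambers[[1]]$circles[[1]], 4)
})

test_that("overlays draw detections in red on an RGB canvas", {
  sc <- makeChamberImage(SceneParams(nCells = 5L, seed = 3L))
  cc <- countChamber(sc$image)
  ov <- drawOverlay(sc$image, circles(cc))
  expect_equal(dim(ov), c(dim(sc$image), 3))
  reds <- ov[, , 1] == 255 & ov[, , 2] == 0
  expect_gt(sum(reds), 0)
})
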