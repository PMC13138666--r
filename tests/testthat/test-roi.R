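test_that("proposals stay within bounds and respect the cap", {
  ph <- makePhoneImage(SceneParams(seed = 0L))
  boxes <- proposeRegions(ph$image, 200L)
  expect_gt(length(boxes), 0)
  expect_lte(length(boxes), 200L)
  for (b in boxes) {
    expect_gte(b@x0, 0); expect_gte(b@y0, 0)
    expect_lte(b@x1, ncol(ph$image)); expect_lte(b@y1, nrow(ph$image))
    expect_gt(b@x1, b@x0); expect_gt(b@y1, b@y0)
  }
  expect_lte(length(proposeRegions(ph$image, 1L)), 1L)
  expect_error(proposeRegions(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("at least one proposal overlaps the true chamber box at IoU >= 0.5", {
  ph <- makePhoneImage(SceneParams(seed = 0L))
  boxes <- proposeRegions(ph$image, 200L)
  ious <- vapply(boxes, boxIoU, numeric(1), b = roiBox(ph$truth))
  expect_gte(max(ious), 0.5)
})

test_that("preprocessCrop resizes to the requested shape and scales to [0,1]", {
  img <- makeChamberImage(SceneParams(seed = 1L))$image
  out <- preprocessCrop(img, RegionBox(50, 80, 250, 300), size = c(256L, 256L))
  expect_equal(dim(out), c(256L, 256L))
  expect_true(all(out >= 0 & out <= 1))
  # full-image box at native size: pure rescaling
  small <- img[1:64, 1:64]
  ident <- preprocessCrop(small, RegionBox(0, 0, 64, 64), size = c(64L, 64L))
  expect_equal(ident, small / 255)
  # constant in, constant out
  flat <- matrix(100, 40, 40)
  expect_equal(unique(as.vector(preprocessCrop(flat, RegionBox(0, 0, 40, 40),
                                               c(16L, 16L)))), 100 / 255)
  expect_error(preprocessCrop(small, RegionBox(0, 0, 100, 100)), "bounds")
})

test_that("extractRoi recovers the chamber from a cluttered phone scene", {
  model <- getTestModel()
  ph <- makePhoneImage(SceneParams(seed = 0L))
  res <- extractRoi(ph$image, model)
  expect_s4_class(res$region, "ClassifiedRegion")
  expect_identical(res$region@label, 1L)
  expect_gte(boxIoU(res$region@box, roiBox(ph$truth)), 0.5)
  b <- res$region@box
  expect_equal(dim(res$crop), c(b@y1 - b@y0, b@x1 - b@x0))
})

test_that("clutter-only scenes yield an explicit no-ROI outcome", {
  model <- getTestModel()
  clutter <- makeClutterImage(c(600L, 600L), clutterLevel = 0.6, seed = 5L)
  expect_error(extractRoi(clutter, model), class = "hemocount_noRoiFound")
})

test_that("a chamber-only image is accepted nearly whole", {
  model <- getTestModel()
  ch <- makeChamberImage(SceneParams(seed = 4L))
  res <- extractRoi(ch$image, model)
  expect_gte(boxArea(res$region@box) / prod(dim(ch$image)), 0.5)
})

test_that("region boxes validate their geometry", {
  expect_error(RegionBox(10, 0, 5, 20), "x1")
  expect_error(RegionBox(0, 10, 5, 5), "y1")
  expect_equal(boxIoU(RegionBox(0, 0, 10, 10), RegionBox(0, 0, 10, 10)), 1)
  expect_equal(boxIoU(RegionBox(0, 0, 10, 10), RegionBox(20, 20, 30, 30)), 0)
  expect_equal(boxIoU(RegionBox(0, 0, 10, 10), RegionBox(5, 0, 15, 10)), 1 / 3)
})
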