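# Seeded generator of hemocytometer-like scenes with exact ground truth.
# Chamber scenes mimic the cropped counting area (bright chamber, dark ruled
# grid, dark quasi-circular cells); phone scenes embed a chamber in a larger
# cluttered canvas the way a hand-held photograph would.

# draw the chamber scene; consumes the current RNG stream (callers seed it)
.chamberScene <- function(params) {
  h <- params@imageSize[1]; w <- params@imageSize[2]
  bg <- params@backgroundIntensity
  img <- matrix(bg, nrow = h, ncol = w)

  # ruled grid: lines every gridSpacing px in both directions
  lw <- params@gridLineWidth
  gxs <- seq(params@gridSpacing, w - 1, by = params@gridSpacing)
  gys <- seq(params@gridSpacing, h - 1, by = params@gridSpacing)
  for (gx in gxs) {
    cols <- (gx + 1):min(gx + lw, w)
    img[, cols] <- params@gridIntensity
  }
  for (gy in gys) {
    rows <- (gy + 1):min(gy + lw, h)
    img[rows, ] <- params@gridIntensity
  }

  # rejection-sample non-overlapping cell centers
  rMin <- params@radiusRange[1]; rMax <- params@radiusRange[2]
  margin <- rMax + 1
  n <- params@nCells
  cells <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0))
  if (n > 0) {
    if (w - 1 - 2 * margin <= 0 || h - 1 - 2 * margin <= 0)
      stop("image too small for the requested cell radii")
    xs <- numeric(n); ys <- numeric(n); rs <- numeric(n)
    placed <- 0L
    attempts <- 0L
    maxAttempts <- max(2000L, 400L * n)
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > maxAttempts)
        stop(structure(class = c("hemocount_placementError", "error", "condition"),
                       list(message = sprintf(
                         "could not place %d cells with separation %g in a %d x %d image",
                         n, params@minCenterSeparation, h, w),
                         call = sys.call(-1))))
      cx <- runif(1, margin, w - 1 - margin)
      cy <- runif(1, margin, h - 1 - margin)
      cr <- runif(1, rMin, rMax)
      if (placed > 0L) {
        d2 <- (xs[seq_len(placed)] - cx)^2 + (ys[seq_len(placed)] - cy)^2
        if (min(d2) < params@minCenterSeparation^2) next
      }
      placed <- placed + 1L
      xs[placed] <- cx; ys[placed] <- cy; rs[placed] <- cr
    }
    cells <- data.frame(x = xs, y = ys, r = rs)

    # anti-aliased dark discs: alpha = coverage of the disc boundary
    for (i in seq_len(n)) {
      c0 <- max(1, floor(xs[i] - rs[i])); c1 <- min(w, ceiling(xs[i] + rs[i]) + 1)
      r0 <- max(1, floor(ys[i] - rs[i])); r1 <- min(h, ceiling(ys[i] + rs[i]) + 1)
      px <- (c0:c1) - 1; py <- (r0:r1) - 1
      dist <- sqrt(outer((py - ys[i])^2, (px - xs[i])^2, "+"))
      alpha <- pmin(pmax(rs[i] + 0.5 - dist, 0), 1)
      patch <- img[r0:r1, c0:c1]
      img[r0:r1, c0:c1] <- patch * (1 - alpha) + params@cellIntensity * alpha
    }
  }

  # linear illumination fall-off along the image diagonal
  g <- params@illuminationGradient
  if (g > 0) {
    ramp <- outer(seq(0, 1, length.out = h), seq(0, 1, length.out = w), "+") / 2
    img <- img * (1 - g * ramp)
  }
  if (params@noiseSd > 0)
    img <- img + matrix(rnorm(h * w, sd = params@noiseSd), nrow = h)
  img <- pmin(pmax(img, 0), 255)
  list(image = img, cells = cells)
}

#' Generate a synthetic chamber image with ground truth
#'
#' Draws a bright chamber carrying a dark ruled grid and \code{nCells} dark
#' anti-aliased discs placed by rejection sampling so that all pairwise center
#' distances respect \code{minCenterSeparation}, then applies the illumination
#' gradient and additive Gaussian noise. The generator is a pure function of
#' its parameters: identical \code{SceneParams} (including the seed) produce
#' bit-identical images.
#'
#' @param params a \code{\link{SceneParams-class}} object.
#' @return list with elements \code{image} (h x w matrix, 0-255) and
#'   \code{truth} (a \code{\link{SceneTruth-class}}; \code{roiBox} is NULL).
#' @examples
#' sc <- makeChamberImage(SceneParams(nCells = 10L, seed = 7L))
#' nCells(sc$truth)
#' @export
makeChamberImage <- function(params) {
  stopifnot(is(params, "SceneParams"))
  validObject(params)
  sc <- withLocalSeed(params@seed, .chamberScene(params))
  list(image = sc$image, truth = SceneTruth(sc$cells, roiBox = NULL))
}

# cluttered background canvas; consumes the current RNG stream
.clutterCanvas <- function(h, w, clutterLevel, noiseSd) {
  base <- 90
  img <- matrix(base, nrow = h, ncol = w)
  if (clutterLevel > 0) {
    # low-frequency mottle
    ch <- max(2L, ceiling(h / 32)); cw <- max(2L, ceiling(w / 32))
    coarse <- matrix(runif(ch * cw, -1, 1) * 45 * clutterLevel, nrow = ch)
    img <- img + .cpp_resize_bilinear(coarse, h, w)
    # random rectangles (desk objects, labels, shadows) spanning the same
    # scale range as plausible region proposals
    nRect <- round(24 * clutterLevel)
    for (i in seq_len(nRect)) {
      rw <- round(runif(1, 20, max(21, w / 2.5))); rh <- round(runif(1, 20, max(21, h / 2.5)))
      x0 <- floor(runif(1, 0, max(1, w - rw))); y0 <- floor(runif(1, 0, max(1, h - rh)))
      val <- runif(1, 20, 170)
      img[(y0 + 1):(y0 + rh), (x0 + 1):(x0 + rw)] <- val
    }
    # text-like strokes
    nStroke <- round(30 * clutterLevel)
    for (i in seq_len(nStroke)) {
      x0 <- runif(1, 0, w - 1); y0 <- runif(1, 0, h - 1)
      ang <- runif(1, 0, 2 * pi); len <- runif(1, 10, 60)
      val <- runif(1, 10, 80)
      t <- seq(0, 1, length.out = max(2, round(len)))
      px <- round(x0 + t * len * cos(ang)); py <- round(y0 + t * len * sin(ang))
      keep <- px >= 0 & px < w & py >= 0 & py < h
      img[cbind(py[keep] + 1, px[keep] + 1)] <- val
    }
    if (noiseSd > 0)
      img <- img + matrix(rnorm(h * w, sd = noiseSd), nrow = h)
  }
  pmin(pmax(img, 0), 255)
}

#' Generate a clutter-only canvas (no chamber)
#'
#' Background texture as in \code{\link{makePhoneImage}} but without a pasted
#' chamber: low-frequency mottle, random rectangles and text-like strokes.
#' Used for non-ROI training examples and negative-control scenes.
#'
#' @param canvasSize integer(2), canvas height and width.
#' @param clutterLevel fraction in [0, 1].
#' @param noiseSd Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return numeric matrix (0-255).
#' @export
makeClutterImage <- function(canvasSize = c(800L, 800L), clutterLevel = 0.5,
                             noiseSd = 5, seed = 1L) {
  stopifnot(clutterLevel >= 0, clutterLevel <= 1)
  withLocalSeed(seed, .clutterCanvas(canvasSize[1], canvasSize[2],
                                     clutterLevel, noiseSd))
}

#' Generate a synthetic phone photograph with ground truth
#'
#' Embeds a chamber scene (drawn exactly as \code{\link{makeChamberImage}}
#' would with the same \code{params}) at a random offset inside a larger
#' cluttered canvas. The truth records the pasted rectangle as the ROI box;
#' pixels inside it are identical to the chamber image.
#'
#' @param params a \code{\link{SceneParams-class}} for the embedded chamber.
#' @param clutterLevel fraction in [0, 1]; 0 leaves the background uniform.
#' @param canvasSize integer(2), canvas height and width; must be at least
#'   the chamber size.
#' @return list with \code{image} (canvas matrix) and \code{truth} (cells in
#'   canvas coordinates and \code{roiBox} set).
#' @export
makePhoneImage <- function(params, clutterLevel = 0.5, canvasSize = c(800L, 800L)) {
  stopifnot(is(params, "SceneParams"))
  validObject(params)
  stopifnot(clutterLevel >= 0, clutterLevel <= 1)
  h <- params@imageSize[1]; w <- params@imageSize[2]
  ch <- as.integer(canvasSize[1]); cw <- as.integer(canvasSize[2])
  if (h > ch || w > cw)
    stop("chamber image exceeds the canvas dimensions")
  withLocalSeed(params@seed, {
    sc <- .chamberScene(params)
    canvas <- .clutterCanvas(ch, cw, clutterLevel, params@noiseSd)
    ox <- floor(runif(1, 0, cw - w + 1))
    oy <- floor(runif(1, 0, ch - h + 1))
    canvas[(oy + 1):(oy + h), (ox + 1):(ox + w)] <- sc$image
    cells <- sc$cells
    if (nrow(cells) > 0) { cells$x <- cells$x + ox; cells$y <- cells$y + oy }
    list(image = canvas,
         truth = SceneTruth(cells, roiBox = RegionBox(ox, oy, ox + w, oy + h)))
  })
}

#' Generate a labeled ROI / non-ROI training set
#'
#' ROI examples (label 1) are random crops of synthetic chamber scenes.
#' Non-ROI examples (label 0) combine random crops of clutter-only canvases
#' with "undesirable" mixed crops from cluttered phone scenes in which the
#' chamber fills at most a minor part of the window -- the oversized or
#' off-target regions a proposal stage produces and the classifier must
#' reject.
#'
#' @param nRoi,nNonroi number of examples per class (>= 1).
#' @param seed integer seed for the whole set.
#' @param params \code{\link{SceneParams-class}} for the underlying chambers.
#' @param cropFraction numeric(2), crop side as a fraction of the source
#'   image's smaller dimension (both object-scale and full-view crops).
#' @param mixedFraction fraction of the non-ROI class drawn as mixed
#'   chamber-plus-clutter crops (chamber covering < 35\% of the window).
#' @return list with \code{images} (list of grayscale matrices) and
#'   \code{labels} (integer vector of 0/1).
#' @export
makeTrainingSet <- function(nRoi, nNonroi, seed = 1L, params = SceneParams(),
                            cropFraction = c(0.3, 1), mixedFraction = 1 / 3) {
  stopifnot(nRoi >= 1, nNonroi >= 1, mixedFraction >= 0, mixedFraction <= 1)
  withLocalSeed(seed, {
    cropsPerScene <- 10L
    cropWindow <- function(d) {
      side <- round(runif(1, cropFraction[1], cropFraction[2]) * min(d))
      side <- max(8L, min(side, min(d)))
      y0 <- floor(runif(1, 0, d[1] - side + 1))
      x0 <- floor(runif(1, 0, d[2] - side + 1))
      c(x0, y0, side)
    }
    randomCrop <- function(img) {
      w <- cropWindow(dim(img))
      img[(w[2] + 1):(w[2] + w[3]), (w[1] + 1):(w[1] + w[3])]
    }
    images <- vector("list", nRoi + nNonroi)
    k <- 0L
    nScenes <- ceiling(nRoi / cropsPerScene)
    for (s in seq_len(nScenes)) {
      scene <- .chamberScene(params)$image
      for (i in seq_len(min(cropsPerScene, nRoi - k))) {
        k <- k + 1L
        images[[k]] <- randomCrop(scene)
      }
    }
    nMixed <- round(nNonroi * mixedFraction)
    nClutter <- nNonroi - nMixed
    placed <- 0L
    for (s in seq_len(ceiling(nClutter / cropsPerScene))) {
      canvas <- .clutterCanvas(params@imageSize[1], params@imageSize[2], 0.8,
                               params@noiseSd)
      for (i in seq_len(min(cropsPerScene, nClutter - placed))) {
        placed <- placed + 1L
        images[[nRoi + placed]] <- randomCrop(canvas)
      }
    }
    if (nMixed > 0) {
      h <- params@imageSize[1]; w <- params@imageSize[2]
      ch <- 2L * h; cw <- 2L * w
      made <- 0L
      while (made < nMixed) {
        sc <- .chamberScene(params)$image
        canvas <- .clutterCanvas(ch, cw, 0.8, params@noiseSd)
        ox <- floor(runif(1, 0, cw - w + 1)); oy <- floor(runif(1, 0, ch - h + 1))
        canvas[(oy + 1):(oy + h), (ox + 1):(ox + w)] <- sc
        for (i in seq_len(min(cropsPerScene, nMixed - made))) {
          # rejection-sample a window whose chamber coverage stays minor
          for (try in 1:50) {
            win <- cropWindow(dim(canvas))
            ix <- max(0, min(ox + w, win[1] + win[3]) - max(ox, win[1]))
            iy <- max(0, min(oy + h, win[2] + win[3]) - max(oy, win[2]))
            if (ix * iy / win[3]^2 < 0.35) break
          }
          made <- made + 1L
          images[[nRoi + placed + made]] <-
            canvas[(win[2] + 1):(win[2] + win[3]), (win[1] + 1):(win[1] + win[3])]
        }
      }
    }
    list(images = images, labels = c(rep(1L, nRoi), rep(0L, nNonroi)))
  })
}

#' Write a scene image and its truth sidecar
#'
#' Writes the scene as PNG plus a JSON truth file
#' \code{{"cells":[[x,y,r],...],"count":N,"roi_box":[x0,y0,x1,y1]}}
#' (\code{roi_box} is null for chamber-only scenes).
#'
#' @param scene list with \code{image} and \code{truth}, as returned by the
#'   generators.
#' @param pngPath,jsonPath output paths.
#' @return invisibly, a character vector of the two paths.
#' @export
writeScene <- function(scene, pngPath, jsonPath) {
  writeImagePNG(scene$image, pngPath)
  truth <- scene$truth
  cellList <- unname(lapply(seq_len(nrow(truth@cells)), function(i)
    as.numeric(truth@cells[i, c("x", "y", "r")])))
  box <- if (is.null(truth@roiBox)) NULL else
    c(truth@roiBox@x0, truth@roiBox@y0, truth@roiBox@x1, truth@roiBox@y1)
  jsonlite::write_json(list(cells = cellList, count = truth@count, roi_box = box),
                       jsonPath, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(pngPath, jsonPath))
}

#' Read a truth sidecar written by \code{\link{writeScene}}
#'
#' @param jsonPath path to the truth JSON.
#' @return a \code{\link{SceneTruth-class}} object.
#' @export
readSceneTruth <- function(jsonPath) {
  x <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  cells <- if (length(x$cells) == 0) data.frame(x = numeric(0), y = numeric(0),
                                                r = numeric(0))
    else as.data.frame(stats::setNames(as.data.frame(x$cells), c("x", "y", "r")))
  box <- if (is.null(x$roi_box)) NULL else
    RegionBox(x$roi_box[1], x$roi_box[2], x$roi_box[3], x$roi_box[4])
  SceneTruth(cells, roiBox = box)
}
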