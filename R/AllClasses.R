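#' Axis-aligned region box
#'
#' A rectangle in pixel coordinates locating a proposed or detected region.
#' Coordinates are 0-based and half-open: the box covers columns
#' \code{[x0, x1)} and rows \code{[y0, y1)}, so its width is \code{x1 - x0}
#' and its height \code{y1 - y0}.
#'
#' @slot x0,y0 numeric, top-left corner (inclusive).
#' @slot x1,y1 numeric, bottom-right corner (exclusive).
#' @export
setClass("RegionBox",
  representation(x0 = "numeric", y0 = "numeric", x1 = "numeric", y1 = "numeric"),
  validity = function(object) {
    v <- c(object@x0, object@y0, object@x1, object@y1)
    if (length(v) != 4 || any(!is.finite(v))) return("coordinates must be finite scalars")
    if (object@x1 <= object@x0) return("x1 must exceed x0")
    if (object@y1 <= object@y0) return("y1 must exceed y0")
    if (any(v < 0)) return("coordinates must be non-negative")
    TRUE
  })

#' @param x0,y0,x1,y1 box corners, 0-based half-open.
#' @rdname RegionBox-class
#' @export
RegionBox <- function(x0, y0, x1, y1) {
  new("RegionBox", x0 = as.numeric(x0), y0 = as.numeric(y0),
      x1 = as.numeric(x1), y1 = as.numeric(y1))
}

setClassUnion("RegionBoxOrNULL", c("RegionBox", "NULL"))

#' Parameters of the synthetic chamber-scene generator
#'
#' Describes a hemocytometer-like scene: a bright chamber carrying a dark
#' ruled grid and dark quasi-circular cells, with additive Gaussian noise and
#' an optional linear illumination gradient. Identical parameter sets
#' (including the seed) generate bit-identical images.
#'
#' @slot imageSize integer(2), chamber image height and width in pixels.
#' @slot nCells integer, number of cells to place.
#' @slot radiusRange numeric(2), cell radius band \code{[rMin, rMax]} in pixels
#'   (\code{rMin >= 2}).
#' @slot minCenterSeparation numeric, minimum pairwise distance between cell
#'   centers in pixels; \code{>= 2 * rMax} guarantees non-overlapping cells.
#' @slot gridSpacing integer, grid-line period in pixels.
#' @slot gridLineWidth integer, grid-line width in pixels.
#' @slot cellIntensity,backgroundIntensity,gridIntensity numeric grayscale
#'   levels in 0-255; cells and grid are darker than the chamber background by
#'   default, matching the appearance of a brightfield hemocytometer.
#' @slot noiseSd numeric, standard deviation of additive Gaussian pixel noise.
#' @slot illuminationGradient numeric in \code{[0, 1]}, relative brightness
#'   drop across the image diagonal (0 = flat illumination).
#' @slot seed integer seed driving the single RNG stream of a generator call.
#' @export
setClass("SceneParams",
  representation(imageSize = "integer", nCells = "integer",
                 radiusRange = "numeric", minCenterSeparation = "numeric",
                 gridSpacing = "integer", gridLineWidth = "integer",
                 cellIntensity = "numeric", backgroundIntensity = "numeric",
                 gridIntensity = "numeric", noiseSd = "numeric",
                 illuminationGradient = "numeric", seed = "integer"),
  validity = function(object) {
    if (length(object@imageSize) != 2 || any(object@imageSize < 8))
      return("imageSize must be two values >= 8")
    if (object@nCells < 0) return("nCells must be >= 0")
    r <- object@radiusRange
    if (length(r) != 2 || r[1] < 2 || r[2] < r[1])
      return("radiusRange must satisfy 2 <= rMin <= rMax")
    if (object@minCenterSeparation < 0) return("minCenterSeparation must be >= 0")
    if (object@gridSpacing < 2) return("gridSpacing must be >= 2")
    if (object@gridLineWidth < 1) return("gridLineWidth must be >= 1")
    ints <- c(object@cellIntensity, object@backgroundIntensity, object@gridIntensity)
    if (any(ints < 0 | ints > 255)) return("intensities must lie in 0-255")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    g <- object@illuminationGradient
    if (g < 0 || g > 1) return("illuminationGradient must lie in [0, 1]")
    TRUE
  })

#' @param imageSize,nCells,radiusRange,minCenterSeparation,gridSpacing
#'   see slot documentation.
#' @param gridLineWidth,cellIntensity,backgroundIntensity,gridIntensity
#'   see slot documentation.
#' @param noiseSd,illuminationGradient,seed see slot documentation.
#' @rdname SceneParams-class
#' @export
SceneParams <- function(imageSize = c(400L, 400L), nCells = 50L,
                        radiusRange = c(6, 10), minCenterSeparation = 20,
                        gridSpacing = 50L, gridLineWidth = 2L,
                        cellIntensity = 60, backgroundIntensity = 200,
                        gridIntensity = 120, noiseSd = 5,
                        illuminationGradient = 0.1, seed = 1L) {
  new("SceneParams", imageSize = as.integer(imageSize), nCells = as.integer(nCells),
      radiusRange = as.numeric(radiusRange),
      minCenterSeparation = as.numeric(minCenterSeparation),
      gridSpacing = as.integer(gridSpacing), gridLineWidth = as.integer(gridLineWidth),
      cellIntensity = as.numeric(cellIntensity),
      backgroundIntensity = as.numeric(backgroundIntensity),
      gridIntensity = as.numeric(gridIntensity), noiseSd = as.numeric(noiseSd),
      illuminationGradient = as.numeric(illuminationGradient), seed = as.integer(seed))
}

#' Ground truth of a generated scene
#'
#' @slot cells data.frame with columns \code{x}, \code{y}, \code{r}: cell
#'   centers and radii in pixels (0-based coordinates).
#' @slot count integer, number of cells (always \code{nrow(cells)}).
#' @slot roiBox the chamber's bounding box inside a phone scene, or NULL for
#'   a chamber-only scene.
#' @export
setClass("SceneTruth",
  representation(cells = "data.frame", count = "integer",
                 roiBox = "RegionBoxOrNULL"),
  validity = function(object) {
    if (!all(c("x", "y", "r") %in% names(object@cells)))
      return("cells must have columns x, y, r")
    if (object@count != nrow(object@cells))
      return("count must equal the number of listed cells")
    TRUE
  })

SceneTruth <- function(cells, roiBox = NULL) {
  new("SceneTruth", cells = cells, count = nrow(cells), roiBox = roiBox)
}

#' Hough circle transform parameters
#'
#' Controls circle detection. \code{param1} is the edge-strength (Canny high)
#' threshold; \code{param2} is the accumulator threshold -- the number of
#' gradient votes a candidate center must collect, i.e. the required evidence
#' for circle smoothness. \code{minRadius}/\code{maxRadius} bound the radius
#' search band and \code{minCenterDist} suppresses duplicate centers.
#'
#' @slot param1 numeric > 0, edge-strength threshold.
#' @slot param2 numeric > 0, accumulator (smoothness) threshold.
#' @slot minRadius,maxRadius numeric, radius band in pixels.
#' @slot minCenterDist numeric, minimum distance between accepted centers.
#' @slot accumulatorResolution numeric >= 1, ratio of image to accumulator
#'   resolution (1 = vote at full pixel resolution).
#' @export
setClass("HoughParams",
  representation(param1 = "numeric", param2 = "numeric", minRadius = "numeric",
                 maxRadius = "numeric", minCenterDist = "numeric",
                 accumulatorResolution = "numeric"),
  validity = function(object) {
    if (object@param1 <= 0 || object@param2 <= 0)
      return("param1 and param2 must be > 0")
    if (object@minRadius <= 0 || object@maxRadius < object@minRadius)
      return("radius band must satisfy 0 < minRadius <= maxRadius")
    if (object@minCenterDist < 0) return("minCenterDist must be >= 0")
    if (object@accumulatorResolution < 1) return("accumulatorResolution must be >= 1")
    TRUE
  })

#' @param param1,param2,minRadius,maxRadius,minCenterDist,accumulatorResolution
#'   see slot documentation; \code{minCenterDist} defaults to \code{minRadius}.
#' @rdname HoughParams-class
#' @export
HoughParams <- function(param1 = 60, param2 = 18, minRadius = 4, maxRadius = 12,
                        minCenterDist = minRadius, accumulatorResolution = 1) {
  new("HoughParams", param1 = as.numeric(param1), param2 = as.numeric(param2),
      minRadius = as.numeric(minRadius), maxRadius = as.numeric(maxRadius),
      minCenterDist = as.numeric(minCenterDist),
      accumulatorResolution = as.numeric(accumulatorResolution))
}

#' Architecture of the ROI classifier
#'
#' A sequential network: two valid-mode convolutions with small square kernels
#' (each followed by batch normalization, ReLU and 2x2 max pooling), one
#' dropout after the convolutional stack, then a dense head whose first two
#' layers carry batch normalization and whose second carries dropout, ending
#' in a 2-way softmax (class 0 = Non-ROI, class 1 = ROI).
#'
#' @slot inputSize integer(2), height and width the classifier sees.
#' @slot channels integer, 3 for RGB input (grayscale inputs are replicated),
#'   1 for grayscale.
#' @slot convFilters integer(2), filters of the two convolutional layers.
#' @slot convKernel integer, square kernel size.
#' @slot convDropout numeric in [0,1), dropout rate after the conv stack.
#' @slot denseUnits integer vector, dense layer widths; the last must be 2.
#' @slot denseDropout numeric in [0,1), dropout rate inside the dense head.
#' @export
setClass("ClassifierConfig",
  representation(inputSize = "integer", channels = "integer",
                 convFilters = "integer", convKernel = "integer",
                 convDropout = "numeric", denseUnits = "integer",
                 denseDropout = "numeric"),
  validity = function(object) {
    if (length(object@inputSize) != 2 || any(object@inputSize < 8))
      return("inputSize must be two values >= 8")
    if (!object@channels %in% c(1L, 3L)) return("channels must be 1 or 3")
    if (length(object@convFilters) != 2 || any(object@convFilters < 1))
      return("convFilters must be two positive counts")
    if (object@convKernel < 2) return("convKernel must be >= 2")
    if (length(object@denseUnits) < 1 ||
        object@denseUnits[length(object@denseUnits)] != 2L)
      return("the final dense layer must have 2 units (Non-ROI, ROI)")
    d <- c(object@convDropout, object@denseDropout)
    if (any(d < 0 | d >= 1)) return("dropout rates must lie in [0, 1)")
    TRUE
  })

#' @param inputSize,channels,convFilters,convKernel,convDropout see slots.
#' @param denseUnits,denseDropout see slots.
#' @rdname ClassifierConfig-class
#' @export
ClassifierConfig <- function(inputSize = c(256L, 256L), channels = 3L,
                             convFilters = c(256L, 128L), convKernel = 2L,
                             convDropout = 0.25,
                             denseUnits = c(128L, 128L, 64L, 2L),
                             denseDropout = 0.5) {
  new("ClassifierConfig", inputSize = as.integer(inputSize),
      channels = as.integer(channels), convFilters = as.integer(convFilters),
      convKernel = as.integer(convKernel), convDropout = as.numeric(convDropout),
      denseUnits = as.integer(denseUnits), denseDropout = as.numeric(denseDropout))
}

#' Training protocol of the ROI classifier
#'
#' @slot epochs integer, training epochs (default 10).
#' @slot batchSize integer, minibatch size (default 32).
#' @slot trainFraction numeric, fraction of the data used for training; the
#'   remainder is the held-out validation split (default 0.9).
#' @slot augmentFlip logical, apply random horizontal flips to training
#'   batches (the only augmentation used).
#' @slot learningRate numeric, Adam step size.
#' @slot seed integer driving shuffling, initialization, dropout and
#'   augmentation.
#' @export
setClass("TrainConfig",
  representation(epochs = "integer", batchSize = "integer",
                 trainFraction = "numeric", augmentFlip = "logical",
                 learningRate = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@epochs < 1) return("epochs must be >= 1")
    if (object@batchSize < 1) return("batchSize must be >= 1")
    f <- object@trainFraction
    if (f <= 0 || f >= 1) return("trainFraction must lie in (0, 1)")
    if (object@learningRate <= 0) return("learningRate must be > 0")
    TRUE
  })

#' @param epochs,batchSize,trainFraction,augmentFlip,learningRate,seed see slots.
#' @rdname TrainConfig-class
#' @export
TrainConfig <- function(epochs = 10L, batchSize = 32L, trainFraction = 0.9,
                        augmentFlip = TRUE, learningRate = 1e-3, seed = 1L) {
  new("TrainConfig", epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      trainFraction = as.numeric(trainFraction), augmentFlip = as.logical(augmentFlip),
      learningRate = as.numeric(learningRate), seed = as.integer(seed))
}

#' A region with its ROI/non-ROI classification
#'
#' @slot box the proposed region.
#' @slot label integer, 0 = Non-ROI, 1 = ROI.
#' @slot score numeric in [0,1], softmax probability of the ROI class.
#' @export
setClass("ClassifiedRegion",
  representation(box = "RegionBox", label = "integer", score = "numeric"),
  validity = function(object) {
    if (!object@label %in% c(0L, 1L)) return("label must be 0 or 1")
    if (object@score < 0 || object@score > 1) return("score must lie in [0, 1]")
    TRUE
  })

ClassifiedRegion <- function(box, label, score) {
  new("ClassifiedRegion", box = box, label = as.integer(label),
      score = as.numeric(score))
}

#' Counting pipeline configuration
#'
#' Bundles the stages of \code{\link{countChamber}}: structuring element for
#' the morphological opening, Gaussian smoothing and Canny thresholds for
#' edge detection (by default coupled to the Hough edge-strength parameter as
#' high = param1, low = param1/2), the Hough circle parameters, and the
#' perimeter-verification support threshold.
#'
#' @slot seShape character, "square" or "disc".
#' @slot seSize integer, odd structuring-element size in pixels.
#' @slot blurSigma numeric, Gaussian sigma used inside Canny.
#' @slot cannyLow,cannyHigh numeric; NA = derive from \code{hough@param1}.
#' @slot hough the \code{\link{HoughParams-class}} settings.
#' @slot supportThreshold numeric in [0,1], minimum fraction of perimeter
#'   sample points supported by an edge pixel for a circle to be counted.
#' @slot perimeterSamples integer, number of perimeter sample points.
#' @export
setClass("CounterConfig",
  representation(seShape = "character", seSize = "integer", blurSigma = "numeric",
                 cannyLow = "numeric", cannyHigh = "numeric",
                 hough = "HoughParams", supportThreshold = "numeric",
                 perimeterSamples = "integer"),
  validity = function(object) {
    if (!object@seShape %in% c("square", "disc"))
      return("seShape must be 'square' or 'disc'")
    if (object@seSize < 1 || object@seSize %% 2 == 0)
      return("seSize must be odd and >= 1")
    if (object@supportThreshold < 0 || object@supportThreshold > 1)
      return("supportThreshold must lie in [0, 1]")
    if (object@perimeterSamples < 8) return("perimeterSamples must be >= 8")
    TRUE
  })

#' @param seShape,seSize,blurSigma,cannyLow,cannyHigh,hough see slots.
#' @param supportThreshold,perimeterSamples see slots.
#' @rdname CounterConfig-class
#' @export
CounterConfig <- function(seShape = "square", seSize = 3L, blurSigma = 1,
                          cannyLow = NA_real_, cannyHigh = NA_real_,
                          hough = HoughParams(), supportThreshold = 0.3,
                          perimeterSamples = 64L) {
  new("CounterConfig", seShape = seShape, seSize = as.integer(seSize),
      blurSigma = as.numeric(blurSigma), cannyLow = as.numeric(cannyLow),
      cannyHigh = as.numeric(cannyHigh), hough = hough,
      supportThreshold = as.numeric(supportThreshold),
      perimeterSamples = as.integer(perimeterSamples))
}

#' Per-chamber count
#'
#' @slot chamberIndex integer in 0-3.
#' @slot nCells integer, accepted circle count.
#' @slot circles data.frame with columns \code{a}, \code{b}, \code{r},
#'   \code{support}: circle centers (x, y), radii, and perimeter support.
#' @export
setClass("ChamberCount",
  representation(chamberIndex = "integer", nCells = "integer",
                 circles = "data.frame"),
  validity = function(object) {
    if (object@chamberIndex < 0 || object@chamberIndex > 3)
      return("chamberIndex must lie in 0-3")
    if (!all(c("a", "b", "r", "support") %in% names(object@circles)))
      return("circles must have columns a, b, r, support")
    if (object@nCells != nrow(object@circles))
      return("nCells must equal the number of circles")
    TRUE
  })

ChamberCount <- function(chamberIndex, circles) {
  new("ChamberCount", chamberIndex = as.integer(chamberIndex),
      nCells = nrow(circles), circles = circles)
}

#' Aggregated count report
#'
#' The hemocytometer chamber grid covers 1 mm^2 at 0.1 mm depth, a volume of
#' 0.1 mm^3 = 1e-4 mL, so concentration = mean count per chamber x dilution
#' factor x 10^4 cells/mL.
#'
#' @slot chambers list of \code{\link{ChamberCount-class}} objects.
#' @slot total integer, summed count.
#' @slot meanPerChamber numeric.
#' @slot dilutionFactor numeric > 0.
#' @slot concentration numeric, cells/mL.
#' @slot cellType character label (e.g. "PC3", "LN-CaP", "DU-145").
#' @export
setClass("CountReport",
  representation(chambers = "list", total = "integer", meanPerChamber = "numeric",
                 dilutionFactor = "numeric", concentration = "numeric",
                 cellType = "character"),
  validity = function(object) {
    counts <- vapply(object@chambers, function(ch) ch@nCells, integer(1))
    if (object@total != sum(counts)) return("total must equal the summed counts")
    if (object@dilutionFactor <= 0) return("dilutionFactor must be > 0")
    TRUE
  })

#' Two-class confusion matrix
#'
#' Rows index the true class, columns the predicted class, in the order
#' (Non-ROI, ROI).
#'
#' @slot counts integer 2x2 matrix, truth x prediction.
#' @slot classes character(2) class names.
#' @export
setClass("ConfusionMatrix2",
  representation(counts = "matrix", classes = "character"),
  validity = function(object) {
    if (!all(dim(object@counts) == c(2, 2))) return("counts must be 2x2")
    if (any(object@counts < 0)) return("counts must be non-negative")
    if (length(object@classes) != 2) return("exactly two classes required")
    TRUE
  })

#' Classification metrics report
#'
#' Per-class precision, recall and F1 with supports, plus overall accuracy and
#' the macro (unweighted class mean) and weighted (support-weighted class
#' mean) averages.
#'
#' @slot perClass data.frame with columns \code{class}, \code{precision},
#'   \code{recall}, \code{f1}, \code{support}.
#' @slot accuracy,macroPrecision,macroRecall,macroF1 numeric in [0,1].
#' @slot weightedPrecision,weightedRecall,weightedF1 numeric in [0,1].
#' @slot total integer, number of samples.
#' @export
setClass("MetricsReport",
  representation(perClass = "data.frame", accuracy = "numeric",
                 macroPrecision = "numeric", macroRecall = "numeric",
                 macroF1 = "numeric", weightedPrecision = "numeric",
                 weightedRecall = "numeric", weightedF1 = "numeric",
                 total = "integer"),
  validity = function(object) {
    vals <- c(object@accuracy, object@macroPrecision, object@macroRecall,
              object@macroF1, object@weightedPrecision, object@weightedRecall,
              object@weightedF1, object@perClass$precision,
              object@perClass$recall, object@perClass$f1)
    if (any(vals < -1e-12 | vals > 1 + 1e-12)) return("metrics must lie in [0, 1]")
    TRUE
  })
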