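#' @name hemocount-accessors
#' @title Accessors for hemocount result objects
#' @param x an object.
#' @param object an object (show methods).
NULL

#' @describeIn hemocount-accessors number of cells in a truth, chamber count
#'   or report object.
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @describeIn hemocount-accessors detected circles as a data.frame.
#' @export
setGeneric("circles", function(x) standardGeneric("circles"))

#' @describeIn hemocount-accessors ground-truth/selected ROI bounding box.
#' @export
setGeneric("roiBox", function(x) standardGeneric("roiBox"))

#' @describeIn hemocount-accessors concentration in cells/mL.
#' @export
setGeneric("concentration", function(x) standardGeneric("concentration"))

#' @describeIn hemocount-accessors box area in pixels.
#' @export
setGeneric("boxArea", function(x) standardGeneric("boxArea"))

setMethod("nCells", "SceneTruth", function(x) x@count)
setMethod("nCells", "ChamberCount", function(x) x@nCells)
setMethod("nCells", "CountReport", function(x) x@total)
setMethod("circles", "ChamberCount", function(x) x@circles)
setMethod("roiBox", "SceneTruth", function(x) x@roiBox)
setMethod("roiBox", "ClassifiedRegion", function(x) x@box)
setMethod("concentration", "CountReport", function(x) x@concentration)
setMethod("boxArea", "RegionBox", function(x) (x@x1 - x@x0) * (x@y1 - x@y0))

#' Intersection-over-union of two region boxes
#'
#' @param a,b \code{\link{RegionBox-class}} objects.
#' @return numeric in [0, 1].
#' @export
boxIoU <- function(a, b) {
  ix <- max(0, min(a@x1, b@x1) - max(a@x0, b@x0))
  iy <- max(0, min(a@y1, b@y1) - max(a@y0, b@y0))
  inter <- ix * iy
  union <- boxArea(a) + boxArea(b) - inter
  if (union <= 0) return(0)
  inter / union
}

setMethod("show", "RegionBox", function(object) {
  cat(sprintf("RegionBox [%g, %g) x [%g, %g) (%g x %g px)\n",
              object@x0, object@x1, object@y0, object@y1,
              object@x1 - object@x0, object@y1 - object@y0))
})

setMethod("show", "SceneParams", function(object) {
  cat("SceneParams\n")
  cat(sprintf("  image %d x %d px, %d cells, radius %g-%g px (sep >= %g)\n",
              object@imageSize[1], object@imageSize[2], object@nCells,
              object@radiusRange[1], object@radiusRange[2],
              object@minCenterSeparation))
  cat(sprintf("  grid every %d px (width %d), intensities cell/grid/bg = %g/%g/%g\n",
              object@gridSpacing, object@gridLineWidth, object@cellIntensity,
              object@gridIntensity, object@backgroundIntensity))
  cat(sprintf("  noise sd %g, illumination gradient %g, seed %d\n",
              object@noiseSd, object@illuminationGradient, object@seed))
})

setMethod("show", "HoughParams", function(object) {
  cat(sprintf(paste0("HoughParams: param1 = %g, param2 = %g, radius %g-%g px, ",
                     "min center dist %g\n"),
              object@param1, object@param2, object@minRadius, object@maxRadius,
              object@minCenterDist))
})

setMethod("show", "ClassifiedRegion", function(object) {
  cat(sprintf("ClassifiedRegion: %s (score %.3f), box [%g,%g)x[%g,%g)\n",
              if (object@label == 1L) "ROI" else "Non-ROI", object@score,
              object@box@x0, object@box@x1, object@box@y0, object@box@y1))
})

setMethod("show", "ChamberCount", function(object) {
  cat(sprintf("ChamberCount: chamber %d, %d cells\n",
              object@chamberIndex, object@nCells))
})

setMethod("show", "CountReport", function(object) {
  counts <- vapply(object@chambers, nCells, integer(1))
  cat("CountReport", if (nzchar(object@cellType)) paste0("(", object@cellType, ")") else "", "\n")
  cat(sprintf("  chambers: %s  (total %d, mean %.2f)\n",
              paste(counts, collapse = ", "), object@total, object@meanPerChamber))
  cat(sprintf("  dilution %g -> concentration %.3g cells/mL\n",
              object@dilutionFactor, object@concentration))
})

setMethod("show", "ConfusionMatrix2", function(object) {
  cat("ConfusionMatrix2 (rows = truth, cols = predicted)\n")
  m <- object@counts
  dimnames(m) <- list(object@classes, object@classes)
  print(m)
})

setMethod("show", "MetricsReport", function(object) {
  cat(formatMetricsTable(object), sep = "\n")
})
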