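# Chamber counting pipeline: grayscale -> morphological opening -> Canny ->
# Hough circles -> perimeter verification, then aggregation of the four
# hemocytometer chambers into a concentration.

#' Count cells in one chamber crop
#'
#' Runs the full counting pipeline on an ROI crop: grayscale conversion,
#' morphological opening (noise suppression), Canny edge detection (high
#' threshold = Hough \code{param1}, low = \code{param1 / 2} unless overridden),
#' gradient-voting Hough circle transform, and perimeter verification. Only
#' circles whose perimeter support reaches the configured threshold are
#' counted; this is what keeps straight grid-line edges out of the count.
#'
#' @param crop RGB array or grayscale matrix of the chamber region (0-255).
#' @param config a \code{\link{CounterConfig-class}} object.
#' @param chamberIndex integer 0-3 recorded on the result.
#' @return a \code{\link{ChamberCount-class}} object.
#' @examples
#' sc <- makeChamberImage(SceneParams(nCells = 12L, seed = 3L))
#' nCells(countChamber(sc$image))
#' @export
countChamber <- function(crop, config = CounterConfig(), chamberIndex = 0L) {
  assertImage(crop)
  validObject(config)
  gray <- toGrayscale(crop)
  se <- structuringElement(config@seShape, config@seSize)
  opened <- morphOpen(gray, se)
  high <- if (is.na(config@cannyHigh)) config@hough@param1 else config@cannyHigh
  low <- if (is.na(config@cannyLow)) high / 2 else config@cannyLow
  edges <- cannyEdges(opened, low, high, config@blurSigma)
  cand <- houghCircles(opened, config@hough, edges = edges,
                       blurSigma = config@blurSigma)
  verified <- verifyPerimeter(cand, edges, config@supportThreshold,
                              config@perimeterSamples)
  acc <- verified[verified$accepted, c("a", "b", "r", "support"), drop = FALSE]
  rownames(acc) <- NULL
  ChamberCount(chamberIndex, acc)
}

#' Aggregate chamber counts into a concentration report
#'
#' Each hemocytometer chamber grid covers 1 mm^2 at 0.1 mm depth, i.e. a
#' volume of 0.1 mm^3 = 1e-4 mL, so
#' concentration = mean count per chamber x dilution factor x 10^4 cells/mL.
#'
#' @param chamberCounts list of \code{\link{ChamberCount-class}} objects; the
#'   standard protocol uses exactly 4 (override with \code{allowPartial}).
#' @param dilutionFactor multiplicative dilution correction, > 0.
#' @param cellType optional cell-line label carried into the report.
#' @param allowPartial allow a number of chambers other than 4.
#' @return a \code{\link{CountReport-class}} object.
#' @examples
#' chs <- lapply(0:3, function(i)
#'   hemocount:::ChamberCount(i, data.frame(a = numeric(0), b = numeric(0),
#'                                          r = numeric(0), support = numeric(0))))
#' concentration(aggregateReport(chs, dilutionFactor = 1))
#' @export
aggregateReport <- function(chamberCounts, dilutionFactor = 1, cellType = "",
                            allowPartial = FALSE) {
  if (!is.list(chamberCounts) ||
      !all(vapply(chamberCounts, is, logical(1), "ChamberCount")))
    stop("chamberCounts must be a list of ChamberCount objects")
  if (length(chamberCounts) != 4 && !allowPartial)
    stop("the standard protocol uses exactly 4 chambers; ",
         "set allowPartial = TRUE to override")
  if (length(chamberCounts) == 0) stop("at least one chamber is required")
  if (dilutionFactor <= 0) stop("dilutionFactor must be > 0")
  counts <- vapply(chamberCounts, nCells, integer(1))
  m <- mean(counts)
  new("CountReport", chambers = chamberCounts, total = as.integer(sum(counts)),
      meanPerChamber = m, dilutionFactor = as.numeric(dilutionFactor),
      concentration = m * dilutionFactor * 1e4, cellType = as.character(cellType))
}

#' Draw detected circles on an image
#'
#' Returns an RGB copy of the image with circle outlines drawn in red, the
#' conventional overlay for inspecting detections.
#'
#' @param image grayscale matrix or RGB array (0-255).
#' @param circlesDf data.frame with columns \code{a}, \code{b}, \code{r}.
#' @param color numeric(3) RGB in 0-255.
#' @return h x w x 3 array.
#' @export
drawOverlay <- function(image, circlesDf, color = c(255, 0, 0)) {
  assertImage(image)
  gray <- toGrayscale(image)
  h <- nrow(gray); w <- ncol(gray)
  rgb <- array(rep(gray, 3), dim = c(h, w, 3))
  for (i in seq_len(nrow(circlesDf))) {
    rad <- circlesDf$r[i]
    n <- max(16L, ceiling(4 * pi * rad))
    th <- 2 * pi * (seq_len(n) - 1) / n
    px <- round(circlesDf$a[i] + rad * cos(th))
    py <- round(circlesDf$b[i] + rad * sin(th))
    keep <- px >= 0 & px < w & py >= 0 & py < h
    idx <- cbind(py[keep] + 1, px[keep] + 1)
    for (k in 1:3) {
      plane <- rgb[, , k]
      plane[idx] <- color[k]
      rgb[, , k] <- plane
    }
  }
  rgb
}

#' Write a count report as JSON
#'
#' Schema:
#' \code{{"cell_type":t,"chambers":[{"index":i,"count":n,"circles":
#' [[a,b,r,support],...]},...],"total":T,"mean":m,"dilution":d,
#' "concentration_cells_per_ml":c}}.
#'
#' @param report a \code{\link{CountReport-class}} object.
#' @param path output JSON file.
#' @return the path, invisibly.
#' @export
writeCountReport <- function(report, path) {
  stopifnot(is(report, "CountReport"))
  chambers <- lapply(report@chambers, function(ch) {
    circ <- unname(lapply(seq_len(nrow(ch@circles)), function(i)
      as.numeric(ch@circles[i, c("a", "b", "r", "support")])))
    list(index = ch@chamberIndex, count = ch@nCells, circles = circ)
  })
  jsonlite::write_json(
    list(cell_type = report@cellType, chambers = chambers, total = report@total,
         mean = report@meanPerChamber, dilution = report@dilutionFactor,
         concentration_cells_per_ml = report@concentration),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
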