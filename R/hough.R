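# Hough circle transform. Circles satisfy r^2 = (x - a)^2 + (y - b)^2; every
# edge pixel votes for candidate centers (a, b) over the radius band, centers
# collecting at least param2 votes are kept (local maxima, then suppression of
# centers closer than minCenterDist), and each center's radius is the most
# supported distance to nearby edge pixels.

.localMaxima8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  keep <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    keep <- keep & (m >= pad[(2:(nr + 1)) + dr, (2:(nc + 1)) + dc])
  }
  keep
}

.emptyCircles <- function() {
  data.frame(a = numeric(0), b = numeric(0), r = numeric(0), votes = numeric(0))
}

#' Detect circles with a Hough transform
#'
#' For grayscale input, edges come from Canny (high = \code{param1}, low =
#' \code{param1 / 2} unless an edge map is supplied) and each edge pixel casts
#' votes at distance r along its gradient direction (both signs) for every
#' radius in the band -- the gradient-voting formulation, which is fast and
#' indifferent to straight edges such as grid lines. If the input is already
#' a binary edge map, votes are cast along full circles instead, since a thin
#' edge map carries no usable interior gradient.
#'
#' @param image grayscale matrix (0-255) or binary edge map (0/255 or 0/1).
#' @param params a \code{\link{HoughParams-class}} object.
#' @param edges optional precomputed binary edge map aligned with
#'   \code{image}; when supplied, gradients still come from \code{image}.
#' @param blurSigma Gaussian sigma for the internal gradient/edge computation.
#' @return data.frame with columns \code{a}, \code{b} (center, 0-based pixel
#'   coordinates), \code{r} (radius) and \code{votes}, ordered by decreasing
#'   votes. Raising \code{param2} always yields a subset of the detections.
#' @export
houghCircles <- function(image, params = HoughParams(), edges = NULL,
                         blurSigma = 1) {
  assertImage(image)
  if (length(dim(image)) != 2) stop("houghCircles expects a grayscale matrix")
  validObject(params)
  rmin <- as.integer(round(params@minRadius))
  rmax <- as.integer(round(params@maxRadius))
  vals <- unique(as.vector(image))
  isEdgeMap <- is.null(edges) && length(vals) <= 2 && all(vals %in% c(0, 1, 255))

  if (isEdgeMap) {
    # full (a, b, r) accumulator: one 2-d vote layer per radius, candidates
    # are per-layer local maxima above param2 (a thin edge map carries no
    # usable interior gradient, so votes go along full circles)
    edgesInt <- matrix(as.integer(image != 0), nrow = nrow(image))
    nr <- nrow(edgesInt); nc <- ncol(edgesInt)
    ep <- which(edgesInt != 0, arr.ind = TRUE)
    if (nrow(ep) == 0) return(.emptyCircles())
    cand <- NULL
    for (rad in rmin:rmax) {
      nAng <- max(16L, 2L * ceiling(2 * pi * rad))
      th <- 2 * pi * (seq_len(nAng) - 1) / nAng
      cr <- round(outer(ep[, 1], rad * sin(th), "+"))
      cc <- round(outer(ep[, 2], rad * cos(th), "+"))
      ok <- cr >= 1 & cr <= nr & cc >= 1 & cc <= nc
      li <- (cr[ok] - 1) + (cc[ok] - 1) * nr + 1
      # count distinct edge pixels supporting each center, not raw angle
      # samples: dedupe (edge pixel, center) pairs before tabulating
      px <- row(cr)[ok]
      li <- li[!duplicated(cbind(px, li))]
      accR <- matrix(tabulate(li, nbins = nr * nc), nr)
      idx <- which(.localMaxima8(accR) & accR >= params@param2, arr.ind = TRUE)
      if (nrow(idx) > 0)
        cand <- rbind(cand, cbind(idx, votes = accR[idx], r = rad))
    }
    if (is.null(cand) || nrow(cand) == 0) return(.emptyCircles())
  } else {
    sm <- .cpp_gaussian_blur(image, blurSigma)
    gxy <- .cpp_sobel(sm)
    if (is.null(edges))
      edges <- cannyEdges(image, params@param1 / 2, params@param1, blurSigma)
    edgesInt <- matrix(as.integer(edges != 0), nrow = nrow(edges))
    if (!all(dim(edgesInt) == dim(image))) stop("edge map size mismatch")
    acc <- .cpp_hough_vote(edgesInt, gxy$gx, gxy$gy, rmin, rmax)
    idx <- which(.localMaxima8(acc) & acc >= params@param2, arr.ind = TRUE)
    if (nrow(idx) == 0) return(.emptyCircles())
    cand <- cbind(idx, votes = acc[idx], r = NA_real_)
  }
  votes <- cand[, "votes"]
  ord <- order(-votes, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  votes <- votes[ord]

  keep <- logical(nrow(cand))
  minD2 <- params@minCenterDist^2
  for (i in seq_len(nrow(cand))) {
    if (any(keep)) {
      prev <- cand[keep, , drop = FALSE]
      d2 <- (prev[, 1] - cand[i, 1])^2 + (prev[, 2] - cand[i, 2])^2
      if (min(d2) < minD2) next
    }
    keep[i] <- TRUE
  }
  cand <- cand[keep, , drop = FALSE]
  votes <- votes[keep]

  out <- lapply(seq_len(nrow(cand)), function(i) {
    cy <- cand[i, 1] - 1; cx <- cand[i, 2] - 1
    rm <- .cpp_radius_mode(edgesInt, cx, cy, rmin, rmax)
    rad <- if (isEdgeMap) cand[i, "r"] else rm$radius
    data.frame(a = cx, b = cy, r = rad, votes = votes[i])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Verify detected circles against the edge map
#'
#' Samples points evenly along each circle's perimeter and records the
#' fraction lying within 1 px of an edge pixel; a circle is accepted when
#' that support reaches \code{supportThreshold}. Raising the threshold never
#' accepts more circles.
#'
#' @param circlesDf data.frame with columns \code{a}, \code{b}, \code{r}
#'   (as returned by \code{\link{houghCircles}}).
#' @param edges binary edge map.
#' @param supportThreshold fraction in [0, 1].
#' @param nSamples number of perimeter sample points.
#' @return the data.frame with added \code{support} and \code{accepted}
#'   columns.
#' @export
verifyPerimeter <- function(circlesDf, edges, supportThreshold = 0.3,
                            nSamples = 64L) {
  stopifnot(supportThreshold >= 0, supportThreshold <= 1)
  edgesInt <- matrix(as.integer(edges != 0), nrow = nrow(edges))
  n <- nrow(circlesDf)
  support <- numeric(n)
  for (i in seq_len(n))
    support[i] <- .cpp_perimeter_support(edgesInt, circlesDf$a[i], circlesDf$b[i],
                                         circlesDf$r[i], as.integer(nSamples))
  circlesDf$support <- support
  circlesDf$accepted <- support >= supportThreshold
  circlesDf
}
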