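# ROI localization: hierarchical region proposals (graph-based segmentation
# followed by agglomerative merging of adjacent regions, recording every
# bounding box along the merge tree) classified by the convolutional network.

#' Propose candidate regions by hierarchical grouping
#'
#' The image is downscaled, segmented into small coherent regions by
#' graph-based (Felzenszwalb-Huttenlocher) segmentation, and the regions are
#' merged bottom-up, most-similar adjacent pair first, using intensity, size
#' and bounding-box fill similarity. The bounding box of every region in the
#' hierarchy is a proposal; boxes created later (coarser groupings, more
#' likely to cover a whole object such as the chamber) are ranked first.
#'
#' @param image grayscale matrix or RGB array (0-255).
#' @param maxProposals maximum number of boxes returned.
#' @param segmentScale Felzenszwalb scale parameter k (larger = coarser
#'   initial segmentation).
#' @param minSegment minimum initial segment size in (downscaled) pixels.
#' @param workingSize images are downscaled so the longer side is at most
#'   this many pixels before segmentation.
#' @return list of \code{\link{RegionBox-class}} objects in original image
#'   coordinates, ranked.
#' @export
proposeRegions <- function(image, maxProposals = 200L, segmentScale = 300,
                           minSegment = 20L, workingSize = 200L) {
  assertImage(image)
  gray <- toGrayscale(image)
  H <- nrow(gray); W <- ncol(gray)
  s <- max(1, max(H, W) / workingSize)
  h <- max(8L, round(H / s)); w <- max(8L, round(W / s))
  small <- if (s > 1) .cpp_resize_bilinear(gray, h, w) else gray
  small <- .cpp_gaussian_blur(small, 0.8)

  lab <- .cpp_felzenszwalb(small, segmentScale, as.integer(minSegment))
  st <- .cpp_region_stats(lab, small)
  adj <- .cpp_region_adjacency(lab)
  nReg <- length(st$size)
  area <- h * w

  size <- st$size; meanI <- st$mean
  bx0 <- st$x0; by0 <- st$y0; bx1 <- st$x1; by1 <- st$y1
  level <- rep(0L, nReg)

  simOf <- function(i, j) {
    sInt <- 1 - abs(meanI[i] - meanI[j]) / 255
    sSize <- 1 - (size[i] + size[j]) / area
    mergedBox <- (max(bx1[i], bx1[j]) - min(bx0[i], bx0[j])) *
                 (max(by1[i], by1[j]) - min(by0[i], by0[j]))
    sFill <- 1 - (mergedBox - size[i] - size[j]) / area
    sInt + sSize + sFill
  }

  # adjacency as an edge table with similarities, merged greedily
  edges <- if (nrow(adj) > 0)
    data.frame(i = adj[, 1], j = adj[, 2],
               s = vapply(seq_len(nrow(adj)), function(k) simOf(adj[k, 1], adj[k, 2]),
                          numeric(1)))
  else data.frame(i = integer(0), j = integer(0), s = numeric(0))

  nextId <- nReg
  lvl <- 0L
  while (nrow(edges) > 0) {
    best <- which.max(edges$s)
    i <- edges$i[best]; j <- edges$j[best]
    nextId <- nextId + 1L
    lvl <- lvl + 1L
    size[nextId] <- size[i] + size[j]
    meanI[nextId] <- (meanI[i] * size[i] + meanI[j] * size[j]) / size[nextId]
    bx0[nextId] <- min(bx0[i], bx0[j]); by0[nextId] <- min(by0[i], by0[j])
    bx1[nextId] <- max(bx1[i], bx1[j]); by1[nextId] <- max(by1[i], by1[j])
    level[nextId] <- lvl
    touched <- edges$i %in% c(i, j) | edges$j %in% c(i, j)
    nbrs <- setdiff(unique(c(edges$i[touched], edges$j[touched])), c(i, j))
    edges <- edges[!touched, , drop = FALSE]
    if (length(nbrs) > 0) {
      newE <- data.frame(i = nbrs, j = nextId,
                         s = vapply(nbrs, function(k) simOf(k, nextId), numeric(1)))
      edges <- rbind(edges, newE)
    }
  }

  ord <- order(-level, -size[seq_along(level)])
  sy <- H / h; sx <- W / w
  boxes <- list()
  seen <- character(0)
  for (id in ord) {
    x0 <- max(0, floor(bx0[id] * sx)); y0 <- max(0, floor(by0[id] * sy))
    x1 <- min(W, ceiling(bx1[id] * sx)); y1 <- min(H, ceiling(by1[id] * sy))
    if (x1 - x0 < 8 || y1 - y0 < 8) next
    key <- paste(x0, y0, x1, y1)
    if (key %in% seen) next
    seen <- c(seen, key)
    boxes[[length(boxes) + 1L]] <- RegionBox(x0, y0, x1, y1)
    if (length(boxes) >= maxProposals) break
  }
  boxes
}

#' Crop a region and prepare it for classification
#'
#' Crops the box out of the image, resizes it to the classifier input size
#' with bilinear interpolation (aspect ratio not preserved), and scales
#' intensities to [0, 1].
#'
#' @param image grayscale matrix or RGB array (0-255).
#' @param box a \code{\link{RegionBox-class}} inside the image.
#' @param size integer(2) target height and width.
#' @return resized crop with intensities in [0, 1].
#' @export
preprocessCrop <- function(image, box, size = c(256L, 256L)) {
  crop <- cropBox(image, box)
  resizeImage(crop, size[1], size[2]) / 255
}

#' Extract the chamber ROI from a phone image
#'
#' Proposes regions, classifies every proposal with the trained network, and
#' returns the crop of the selected ROI-labelled proposal: the largest-area
#' proposal whose ROI probability reaches \code{scoreThreshold}, ties broken
#' by higher score. A well-trained classifier saturates its score on any pure
#' chamber crop -- a single grid square scores as high as the full chamber --
#' so the score ranks reliability of the label, not quality of the crop;
#' among accepted crops the largest is the fullest chamber view, while
#' oversized chamber-plus-clutter boxes are already rejected by the label
#' (they are trained as non-ROI). If no proposal is classified as ROI, a
#' condition of class \code{hemocount_noRoiFound} is signalled; callers may
#' catch it and fall back to the whole image.
#'
#' @param image grayscale matrix or RGB array (0-255).
#' @param model a trained \code{roiClassifier}.
#' @param maxProposals maximum proposals to score.
#' @param scoreThreshold minimum ROI probability for the ROI label.
#' @return list with \code{crop} (image subarray, 0-255) and \code{region}
#'   (a \code{\link{ClassifiedRegion-class}}).
#' @export
extractRoi <- function(image, model, maxProposals = 200L, scoreThreshold = 0.5) {
  stopifnot(inherits(model, "roiClassifier"))
  boxes <- proposeRegions(image, maxProposals)
  if (length(boxes) == 0)
    stop(structure(class = c("hemocount_noRoiFound", "error", "condition"),
                   list(message = "no region proposals produced", call = NULL)))
  crops <- lapply(boxes, function(b) cropBox(image, b))
  probs <- predictClassifier(model, crops)
  scores <- probs[, "ROI"]
  isRoi <- scores >= scoreThreshold
  if (!any(isRoi))
    stop(structure(class = c("hemocount_noRoiFound", "error", "condition"),
                   list(message = "no proposal classified as ROI", call = NULL)))
  areas <- vapply(boxes, boxArea, numeric(1))
  cand <- which(isRoi)
  ord <- cand[order(-areas[cand], -scores[cand])]
  best <- ord[1]
  list(crop = cropBox(image, boxes[[best]]),
       region = ClassifiedRegion(boxes[[best]], 1L, scores[best]))
}
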