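# Independent brute-force oracles used to pin down expected values.

# symmetric boundary reflection on 1-based indices
reflect1 <- function(i, n) {
  i0 <- i - 1
  while (i0 < 0 || i0 >= n) {
    if (i0 < 0) i0 <- -i0 - 1
    if (i0 >= n) i0 <- 2 * n - i0 - 1
  }
  i0 + 1
}

# literal double-loop evaluation of the fits/hits definitions (binary) and
# neighborhood min/max (grayscale), with reflected borders
oracleMorph <- function(img, se, dilate) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(se); kc <- ncol(se)
  orr <- (kr + 1) / 2; occ <- (kc + 1) / 2
  out <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    vals <- c()
    for (i in 1:kr) for (j in 1:kc) {
      if (!se[i, j]) next
      vals <- c(vals, img[reflect1(r + i - orr, nr), reflect1(c + j - occ, nc)])
    }
    out[r, c] <- if (dilate) max(vals) else min(vals)
  }
  out
}

# exhaustive (a, b, r) circle accumulator: support(a, b, r) = number of edge
# pixels whose rounded distance to (a, b) equals r; detections are triples
# whose support reaches minFrac of the ideal perimeter, reduced by greedy
# suppression of nearby centers (support-descending order)
oracleHoughCircles <- function(edges, rmin, rmax, minFrac = 0.6, minCenterDist = 10) {
  ep <- which(edges != 0, arr.ind = TRUE)
  if (nrow(ep) == 0) return(data.frame(a = numeric(0), b = numeric(0), r = numeric(0)))
  nr <- nrow(edges); nc <- ncol(edges)
  centers <- expand.grid(row = 1:nr, col = 1:nc)
  D <- sqrt(outer(centers$row, ep[, 1], "-")^2 + outer(centers$col, ep[, 2], "-")^2)
  hits <- NULL
  for (r in rmin:rmax) {
    supp <- rowSums(round(D) == r)
    ok <- which(supp >= minFrac * 2 * pi * r)
    if (length(ok) > 0)
      hits <- rbind(hits, data.frame(a = centers$col[ok] - 1,
                                     b = centers$row[ok] - 1,
                                     r = r, support = supp[ok]))
  }
  if (is.null(hits)) return(data.frame(a = numeric(0), b = numeric(0), r = numeric(0)))
  hits <- hits[order(-hits$support, hits$b, hits$a), ]
  kept <- hits[0, ]
  for (i in seq_len(nrow(hits))) {
    if (nrow(kept) > 0 &&
        min((kept$a - hits$a[i])^2 + (kept$b - hits$b[i])^2) < minCenterDist^2) next
    kept <- rbind(kept, hits[i, ])
  }
  kept
}

# draw a one-pixel ring into a zero matrix (edge-map fixture)
drawRing <- function(mat, cx, cy, r) {
  th <- seq(0, 2 * pi, length.out = max(64, round(16 * r)))
  mat[cbind(round(cy + r * sin(th)) + 1, round(cx + r * cos(th)) + 1)] <- 255
  mat
}
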