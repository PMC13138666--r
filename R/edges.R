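#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, and double-threshold hysteresis: pixels
#' above \code{high} seed edges, pixels between \code{low} and \code{high}
#' are kept only when 8-connected to a seed.
#'
#' @param image grayscale numeric matrix (0-255).
#' @param low,high hysteresis thresholds on gradient magnitude,
#'   \code{high >= low > 0}.
#' @param sigma Gaussian sigma applied before differentiation (0 disables
#'   smoothing).
#' @return binary matrix with edge pixels 255 and background 0.
#' @examples
#' step <- cbind(matrix(0, 32, 16), matrix(255, 32, 16))
#' sum(cannyEdges(step, 20, 60) > 0) > 0
#' @export
cannyEdges <- function(image, low, high, sigma = 1) {
  assertImage(image)
  if (length(dim(image)) != 2) stop("cannyEdges expects a grayscale matrix")
  if (!is.finite(low) || !is.finite(high) || low <= 0 || high < low)
    stop("thresholds must satisfy high >= low > 0")
  out <- .cpp_canny(image, low, high, sigma)
  storage.mode(out) <- "double"
  out
}
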