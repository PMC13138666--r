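# Mathematical morphology. On binary (0/1) images erosion keeps a pixel iff
# the structuring element, centered there, fits entirely inside the
# foreground, and dilation iff it hits the foreground; the grayscale
# operators are the neighborhood minimum / maximum, which reduce exactly to
# those set-theoretic rules on 0/1 images. Borders are reflected.

#' Create a structuring element
#'
#' @param shape "square" or "disc".
#' @param size odd side length / diameter in pixels, centered origin.
#' @return a logical matrix mask.
#' @examples
#' structuringElement("disc", 5)
#' @export
structuringElement <- function(shape = c("square", "disc"), size = 3L) {
  shape <- match.arg(shape)
  size <- as.integer(size)
  if (size < 1 || size %% 2 == 0) stop("size must be odd and >= 1")
  if (shape == "square") return(matrix(TRUE, size, size))
  r <- (size - 1) / 2
  d <- sqrt(outer((-r:r)^2, (-r:r)^2, "+"))
  d <= r + 1e-9
}

.checkSe <- function(se) {
  if (is.numeric(se)) se <- se != 0
  if (!is.matrix(se) || !is.logical(se) || !any(se))
    stop("structuring element must be a non-empty logical matrix")
  if (nrow(se) %% 2 == 0 || ncol(se) %% 2 == 0)
    stop("structuring element dimensions must be odd (centered origin)")
  se
}

#' Morphological erosion
#'
#' Grayscale erosion (neighborhood minimum over the structuring element,
#' reflected borders). On 0/1 images this equals the binary rule: output 1
#' iff the element fits the foreground.
#'
#' @param image numeric matrix (grayscale or 0/1).
#' @param se logical matrix from \code{\link{structuringElement}}.
#' @return eroded matrix.
#' @export
morphErode <- function(image, se = structuringElement("square", 3L)) {
  assertImage(image)
  .cpp_morph(image, .checkSe(se), dilate = FALSE)
}

#' Morphological dilation
#'
#' Grayscale dilation (neighborhood maximum, reflected borders); on 0/1
#' images: output 1 iff the element hits the foreground.
#'
#' @inheritParams morphErode
#' @return dilated matrix.
#' @export
morphDilate <- function(image, se = structuringElement("square", 3L)) {
  assertImage(image)
  .cpp_morph(image, .checkSe(se), dilate = TRUE)
}

#' Morphological opening
#'
#' Erosion followed by dilation with the same element. Removes bright
#' structures smaller than the element while preserving larger shapes;
#' idempotent and anti-extensive.
#'
#' @inheritParams morphErode
#' @return opened matrix.
#' @export
morphOpen <- function(image, se = structuringElement("square", 3L)) {
  se <- .checkSe(se)
  morphDilate(morphErode(image, se), se)
}
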