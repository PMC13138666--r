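# Raster images are plain numeric arrays in 0-255: a matrix (h x w) for
# grayscale or an h x w x 3 array for RGB. Pixel (x, y) is 0-based with
# x = column - 1, y = row - 1; boxes are half-open [x0,x1) x [y0,y1).

assertImage <- function(img) {
  if (!is.numeric(img) || length(dim(img)) < 2)
    stop("image must be a numeric matrix or h x w x 3 array")
  d <- dim(img)
  if (length(d) == 3 && !d[3] %in% c(1L, 3L))
    stop("3-d images must have 1 or 3 planes")
  if (any(d[1:2] < 1) || length(img) == 0) stop("image must be non-empty")
  invisible(img)
}

imageChannels <- function(img) if (length(dim(img)) == 3) dim(img)[3] else 1L

#' Convert an RGB image to grayscale
#'
#' Uses the ITU-R BT.601 luminance weights 0.299 R + 0.587 G + 0.114 B.
#' Single-plane input is returned as a matrix unchanged.
#'
#' @param image numeric matrix (h x w) or array (h x w x 3), intensities 0-255.
#' @return numeric matrix of the same spatial size.
#' @export
toGrayscale <- function(image) {
  assertImage(image)
  if (length(dim(image)) == 2) return(image)
  if (dim(image)[3] == 1) return(image[, , 1])
  if (dim(image)[3] != 3) stop("expected a 3-plane RGB image")
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Read a PNG or JPEG image
#'
#' @param path image file; format chosen by extension.
#' @return numeric matrix or h x w x 3 array with intensities 0-255.
#' @export
readImageFile <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]  # drop alpha
  if (length(dim(img)) == 3 && dim(img)[3] == 1) img <- img[, , 1]
  img * 255
}

#' Write an image as PNG
#'
#' @param image numeric matrix or h x w x 3 array, intensities 0-255.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeImagePNG <- function(image, path) {
  assertImage(image)
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

#' Crop an image to a region box
#'
#' @param image numeric matrix or array.
#' @param box a \code{\link{RegionBox-class}} in 0-based half-open coordinates.
#' @return the cropped image.
#' @export
cropBox <- function(image, box) {
  assertImage(image)
  d <- dim(image)
  if (box@x0 < 0 || box@y0 < 0 || box@x1 > d[2] || box@y1 > d[1])
    stop("box exceeds image bounds")
  rows <- (floor(box@y0) + 1):ceiling(box@y1)
  cols <- (floor(box@x0) + 1):ceiling(box@x1)
  if (length(d) == 3) image[rows, cols, , drop = FALSE] else image[rows, cols, drop = FALSE]
}

#' Resize an image with bilinear interpolation
#'
#' @param image numeric matrix or h x w x 3 array.
#' @param height,width target size in pixels.
#' @return resized image of the same kind.
#' @export
resizeImage <- function(image, height, width) {
  assertImage(image)
  if (length(dim(image)) == 2)
    return(.cpp_resize_bilinear(image, as.integer(height), as.integer(width)))
  planes <- lapply(seq_len(dim(image)[3]), function(k)
    .cpp_resize_bilinear(image[, , k], as.integer(height), as.integer(width)))
  array(unlist(planes), dim = c(height, width, dim(image)[3]))
}
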