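#' Image conventions and raster I/O
#'
#' Throughout the package a grayscale image is a plain numeric matrix of
#' intensities in \code{[0, 255]} (rows = image rows), and an RGB raster is a
#' \code{height x width x 3} array on the same scale. Binary layers produced by
#' segmentation use foreground = 255, background = 0, so they can be fed to the
#' co-occurrence analysis as ordinary grayscale images.
#'
#' @param path path to a PNG file.
#' @return \code{read_image()} returns a matrix (grayscale PNG) or a
#'   \code{h x w x 3} array (color PNG), intensities in \code{[0, 255]}.
#' @export
read_image <- function(path) {
  x <- png::readPNG(path)
  x <- round(x * 255)
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] == 1L) x <- x[, , 1L]
    else if (dim(x)[3] >= 3L) x <- x[, , 1:3, drop = FALSE] # drop alpha
  }
  x
}

#' @rdname read_image
#' @param img grayscale matrix or RGB array, intensities in \code{[0, 255]}.
#' @export
write_image <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Convert a raster to grayscale
#'
#' Luminance conversion with ITU-R BT.601 weights (0.299, 0.587, 0.114),
#' rounded to the nearest integer. Single-channel input passes through
#' unchanged.
#'
#' @param img a grayscale matrix, \code{h x w x 1}, or \code{h x w x 3} RGB
#'   array with intensities in \code{[0, 255]}.
#' @return an integer-valued matrix of intensities in \code{[0, 255]}.
#' @export
to_grayscale <- function(img) {
  if (length(img) == 0L)
    stopf("empty raster", class = "scmhand_empty_image")
  d <- dim(img)
  if (is.null(d) || length(d) < 2L)
    stopf("expected a matrix or array raster", class = "scmhand_bad_image")
  if (length(d) == 2L) return(img)
  g <- if (d[3] == 1L) img[, , 1L]
       else round(0.299 * img[, , 1L] + 0.587 * img[, , 2L] +
                  0.114 * img[, , 3L])
  dim(g) <- d[1:2] # keep matrix shape even for 1-pixel rasters
  g
}

# EBImage stores images column-major with x = columns; our matrices are plain
# row/col intensity grids on [0,255]. These two keep the scale conversion in
# one place (EBImage operates on [0,1]).
as_eb <- function(mat) EBImage::Image(t(mat) / 255)
from_eb <- function(img) t(EBImage::imageData(img)) * 255
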