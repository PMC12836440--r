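# Grayscale images are plain integer matrices with values in [0, 255],
# indexed (row, column) with a 0-based top-left origin at the API surface.
# Binary images are logical matrices (TRUE = foreground).

#' Validate a grayscale image
#'
#' A grayscale image is an integer matrix with every value in \[0, 255\].
#'
#' @param img object to validate.
#' @return `img` invisibly, as an integer matrix.
#' @keywords internal
assert_gray <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("grayscale image must be a numeric matrix", call. = FALSE)
  if (nrow(img) < 1L || ncol(img) < 1L)
    stop("grayscale image must have positive dimensions", call. = FALSE)
  if (anyNA(img) || any(img < 0) || any(img > 255) || any(img != round(img)))
    stop("grayscale intensities must be integers in [0, 255]", call. = FALSE)
  invisible(matrix(as.integer(img), nrow(img), ncol(img)))
}

#' @keywords internal
assert_binary <- function(img) {
  if (!is.matrix(img) || !is.logical(img))
    stop("binary image must be a logical matrix", call. = FALSE)
  if (anyNA(img)) stop("binary image must not contain NA", call. = FALSE)
  invisible(img)
}

#' Specify a rectangular region of interest
#'
#' Coordinates follow the raster convention used throughout the package:
#' 0-based, top-left origin, half-open windows, so the ROI covers columns
#' `[x, x + width)` and rows `[y, y + height)`. The 100 x 100 px default is
#' the condylar ROI size used for panoramic radiographs.
#'
#' @param x,y 0-based column/row of the top-left corner.
#' @param width,height ROI extent in pixels (both at least 8).
#' @return An object of class `roi_spec`.
#' @export
#' @examples
#' roi_spec(10, 20)            # 100 x 100 window at column 10, row 20
#' roi_spec(0, 0, 64, 64)
roi_spec <- function(x, y, width = 100L, height = 100L) {
  x <- as.integer(x); y <- as.integer(y)
  width <- as.integer(width); height <- as.integer(height)
  if (is.na(x) || is.na(y) || x < 0L || y < 0L)
    stop("ROI origin must satisfy x >= 0 and y >= 0", call. = FALSE)
  if (is.na(width) || is.na(height) || width < 8L || height < 8L)
    stop("ROI width and height must be at least 8 pixels", call. = FALSE)
  structure(list(x = x, y = y, width = width, height = height),
            class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("ROI: %d x %d px at (x = %d, y = %d), 0-based top-left origin\n",
              x$width, x$height, x$x, x$y))
  invisible(x)
}

#' Load a radiograph as an 8-bit grayscale matrix
#'
#' Reads a PNG or TIFF image and normalizes it to an integer matrix in
#' \[0, 255\]. Multi-channel images are collapsed by the per-pixel channel
#' mean; higher bit depths are rescaled linearly so the representable
#' maximum maps to 255.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return Integer matrix (rows x columns) of intensities in \[0, 255\].
#' @export
load_grayscale <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("cannot read image: no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' for ", path,
         " (expected png/tif/tiff)", call. = FALSE)
  )
  # readPNG/readTIFF return values in [0, 1]; drop alpha, average channels
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3L] %in% c(2L, 4L)) arr <- arr[, , -dim(arr)[3L], drop = FALSE]
    arr <- apply(arr, c(1L, 2L), mean)
  }
  if (length(arr) == 0L) stop("zero-area image: ", path, call. = FALSE)
  assert_gray(matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr)))
}

#' Extract a region of interest
#'
#' Copies the half-open window `[y, y + height) x [x, x + width)` out of a
#' grayscale image. The result is an independent copy; modifying it never
#' touches the source.
#'
#' @param img grayscale image matrix.
#' @param roi an [roi_spec()].
#' @return Grayscale matrix of dimension `height x width`.
#' @export
extract_roi <- function(img, roi) {
  img <- assert_gray(img)
  if (!inherits(roi, "roi_spec")) stop("roi must be an roi_spec", call. = FALSE)
  over_x <- roi$x + roi$width - ncol(img)
  over_y <- roi$y + roi$height - nrow(img)
  if (over_x > 0L || over_y > 0L)
    stop(sprintf(
      "ROI exceeds image bounds by %d px in x and %d px in y (image %d x %d)",
      max(over_x, 0L), max(over_y, 0L), ncol(img), nrow(img)), call. = FALSE)
  img[(roi$y + 1L):(roi$y + roi$height),
      (roi$x + 1L):(roi$x + roi$width), drop = FALSE]
}

#' Write a grayscale or binary image to disk
#'
#' Grayscale matrices round-trip losslessly through 8-bit PNG/TIFF; binary
#' matrices are written as 0/255.
#'
#' @param img grayscale (integer) or binary (logical) matrix.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  if (is.logical(img)) {
    assert_binary(img)
    img <- matrix(ifelse(img, 255L, 0L), nrow(img), ncol(img))
  }
  img <- assert_gray(img)
  if (!dir.exists(dirname(path)))
    stop("cannot write image: no such directory: ", dirname(path),
         call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  norm <- img / 255
  switch(ext,
    png = png::writePNG(norm, path),
    tif = ,
    tiff = tiff::writeTIFF(norm, path, bits.per.sample = 8L),
    stop("unsupported output format '", ext, "'", call. = FALSE)
  )
  invisible(path)
}
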