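# Box-counting fractal dimension: cover the binary image with grids of
# edge length eps, count occupied cells N(eps), and estimate
# FD = -slope of the OLS fit of log N(eps) on log eps.

#' Default box-size schedule
#'
#' The standard box-edge schedule of the macro environment used for dental
#' radiograph fractal analysis, capped at the shorter image side. The
#' schedule is echoed in every result record because FD values are only
#' comparable across studies under the same schedule.
#'
#' @param bin optional binary image; sizes exceeding `min(dim(bin))` are
#'   dropped.
#' @return Integer vector of box edge lengths.
#' @export
default_box_sizes <- function(bin = NULL) {
  sizes <- c(2L, 3L, 4L, 6L, 8L, 12L, 16L, 32L, 64L)
  if (!is.null(bin)) sizes <- sizes[sizes <= min(dim(bin))]
  sizes
}

#' Count occupied boxes at one scale
#'
#' Grid anchored at the top-left corner; edge boxes may be partial. Returns
#' the number of grid cells of edge `size` containing at least one
#' foreground pixel.
#'
#' @param bin logical matrix.
#' @param size box edge length in pixels, `1 <= size <= min(dim(bin))`.
#' @return Integer count.
#' @export
count_boxes <- function(bin, size) {
  assert_binary(bin)
  size <- as.integer(size)
  if (is.na(size) || size < 1L || size > min(dim(bin)))
    stop("box size must satisfy 1 <= size <= min(image dimensions)",
         call. = FALSE)
  idx <- which(bin, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0L)
  cell_r <- (idx[, 1L] - 1L) %/% size
  cell_c <- (idx[, 2L] - 1L) %/% size
  length(unique(cell_r * (ncol(bin) %/% size + 1L) + cell_c))
}

#' Box-counting fractal dimension of a binary image
#'
#' Ordinary least squares of `log N(eps)` on `log eps` over the given box
#' sizes; `fd = -slope`. The fit uses a single top-left-anchored grid per
#' scale (no offset averaging), mirroring the automated macro protocol.
#'
#' @param bin logical matrix with at least one foreground pixel.
#' @param box_sizes integer vector of at least 3 distinct box edges, all
#'   `<= min(dim(bin))`. Defaults to [default_box_sizes()].
#' @return Object of class `fd_boxcount`: list with `box_sizes`, `counts`,
#'   `slope`, `intercept`, `r_squared` and `fd`.
#' @export
#' @examples
#' carpet <- make_sierpinski_carpet(4)
#' fractal_dimension(carpet, c(1, 3, 9, 27))$fd  # ~ log(8)/log(3)
fractal_dimension <- function(bin, box_sizes = default_box_sizes(bin)) {
  assert_binary(bin)
  if (!any(bin)) stop("no foreground to measure", call. = FALSE)
  box_sizes <- sort(unique(as.integer(box_sizes)))
  if (any(box_sizes < 1L) || any(box_sizes > min(dim(bin))))
    stop("all box sizes must lie in [1, min(image dimensions)]",
         call. = FALSE)
  if (length(box_sizes) < 3L)
    stop("need at least 3 distinct usable box sizes", call. = FALSE)
  counts <- vapply(box_sizes, function(s) count_boxes(bin, s), integer(1))
  lx <- log(box_sizes); ly <- log(counts)
  slope <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  intercept <- mean(ly) - slope * mean(lx)
  ss_res <- sum((ly - intercept - slope * lx)^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r_squared <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  fd <- -slope
  if (!is.finite(fd) || fd <= 0 || fd > 2 + 1e-9)
    stop(sprintf(
      "box-count fit gave fd = %.4f outside (0, 2]: pattern too sparse or degenerate for these box sizes",
      fd), call. = FALSE)
  structure(list(
    box_sizes = box_sizes,
    counts = counts,
    slope = slope,
    intercept = intercept,
    r_squared = r_squared,
    fd = fd), class = "fd_boxcount")
}

#' @export
print.fd_boxcount <- function(x, ...) {
  cat(sprintf("Box-counting fractal dimension: %.4f (R^2 = %.4f)\n",
              x$fd, x$r_squared))
  cat("  box sizes:", paste(x$box_sizes, collapse = " "), "\n")
  cat("  counts:   ", paste(x$counts, collapse = " "), "\n")
  invisible(x)
}

#' End-to-end FD of one condylar ROI
#'
#' Runs the ten-step preprocessing chain and box counting on the resulting
#' skeleton; one call per condyle. A flat ROI whose skeleton is empty is a
#' degenerate input and raises an error rather than returning a number.
#'
#' @param img grayscale radiograph matrix.
#' @param roi an [roi_spec()].
#' @param config a [pipeline_config()].
#' @param box_sizes box-edge schedule; defaults to [default_box_sizes()]
#'   capped at the ROI size.
#' @param subject,side optional identifiers echoed into the record.
#' @return List with `trace` (`fd_trace`) and `result` (`fd_boxcount`),
#'   plus a flat `record` list (subject, side, fd, r_squared, config echo).
#' @export
fd_from_image <- function(img, roi, config = pipeline_config(),
                          box_sizes = NULL, subject = NA_character_,
                          side = NA_character_) {
  trace <- preprocess_roi(img, roi, config)
  skeleton <- trace$steps$skeleton
  if (!any(skeleton))
    stop("degenerate ROI: preprocessing produced an empty skeleton",
         call. = FALSE)
  if (is.null(box_sizes)) box_sizes <- default_box_sizes(skeleton)
  result <- fractal_dimension(skeleton, box_sizes)
  list(trace = trace, result = result,
       record = list(subject = subject, side = side, fd = result$fd,
                     slope = result$slope, intercept = result$intercept,
                     r_squared = result$r_squared,
                     box_sizes = result$box_sizes, counts = result$counts,
                     gaussian_sigma = config$gaussian_sigma,
                     binarize_threshold = config$binarize_threshold,
                     morphology_radius = config$morphology_radius,
                     morphology_iterations = config$morphology_iterations))
}
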