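# Ten-step preprocessing chain turning a grayscale condylar ROI into a
# skeletonized binary trabecular pattern:
#   (1) ROI, (2) duplicate, (3) Gaussian blur, (4) subtract blurred from
#   duplicate, (5) add 128, (6) binarize, (7) erode, (8) dilate,
#   (9) invert, (10) skeletonize.
# Steps 3-5 are a background-subtraction that recenters local texture at
# gray level 128; 6-10 reduce it to a 1-px-wide trabecular skeleton.

#' Configuration for the trabecular preprocessing chain
#'
#' @param gaussian_sigma standard deviation (pixels) of the Gaussian
#'   background estimate. The default of 35 px follows the established
#'   dental-radiograph fractal-analysis protocol for 100 x 100 px condylar
#'   ROIs: the blur must be wide enough to capture soft-tissue / ramus
#'   background without erasing trabecular detail.
#' @param offset gray levels added after background subtraction; fixed at
#'   128 so zero-difference texture sits mid-scale.
#' @param binarize_threshold gray level; foreground where intensity is
#'   strictly greater. 128 is the natural cut after the recentering step.
#' @param morphology_radius half-width of the square structuring element
#'   (radius 1 = 3 x 3) used by erosion and dilation.
#' @param morphology_iterations number of passes of each morphology step.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(gaussian_sigma = 35, offset = 128L,
                            binarize_threshold = 128L,
                            morphology_radius = 1L,
                            morphology_iterations = 1L) {
  if (!is.numeric(gaussian_sigma) || gaussian_sigma <= 0)
    stop("gaussian_sigma must be > 0", call. = FALSE)
  if (offset != 128L) stop("offset is fixed at 128 gray levels", call. = FALSE)
  if (binarize_threshold <= 0 || binarize_threshold >= 255)
    stop("binarize_threshold must lie strictly inside (0, 255)", call. = FALSE)
  if (morphology_radius < 1L) stop("morphology_radius must be >= 1", call. = FALSE)
  if (morphology_iterations < 1L)
    stop("morphology_iterations must be >= 1", call. = FALSE)
  structure(list(gaussian_sigma = gaussian_sigma,
                 offset = 128L,
                 binarize_threshold = as.integer(binarize_threshold),
                 morphology_radius = as.integer(morphology_radius),
                 morphology_iterations = as.integer(morphology_iterations)),
            class = "pipeline_config")
}

# 1-D convolution matrix with clamped (edge-replicated) indices: row i gives
# the weights applied to the input to produce output i. Blur is then
# K_rows %*% img %*% t(K_cols); per-axis clamping makes this exactly equal
# to full 2-D convolution with edge replication.
conv_matrix <- function(n, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- pmin(pmax(i + seq(-r, r), 1L), n)
    for (j in seq_along(idx)) m[i, idx[j]] <- m[i, idx[j]] + k[j]
  }
  m
}

#' Gaussian blur with edge replication
#'
#' Isotropic Gaussian convolution (kernel truncated at 3 sigma), borders
#' handled by edge replication, result rounded and clamped to \[0, 255\].
#'
#' @param img grayscale matrix.
#' @param sigma kernel standard deviation in pixels (> 0).
#' @return Blurred grayscale matrix of the same dimension.
#' @export
gaussian_blur <- function(img, sigma) {
  img <- assert_gray(img)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a positive number", call. = FALSE)
  out <- conv_matrix(nrow(img), sigma) %*% img %*% t(conv_matrix(ncol(img), sigma))
  matrix(as.integer(pmin(pmax(round(out), 0), 255)), nrow(img), ncol(img))
}

#' Saturating pixelwise subtraction
#'
#' `a - b` clamped below at 0 (8-bit saturating arithmetic).
#'
#' @param a,b grayscale matrices of identical dimension.
#' @return Grayscale matrix.
#' @export
subtract_images <- function(a, b) {
  a <- assert_gray(a); b <- assert_gray(b)
  if (!identical(dim(a), dim(b)))
    stop("images must have identical dimensions", call. = FALSE)
  matrix(pmax(a - b, 0L), nrow(a), ncol(a))
}

#' Saturating offset addition
#'
#' `img + offset` clamped above at 255.
#'
#' @param img grayscale matrix.
#' @param offset gray levels in \[0, 255\].
#' @return Grayscale matrix.
#' @export
add_offset <- function(img, offset = 128L) {
  img <- assert_gray(img)
  offset <- as.integer(offset)
  if (is.na(offset) || offset < 0L || offset > 255L)
    stop("offset must lie in [0, 255]", call. = FALSE)
  matrix(pmin(img + offset, 255L), nrow(img), ncol(img))
}

#' Fixed-threshold binarization
#'
#' Foreground where intensity is strictly greater than the threshold.
#'
#' @param img grayscale matrix.
#' @param threshold gray level strictly inside (0, 255).
#' @return Logical matrix (TRUE = foreground).
#' @export
binarize <- function(img, threshold = 128L) {
  img <- assert_gray(img)
  if (threshold <= 0 || threshold >= 255)
    stop("threshold must lie strictly inside (0, 255)", call. = FALSE)
  img > threshold
}

# Shift a logical matrix by (dr, dc), filling vacated cells with `pad`.
shift_logical <- function(x, dr, dc, pad) {
  n <- nrow(x); m <- ncol(x)
  out <- matrix(pad, n, m)
  rs <- max(1L, 1L + dr):min(n, n + dr)
  cs <- max(1L, 1L + dc):min(m, m + dc)
  if (length(rs) > 0L && length(cs) > 0L)
    out[rs, cs] <- x[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Binary erosion with a square structuring element
#'
#' A pixel survives iff its whole `(2 * radius + 1)^2` neighborhood is
#' foreground. Out-of-image neighbors are treated as `pad` (background by
#' default), so foreground touching the border erodes away.
#'
#' @param bin logical matrix.
#' @param radius structuring-element half-width (>= 1).
#' @param iterations number of passes.
#' @param pad value assumed outside the image.
#' @return Logical matrix.
#' @export
erode <- function(bin, radius = 1L, iterations = 1L, pad = FALSE) {
  assert_binary(bin)
  radius <- as.integer(radius); iterations <- as.integer(iterations)
  if (radius < 1L || iterations < 1L)
    stop("radius and iterations must be >= 1", call. = FALSE)
  for (it in seq_len(iterations)) {
    acc <- bin
    for (dr in -radius:radius) for (dc in -radius:radius) {
      if (dr == 0L && dc == 0L) next
      acc <- acc & shift_logical(bin, dr, dc, pad)
    }
    bin <- acc
  }
  bin
}

#' Binary dilation with a square structuring element
#'
#' A pixel becomes foreground iff any pixel of its neighborhood is
#' foreground; dual of [erode()] under the mirrored border convention.
#'
#' @inheritParams erode
#' @return Logical matrix.
#' @export
dilate <- function(bin, radius = 1L, iterations = 1L, pad = FALSE) {
  assert_binary(bin)
  radius <- as.integer(radius); iterations <- as.integer(iterations)
  if (radius < 1L || iterations < 1L)
    stop("radius and iterations must be >= 1", call. = FALSE)
  for (it in seq_len(iterations)) {
    acc <- bin
    for (dr in -radius:radius) for (dc in -radius:radius) {
      if (dr == 0L && dc == 0L) next
      acc <- acc | shift_logical(bin, dr, dc, pad)
    }
    bin <- acc
  }
  bin
}

#' Invert a binary image
#'
#' Swaps foreground and background; an involution.
#'
#' @param bin logical matrix.
#' @return Logical matrix.
#' @export
invert <- function(bin) {
  assert_binary(bin)
  !bin
}

#' Zhang-Suen skeletonization
#'
#' Iterative two-subiteration thinning of the foreground to 1-px-wide
#' curves with 8-connected foreground. The skeleton is always a subset of
#' the input foreground and thinning is idempotent.
#'
#' @param bin logical matrix.
#' @return Logical matrix.
#' @export
skeletonize <- function(bin) {
  assert_binary(bin)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbors p2..p9 clockwise from north; background padding
      p <- list(
        p2 = shift_logical(bin,  1L,  0L, FALSE),  # north: row - 1 of source
        p3 = shift_logical(bin,  1L, -1L, FALSE),
        p4 = shift_logical(bin,  0L, -1L, FALSE),
        p5 = shift_logical(bin, -1L, -1L, FALSE),
        p6 = shift_logical(bin, -1L,  0L, FALSE),
        p7 = shift_logical(bin, -1L,  1L, FALSE),
        p8 = shift_logical(bin,  0L,  1L, FALSE),
        p9 = shift_logical(bin,  1L,  1L, FALSE)
      )
      b <- Reduce(`+`, p)                      # foreground neighbor count
      seqn <- p[c(2:8, 1)]                     # p3..p9, p2
      a <- Reduce(`+`, Map(function(u, v) (!u) & v, p, seqn))  # 0->1 transitions
      cond <- bin & b >= 2L & b <= 6L & a == 1L
      if (sub == 1L)
        cond <- cond & !(p$p2 & p$p4 & p$p6) & !(p$p4 & p$p6 & p$p8)
      else
        cond <- cond & !(p$p2 & p$p4 & p$p8) & !(p$p2 & p$p6 & p$p8)
      if (any(cond)) { bin <- bin & !cond; changed <- TRUE }
    }
    if (!changed) break
  }
  bin
}

#' Run the full ten-step preprocessing chain
#'
#' Executes, in order: ROI extraction, duplication, Gaussian blur of the
#' duplicate, subtraction of the blurred image from the duplicate, addition
#' of 128 gray levels, binarization, erosion, dilation, inversion and
#' skeletonization. The returned trace holds all ten intermediates, so the
#' standard step montage can be written with [save_image()].
#'
#' @param img grayscale radiograph matrix.
#' @param roi an [roi_spec()] locating the condylar window.
#' @param config a [pipeline_config()].
#' @return An object of class `fd_trace`: list with `steps` (named list of
#'   the 10 intermediates, grayscale then binary) and `config`.
#' @export
preprocess_roi <- function(img, roi, config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config", call. = FALSE)
  roi_img    <- extract_roi(img, roi)
  duplicate  <- roi_img
  blurred    <- gaussian_blur(duplicate, config$gaussian_sigma)
  subtracted <- subtract_images(duplicate, blurred)
  offset_add <- add_offset(subtracted, config$offset)
  binary     <- binarize(offset_add, config$binarize_threshold)
  eroded     <- erode(binary, config$morphology_radius,
                      config$morphology_iterations)
  dilated    <- dilate(eroded, config$morphology_radius,
                       config$morphology_iterations)
  inverted   <- invert(dilated)
  # A binarization with no foreground means no trabecular texture was
  # detected; the inverted plate then has no network to thin, so the
  # skeleton is empty by definition (the degenerate-ROI signal).
  skeleton   <- if (!any(binary)) matrix(FALSE, nrow(binary), ncol(binary))
                else skeletonize(inverted)
  structure(list(
    steps = list(roi = roi_img, duplicate = duplicate, blurred = blurred,
                 subtracted = subtracted, offset_added = offset_add,
                 binary = binary, eroded = eroded, dilated = dilated,
                 inverted = inverted, skeleton = skeleton),
    config = config), class = "fd_trace")
}

#' @export
print.fd_trace <- function(x, ...) {
  sk <- x$steps$skeleton
  cat(sprintf(
    "Trabecular preprocessing trace: %d steps, %d x %d px, skeleton fraction %.4f\n",
    length(x$steps), nrow(sk), ncol(sk), mean(sk)))
  invisible(x)
}

#' Write the ten intermediates of a trace as numbered PNGs
#'
#' @param trace an `fd_trace` from [preprocess_roi()].
#' @param dir output directory (created if absent).
#' @return Character vector of the ten file paths, invisibly.
#' @export
save_trace_steps <- function(trace, dir) {
  if (!inherits(trace, "fd_trace")) stop("not an fd_trace", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("%02d_%s.png", seq_along(trace$steps),
                                  names(trace$steps)))
  for (i in seq_along(paths)) save_image(trace$steps[[i]], paths[i])
  invisible(paths)
}
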