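#' Read an image file as an 8-bit array
#'
#' Reads a PNG or TIFF image and returns it on the 0..255 intensity scale:
#' a matrix for grayscale input, a height x width x 3 array for color input
#' (an alpha channel, if present, is dropped).
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix (grayscale) or height x width x 3 array (RGB),
#'   values in \[0, 255\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_hypoxiafeat(sprintf("unsupported image format '%s'", ext),
                     "hypoxiafeat_io_error"))
  x <- raw * 255
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] >= 3L) x <- x[, , 1:3, drop = FALSE] else x <- x[, , 1]
  }
  x
}

#' Write an image file
#'
#' Writes a grayscale matrix or RGB array (0..255 scale) to PNG or TIFF,
#' quantizing to 8 bits. This is the only place the pipeline quantizes
#' smoothed images.
#'
#' @param img Numeric matrix or height x width x 3 array, values in \[0, 255\].
#' @param path Output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  x <- clamp(round(img), 0, 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop_hypoxiafeat(sprintf("unsupported image format '%s'", ext),
                     "hypoxiafeat_io_error"))
  invisible(path)
}

#' Convert an RGB image to 8-bit grayscale
#'
#' Uses the ITU-R BT.601 luma weights (0.299, 0.587, 0.114), the common
#' rgb2gray convention, and rounds to the integer 8-bit scale.
#'
#' @param img Height x width x 3 numeric array, channel values in \[0, 255\].
#' @return Numeric matrix of the same height and width, integer values in
#'   \[0, 255\].
#' @export
to_gray <- function(img) {
  assert_rgb(img)
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  clamp(round(g), 0, 255)
}

#' Smoothing configuration
#'
#' @param mask_size Odd kernel width in pixels (default 5).
#' @param sigma Gaussian standard deviation in pixels (default 5.0). The
#'   kernel is truncated to the mask and renormalized.
#' @param iterations Number of times the kernel is applied (default 100).
#' @return A list of class `smoothing_config`.
#' @export
smoothing_config <- function(mask_size = 5L, sigma = 5.0, iterations = 100L) {
  if (!is_count(mask_size, 1L) || mask_size %% 2L == 0L)
    stop_hypoxiafeat("mask_size must be an odd integer >= 1", "hypoxiafeat_config_error")
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop_hypoxiafeat("sigma must be > 0", "hypoxiafeat_config_error")
  if (!is_count(iterations, 0L))
    stop_hypoxiafeat("iterations must be a nonnegative integer", "hypoxiafeat_config_error")
  structure(list(mask_size = as.integer(mask_size), sigma = sigma,
                 iterations = as.integer(iterations)),
            class = "smoothing_config")
}

gaussian_taps <- function(mask_size, sigma) {
  h <- (mask_size - 1) / 2
  w <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  w / sum(w)
}

# One separable Gaussian pass with replicate-edge padding.
smooth_pass <- function(X, w) {
  h <- (length(w) - 1L) / 2L
  n <- nrow(X); m <- ncol(X)
  if (h > 0L) {
    P <- X[c(rep(1L, h), seq_len(n), rep(n, h)), , drop = FALSE]
    R <- 0
    for (k in seq_along(w)) R <- R + w[k] * P[k:(k + n - 1L), , drop = FALSE]
    P <- R[, c(rep(1L, h), seq_len(m), rep(m, h)), drop = FALSE]
    R <- 0
    for (k in seq_along(w)) R <- R + w[k] * P[, k:(k + m - 1L), drop = FALSE]
    R
  } else X
}

#' Iterative Gaussian smoothing
#'
#' Applies a truncated Gaussian kernel (separable, replicate-edge padding)
#' `iterations` times. The default configuration (5 x 5 mask, sigma 5,
#' 100 iterations) averages away high-frequency structure while preserving
#' the radial stain gradient. Results are kept in floating point; quantize
#' only on export via [write_image()].
#'
#' @param img Grayscale matrix, values in \[0, 255\].
#' @param cfg A [smoothing_config()].
#' @return Smoothed matrix of identical dimensions, values in \[0, 255\].
#' @export
smooth <- function(img, cfg = smoothing_config()) {
  assert_gray(img)
  if (!inherits(cfg, "smoothing_config")) cfg <- do.call(smoothing_config, cfg)
  w <- gaussian_taps(cfg$mask_size, cfg$sigma)
  for (i in seq_len(cfg$iterations)) img <- smooth_pass(img, w)
  clamp(img, 0, 255)
}

#' Overlay a fitted radial gradient onto an image
#'
#' Renders the piecewise-linear radial intensity profile of a segmented fit
#' as concentric gray levels around `center` and alpha-composites them onto
#' `base`, mirroring how inferred hypoxia gradients are superimposed on raw
#' histology for visual inspection. Pixels beyond the fit's radial extent
#' are left unchanged.
#'
#' @param base RGB array (height x width x 3) or grayscale matrix, 0..255.
#' @param center Numeric `c(x, y)`, 0-based pixel coordinates of the vessel
#'   landmark.
#' @param fit A [segmented_least_squares()] fit over radial distance.
#' @param alpha Overlay opacity in \[0, 1\] (0.5 reproduces the half-opacity
#'   composite view).
#' @return Image of the same shape as `base`.
#' @export
overlay_gradient <- function(base, center, fit, alpha = 0.5) {
  gray_in <- is.matrix(base)
  if (gray_in) {
    assert_gray(base)
    base <- array(rep(base, 3L), dim = c(dim(base), 3L))
  } else assert_rgb(base)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop_hypoxiafeat("alpha must lie in [0, 1]", "hypoxiafeat_config_error")
  stopifnot(inherits(fit, "segmented_fit"))
  rc <- center_to_rc(center, base[, , 1])
  h <- dim(base)[1]; w <- dim(base)[2]
  rmax <- max(fit$segments$end_x)
  if (rmax <= 0)
    stop_hypoxiafeat("fit radial extent must be > 0", "hypoxiafeat_config_error")
  xs <- matrix(rep(seq_len(w), each = h), h)
  ys <- matrix(rep(seq_len(h), w), h)
  r <- sqrt((xs - rc[["col"]])^2 + (ys - rc[["row"]])^2)
  inside <- r <= rmax
  gray <- clamp(predict(fit, pmax(r[inside], min(fit$segments$start_x))), 0, 255)
  out <- base
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[inside] <- (1 - alpha) * plane[inside] + alpha * gray
    out[, , ch] <- plane
  }
  if (gray_in) out[, , 1] else out
}
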