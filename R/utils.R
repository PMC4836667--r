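# Internal helpers shared across modules.
#
# Coordinate convention (package-wide): pixel coordinates are 0-based,
# x = column index increasing rightward, y = row index increasing downward,
# origin at the top-left pixel. Images are stored as base R matrices indexed
# [row, col] = [y + 1, x + 1], values on the 8-bit 0..255 scale (fractional
# values are allowed after smoothing; quantization happens only on export).

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

stop_hypoxiafeat <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hypoxiafeat_error")))
}

assert_gray <- function(img) {
  if (!is.matrix(img) || !is.numeric(img) || nrow(img) < 1L || ncol(img) < 1L)
    stop_hypoxiafeat("grayscale image must be a numeric matrix with >= 1 row and column",
                     "hypoxiafeat_dimension_error")
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop_hypoxiafeat("grayscale intensities must lie in [0, 255] with no missing values",
                     "hypoxiafeat_range_error")
  invisible(img)
}

assert_rgb <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L ||
      dim(img)[1] < 1L || dim(img)[2] < 1L)
    stop_hypoxiafeat("RGB image must be a height x width x 3 numeric array",
                     "hypoxiafeat_dimension_error")
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop_hypoxiafeat("RGB channel values must lie in [0, 255]",
                     "hypoxiafeat_range_error")
  invisible(img)
}

# center given in 0-based (x, y); returns 1-based (row, col)
center_to_rc <- function(center, img) {
  x <- center[[1]]; y <- center[[2]]
  h <- nrow(img); w <- ncol(img)
  if (!is.finite(x) || !is.finite(y) || x < 0 || y < 0 || x > w - 1 || y > h - 1)
    stop_hypoxiafeat(sprintf("center (%s, %s) lies outside the %d x %d image", x, y, w, h),
                     "hypoxiafeat_coordinate_error")
  c(row = y + 1, col = x + 1)
}
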