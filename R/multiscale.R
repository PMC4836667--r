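#' Quad-tree decomposition by intensity variability
#'
#' Recursively splits a rectangular frame into four near-equal rectangles
#' while the coefficient of variation (sd/mean) of the frame's pixel
#' intensities exceeds `tau` (study default 0.02), locating regions of high
#' noise-to-signal ratio at every scale. Works for any aspect ratio: odd
#' extents split into floor/ceil halves. One-pixel frames, frames with zero
#' mean intensity (CV defined as 0 there), and frames at ply 12 never split.
#'
#' @param img Grayscale matrix.
#' @param tau CV split threshold, > 0.
#' @param max_ply Maximum leaf depth (default 12; the root is ply 0).
#' @return Data frame of leaves with 0-based `x`, `y`, `width`, `height`,
#'   and `ply`.
#' @export
quadtree <- function(img, tau = 0.02, max_ply = 12L) {
  assert_gray(img)
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop_hypoxiafeat("tau must be > 0", "hypoxiafeat_config_error")
  leaves <- vector("list", 256L); nl <- 0L
  stack <- list(c(1L, 1L, nrow(img), ncol(img), 0L))   # row, col, h, w, ply
  while (length(stack)) {
    fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    r0 <- fr[1]; c0 <- fr[2]; h <- fr[3]; w <- fr[4]; ply <- fr[5]
    px <- img[r0:(r0 + h - 1L), c0:(c0 + w - 1L)]
    mu <- mean(px)
    cv <- if (mu > 0 && length(px) > 1L) stats::sd(px) / mu else 0
    if (cv > tau && ply < max_ply && (h > 1L || w > 1L)) {
      h1 <- if (h > 1L) h %/% 2L else 1L
      w1 <- if (w > 1L) w %/% 2L else 1L
      rows <- if (h > 1L) list(c(r0, h1), c(r0 + h1, h - h1)) else list(c(r0, h))
      cols <- if (w > 1L) list(c(c0, w1), c(c0 + w1, w - w1)) else list(c(c0, w))
      for (rr in rows) for (cc in cols)
        stack[[length(stack) + 1L]] <- c(rr[1], cc[1], rr[2], cc[2], ply + 1L)
    } else {
      nl <- nl + 1L
      if (nl > length(leaves)) leaves <- c(leaves, vector("list", length(leaves)))
      leaves[[nl]] <- c(x = c0 - 1L, y = r0 - 1L, width = w, height = h, ply = ply)
    }
  }
  as.data.frame(do.call(rbind, leaves[seq_len(nl)]))
}

#' Search-tree statistics of a quad-tree decomposition
#'
#' Reports the leaf-count histogram over ply depth together with the count,
#' sum, mean, median, standard deviation and coefficient of variation of
#' the per-ply leaf counts. The nominal frame size at ply `i` of an
#' `x_dim x y_dim` image is `(x_dim / 2^i) x (y_dim / 2^i)`.
#'
#' @param leaves Leaf data frame from [quadtree()].
#' @param img_dim Optional `c(width, height)` used to annotate frame sizes.
#' @return List of class `ply_stats` with `histogram` (named leaf counts per
#'   ply), summary statistics of those counts, and `frame_sizes`.
#' @export
ply_stats <- function(leaves, img_dim = NULL) {
  if (is.null(leaves) || nrow(leaves) == 0L)
    stop_hypoxiafeat("leaf list is empty", "hypoxiafeat_input_error")
  plys <- sort(unique(leaves$ply))
  histo <- vapply(plys, function(p) sum(leaves$ply == p), integer(1))
  names(histo) <- plys
  cnt <- as.numeric(histo)
  sdv <- if (length(cnt) > 1L) stats::sd(cnt) else 0
  fs <- if (!is.null(img_dim))
    data.frame(ply = plys, width = img_dim[1] / 2^plys, height = img_dim[2] / 2^plys)
  else NULL
  structure(list(histogram = histo,
                 count = length(cnt), sum = sum(cnt), mean = mean(cnt),
                 median = stats::median(cnt), std = sdv,
                 cv = if (mean(cnt) > 0) sdv / mean(cnt) else 0,
                 frame_sizes = fs),
            class = "ply_stats")
}

#' @export
print.ply_stats <- function(x, ...) {
  cat("Quad-tree ply statistics\n leaves per ply:\n")
  print(x$histogram)
  cat(sprintf(" count %d | sum %g | mean %.3f | median %.3f | std %.3f | cv %.3f\n",
              x$count, x$sum, x$mean, x$median, x$std, x$cv))
  invisible(x)
}

#' Euler-Poincare characteristic of a binary image
#'
#' Computes `chi = components - holes` on the pixel lattice with
#' 8-connected foreground and 4-connected background (the standard digital
#' topology pairing), using exact 2 x 2 quad counts: with `C1`, `C3` the
#' numbers of 2 x 2 windows containing exactly one and exactly three
#' foreground pixels and `CD` the number of diagonal pairs,
#' `chi = (C1 - C3 - 2 * CD) / 4` over the zero-padded image.
#'
#' @param binary Logical (or 0/1 numeric) matrix; `TRUE` is foreground.
#' @return Integer Euler characteristic.
#' @export
epc <- function(binary) {
  if (!is.matrix(binary) || length(binary) == 0L)
    stop_hypoxiafeat("binary image must be a nonempty matrix", "hypoxiafeat_input_error")
  B <- binary != 0
  P <- matrix(FALSE, nrow(B) + 2L, ncol(B) + 2L)
  P[2:(nrow(B) + 1L), 2:(ncol(B) + 1L)] <- B
  a <- P[-nrow(P), -ncol(P)]; b <- P[-nrow(P), -1]
  c <- P[-1, -ncol(P)];       d <- P[-1, -1]
  s <- a + b + c + d
  C1 <- sum(s == 1L); C3 <- sum(s == 3L)
  CD <- sum(s == 2L & ((a & d) | (b & c)))
  as.integer(round((C1 - C3 - 2L * CD) / 4))
}

#' Euler-Poincare signature curve of an image
#'
#' Converts an RGB image to grayscale (no smoothing), then for each gray
#' level `i = 1..255` binarizes and records the Euler characteristic,
#' producing a 255-point topological signature of the image. The
#' binarization direction is switchable: `"bright"` (default) takes pixels
#' with intensity `>= i` as foreground, `"dark"` takes intensity `< i`.
#'
#' @param img RGB array or grayscale matrix (0..255).
#' @param foreground `"bright"` or `"dark"`.
#' @return Object of class `epc_signature`: integer vector `chi` of length
#'   255 with attribute `thresholds = 1:255`.
#' @export
epc_signature <- function(img, foreground = c("bright", "dark")) {
  foreground <- match.arg(foreground)
  g <- if (length(dim(img)) == 3L) to_gray(img) else { assert_gray(img); img }
  gi <- as.integer(clamp(round(g), 0, 255))
  dim(gi) <- dim(g)
  chi <- vapply(1:255, function(i) {
    epc(if (foreground == "bright") gi >= i else gi < i)
  }, integer(1))
  structure(chi, class = "epc_signature", thresholds = 1:255,
            foreground = foreground)
}

#' Mean and standard-deviation EPC curves of an image stratum
#'
#' @param signatures List of [epc_signature()] vectors (equal length).
#' @return List with `mean` and `std` curves (length 255) and `n`.
#' @export
mean_epc <- function(signatures) {
  if (length(signatures) < 1L)
    stop_hypoxiafeat("need at least one signature", "hypoxiafeat_input_error")
  M <- do.call(rbind, lapply(signatures, as.numeric))
  std <- if (nrow(M) > 1L) apply(M, 2, stats::sd) else rep(0, ncol(M))
  list(mean = colMeans(M), std = std, n = nrow(M))
}

#' Segmented fit of an EPC signature curve
#'
#' Compresses a 255-point Euler-characteristic curve into a piecewise-linear
#' description via [segmented_least_squares()] (study cost `C = 50000`).
#' The compression factor is `255 / (2 * segments)` since each segment is
#' specified by a slope and an intercept; the normalized error is the total
#' SSE over all segments.
#'
#' @param curve Numeric vector of length 255 (an `epc_signature` or a mean
#'   curve).
#' @param C Segment cost penalty (default 50000).
#' @return List of class `epc_fit` with `fit`, `n_segments`,
#'   `compression_factor`, and `normalized_error`.
#' @export
fit_epc <- function(curve, C = 50000) {
  y <- as.numeric(curve)
  if (length(y) != 255L)
    stop_hypoxiafeat("EPC curve must have 255 points (thresholds 1..255)",
                     "hypoxiafeat_input_error")
  fit <- segmented_least_squares(1:255, y, C)
  k <- nrow(fit$segments)
  structure(list(fit = fit, n_segments = k,
                 compression_factor = 255 / (2 * k),
                 normalized_error = sum(fit$segments$e)),
            class = "epc_fit")
}

#' @export
print.epc_fit <- function(x, ...) {
  cat(sprintf("EPC curve fit: %d segments (%d coefficients), compression factor %.2f, error %.2f\n",
              x$n_segments, 2L * x$n_segments, x$compression_factor, x$normalized_error))
  invisible(x)
}
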