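#' Fixed study intensity intervals
#'
#' The manually derived three-way partition of 8-bit intensity used for the
#' canonical high-concentration image: \[0, 156\] hypoxic (dark stain),
#' \[157, 175\] viable, \[176, 255\] necrotic (bright). Expressed as the
#' threshold pair `(t1, t2) = (156, 175)`.
#'
#' @return Named numeric vector `c(t1 = 156, t2 = 175)`.
#' @export
fixed_study_thresholds <- function() c(t1 = 156, t2 = 175)

#' Two-threshold Otsu multithresholding
#'
#' Finds the pair of intensity thresholds `0 <= t1 < t2 <= 255` maximizing
#' the between-class variance of the three classes they induce on the
#' 256-bin histogram (Otsu's criterion extended to three classes). Smoothed
#' (fractional) images are re-quantized to integer bins first. Ties are
#' broken toward the lexicographically smallest pair.
#'
#' @param img Grayscale matrix, values in \[0, 255\].
#' @return Named numeric vector `c(t1, t2)`.
#' @export
otsu_two_thresholds <- function(img) {
  assert_gray(img)
  v <- as.integer(clamp(round(img), 0, 255))
  if (length(unique(v)) < 3L)
    stop_hypoxiafeat("image needs at least 3 distinct intensity levels for two thresholds",
                     "hypoxiafeat_degenerate_histogram_error")
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  lev <- 0:255
  P <- cumsum(p)                 # P[k] = mass of levels 0..k-1? careful: P[i] = mass 0..(i-1)
  Spx <- cumsum(p * lev)
  # class over (a, b]: mass and mean via prefix sums at 1-based index = level + 1
  cw <- function(a, b) P[b + 1L] - if (a < 0) 0 else P[a + 1L]
  cs <- function(a, b) Spx[b + 1L] - if (a < 0) 0 else Spx[a + 1L]
  mu_tot <- Spx[256L]
  best <- -Inf; best_pair <- c(NA_real_, NA_real_)
  for (t1 in 0:254) {
    w0 <- cw(-1L, t1); s0 <- cs(-1L, t1)
    t2 <- (t1 + 1L):255L
    w1 <- P[t2 + 1L] - P[t1 + 2L - 1L]
    s1 <- Spx[t2 + 1L] - Spx[t1 + 1L]
    w2 <- 1 - w0 - w1
    s2 <- mu_tot - s0 - s1
    sb <- rep(0, length(t2))
    ok0 <- w0 > 0; ok1 <- w1 > 0; ok2 <- w2 > 0
    if (ok0) sb <- sb + s0^2 / w0
    sb[ok1] <- sb[ok1] + s1[ok1]^2 / w1[ok1]
    sb[ok2] <- sb[ok2] + s2[ok2]^2 / w2[ok2]
    sb <- sb - mu_tot^2
    i <- which.max(sb)           # first max: smallest t2 for this t1
    if (sb[i] > best + 1e-12) { best <- sb[i]; best_pair <- c(t1, t2[i]) }
  }
  c(t1 = best_pair[1], t2 = best_pair[2])
}

#' Segment a grayscale image into tissue classes
#'
#' Labels each pixel hypoxic (`H`) if its intensity is `<= t1`, viable (`V`)
#' if in `(t1, t2]`, and necrotic (`N`) otherwise: the anti-pimonidazole
#' stain is dark where tissue is hypoxic and necrosis appears bright.
#'
#' @param img Grayscale matrix, values in \[0, 255\].
#' @param thresholds Numeric `c(t1, t2)` with `0 <= t1 < t2 <= 255`, e.g.
#'   from [otsu_two_thresholds()] or [fixed_study_thresholds()].
#' @return Integer matrix of class `tissue_labels` with codes
#'   `H = 0, V = 1, N = 2` (attribute `levels` records the mapping).
#' @export
segment_by_thresholds <- function(img, thresholds) {
  assert_gray(img)
  t1 <- thresholds[[1]]; t2 <- thresholds[[2]]
  if (!is.finite(t1) || !is.finite(t2) || t1 < 0 || t2 > 255 || t1 >= t2)
    stop_hypoxiafeat("thresholds must satisfy 0 <= t1 < t2 <= 255",
                     "hypoxiafeat_config_error")
  lab <- matrix(2L, nrow(img), ncol(img))
  lab[img <= t2] <- 1L
  lab[img <= t1] <- 0L
  structure(lab, class = "tissue_labels", levels = c("H", "V", "N"))
}

#' Make a tissue label field from a character matrix
#'
#' @param chars Character matrix over `"H"`, `"V"`, `"N"`.
#' @return A `tissue_labels` integer matrix (`H = 0, V = 1, N = 2`).
#' @export
tissue_labels_from_chars <- function(chars) {
  stopifnot(is.matrix(chars), all(chars %in% c("H", "V", "N")))
  lab <- matrix(match(chars, c("H", "V", "N")) - 1L, nrow(chars), ncol(chars))
  structure(lab, class = "tissue_labels", levels = c("H", "V", "N"))
}

#' Tissue label at coordinates
#'
#' @param field A `tissue_labels` matrix.
#' @param x,y 0-based pixel coordinates (vectors of equal length).
#' @return Character vector over `"H"`, `"V"`, `"N"`.
#' @export
label_at <- function(field, x, y) {
  stopifnot(inherits(field, "tissue_labels"))
  if (any(x < 0 | y < 0 | x > ncol(field) - 1 | y > nrow(field) - 1))
    stop_hypoxiafeat("path leaves the label field", "hypoxiafeat_coordinate_error")
  attr(field, "levels")[field[cbind(y + 1, x + 1)] + 1L]
}

#' Tissue area ratios
#'
#' Computes pixel-count fractions of each tissue class relative to the whole
#' image (`h_to_i`, `v_to_i`, `n_to_i`, summing to 1 exactly) and the
#' hypoxic-to-viable ratio `h_to_v` (the state function used by the hypoxia
#' proposition's ratio term). `h_to_v` is `NA` when no viable pixels exist.
#'
#' @param field A `tissue_labels` matrix from [segment_by_thresholds()].
#' @return List with `h_to_i`, `v_to_i`, `n_to_i`, `h_to_v`, and raw
#'   `counts`.
#' @export
tissue_ratios <- function(field) {
  stopifnot(inherits(field, "tissue_labels"))
  n <- length(field)
  if (n == 0L) stop_hypoxiafeat("label field is empty", "hypoxiafeat_dimension_error")
  counts <- tabulate(as.integer(field) + 1L, nbins = 3L)
  names(counts) <- c("H", "V", "N")
  list(h_to_i = counts[["H"]] / n,
       v_to_i = counts[["V"]] / n,
       n_to_i = counts[["N"]] / n,
       h_to_v = if (counts[["V"]] > 0L) counts[["H"]] / counts[["V"]] else NA_real_,
       counts = counts)
}
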