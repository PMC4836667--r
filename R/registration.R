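#' Displacement vectors between matched landmarks
#'
#' For each landmark pair, the displacement is the anti-pimonidazole
#' position minus the H&E position (`P_i - H_i`), recorded with its origin
#' (the H&E position), length in pixels, and angle in radians relative to
#' horizontal (y measured downward; angle in `(-pi, pi]`).
#'
#' @param pairs Data frame or matrix with columns `h_x`, `h_y`, `p_x`,
#'   `p_y` (0-based pixel coordinates).
#' @return Data frame with `origin_x`, `origin_y`, `dx`, `dy`, `length`,
#'   `angle`.
#' @export
displacements <- function(pairs) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("h_x", "h_y", "p_x", "p_y") %in% names(pairs)), nrow(pairs) >= 1L)
  dx <- pairs$p_x - pairs$h_x
  dy <- pairs$p_y - pairs$h_y
  ang <- atan2(dy, dx)
  ang[dx == 0 & dy == 0] <- 0
  data.frame(origin_x = pairs$h_x, origin_y = pairs$h_y, dx = dx, dy = dy,
             length = sqrt(dx^2 + dy^2), angle = ang)
}

# Unwrap angles to the branch nearest their circular mean, avoiding +-pi
# discontinuities in the polynomial fit.
unwrap_angles <- function(a) {
  mu <- atan2(mean(sin(a)), mean(cos(a)))
  mu + ((a - mu + pi) %% (2 * pi)) - pi
}

#' Fit the two-polynomial displacement vector-field model
#'
#' Models slice-to-slice tissue deformation by assuming the displacement
#' angle varies with the x position and the displacement magnitude with the
#' y position, fitting a second-order polynomial to each. With exactly
#' three landmarks (the study case) both fits interpolate exactly; with
#' more they are ordinary least squares.
#'
#' @param vectors Data frame from [displacements()].
#' @return Object of class `vector_field`: `angle_coeffs` and
#'   `magnitude_coeffs` (each `c(intercept, linear, quadratic)`).
#' @export
fit_vector_field <- function(vectors) {
  if (nrow(vectors) < 3L)
    stop_hypoxiafeat("need at least 3 displacement vectors", "hypoxiafeat_input_error")
  qr_fit <- function(u, y) {
    X <- cbind(1, u, u^2)
    f <- qr(X)
    if (f$rank < 3L)
      stop_hypoxiafeat("duplicate abscissae make the polynomial system rank-deficient",
                       "hypoxiafeat_fit_error")
    qr.coef(f, y)
  }
  a <- qr_fit(vectors$origin_x, unwrap_angles(vectors$angle))
  m <- qr_fit(vectors$origin_y, vectors$length)
  structure(list(angle_coeffs = unname(a), magnitude_coeffs = unname(m)),
            class = "vector_field")
}

#' Evaluate the vector-field model at positions
#'
#' @param model A `vector_field` from [fit_vector_field()].
#' @param x,y Positions (vectors of equal length, 0-based pixels).
#' @return Data frame with `origin_x`, `origin_y`, `dx`, `dy`, `length`,
#'   `angle` (length always taken nonnegative).
#' @export
evaluate_field <- function(model, x, y) {
  stopifnot(inherits(model, "vector_field"), length(x) == length(y))
  ac <- model$angle_coeffs; mc <- model$magnitude_coeffs
  ang <- ac[1] + ac[2] * x + ac[3] * x^2
  len <- pmax(mc[1] + mc[2] * y + mc[3] * y^2, 0)
  data.frame(origin_x = x, origin_y = y,
             dx = len * cos(ang), dy = len * sin(ang),
             length = len, angle = atan2(sin(ang), cos(ang)))
}

#' @export
print.vector_field <- function(x, ...) {
  cat("Displacement vector field\n")
  cat(sprintf(" angle(x)     = %.6g + %.6g x + %.6g x^2  (radians)\n",
              x$angle_coeffs[1], x$angle_coeffs[2], x$angle_coeffs[3]))
  cat(sprintf(" magnitude(y) = %.6g + %.6g y + %.6g y^2  (pixels)\n",
              x$magnitude_coeffs[1], x$magnitude_coeffs[2], x$magnitude_coeffs[3]))
  invisible(x)
}
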