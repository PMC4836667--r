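#' Ray-sampling configuration
#'
#' Parameters of the radial intensity sampler: `n` equal-angle rays grouped
#' into `m` equal-angle bundles (sectors), samples every `d_s` pixels along
#' each ray, each sample averaged over a square neighborhood of radius `r_n`
#' (0 by default since images are smoothed upstream), and a threshold length
#' `l_t` (default 1000 px) bounding the search window for the measurement
#' radius.
#'
#' @param n Number of rays (>= 1).
#' @param m Number of bundles (1 <= m <= n).
#' @param d_s Inter-sample distance in pixels (>= 1).
#' @param r_n Square neighborhood radius in pixels (>= 0).
#' @param l_t Threshold length in pixels (>= 1).
#' @return List of class `ray_config`.
#' @export
ray_config <- function(n = 80L, m = 1L, d_s = 1, r_n = 0L, l_t = 1000L) {
  if (!is_count(n, 1L)) stop_hypoxiafeat("n must be >= 1", "hypoxiafeat_config_error")
  if (!is_count(m, 1L) || m > n)
    stop_hypoxiafeat("m must satisfy 1 <= m <= n", "hypoxiafeat_config_error")
  if (!is.numeric(d_s) || d_s < 1) stop_hypoxiafeat("d_s must be >= 1", "hypoxiafeat_config_error")
  if (!is_count(r_n, 0L)) stop_hypoxiafeat("r_n must be >= 0", "hypoxiafeat_config_error")
  if (!is_count(l_t, 1L)) stop_hypoxiafeat("l_t must be >= 1", "hypoxiafeat_config_error")
  structure(list(n = as.integer(n), m = as.integer(m), d_s = d_s,
                 r_n = as.integer(r_n), l_t = as.integer(l_t)),
            class = "ray_config")
}

#' Radial intensity sampling along ray bundles
#'
#' Samples image intensity along `n` rays from `center` outward. Ray `j`
#' (0-based) points at angle `j * 2*pi/n` (x rightward, y downward); sample
#' `k` sits at distance `k * d_s` from the center, read by nearest-pixel
#' rounding and, for `r_n > 0`, averaged over the `(2*r_n+1)^2` pixel window
#' clipped at the image border. Samples beyond the image edge are `Inf`
#' sentinels, so every row is a prefix of valid samples followed by
#' sentinels. The matrix has `ceiling(hypot(width, height) / d_s)` columns:
#' a corner-placed center can require the full image diagonal.
#'
#' @param img Grayscale matrix (smoothed upstream).
#' @param center `c(x, y)` 0-based pixel coordinates of the vessel centroid.
#' @param cfg A [ray_config()].
#' @return Object of class `ray_matrix`: the `n x c` sample matrix with
#'   attributes `angles` and `cfg`. Radial index `i` corresponds to pixel
#'   distance `i * d_s` from the center (the center pixel is not a sample).
#' @export
sample_rays <- function(img, center, cfg = ray_config()) {
  assert_gray(img)
  rc <- center_to_rc(center, img)
  h <- nrow(img); w <- ncol(img)
  cmax <- as.integer(ceiling(sqrt(h^2 + w^2) / cfg$d_s))
  ang <- (seq_len(cfg$n) - 1L) * 2 * pi / cfg$n
  base <- if (cfg$r_n > 0L) box_mean(img, cfg$r_n) else img
  M <- matrix(Inf, cfg$n, cmax)
  k <- seq_len(cmax) * cfg$d_s
  for (j in seq_len(cfg$n)) {
    px <- round(rc[["col"]] + k * cos(ang[j]))
    py <- round(rc[["row"]] + k * sin(ang[j]))
    ok <- px >= 1 & px <= w & py >= 1 & py <= h
    # a ray stops at its first out-of-image sample
    if (!all(ok)) ok[seq_along(ok) >= which.min(ok)] <- FALSE
    M[j, ok] <- base[cbind(py[ok], px[ok])]
  }
  structure(M, class = "ray_matrix", angles = ang, cfg = cfg)
}

# Border-clipped square-window mean (window radius r pixels), via an
# integral image.
box_mean <- function(img, r) {
  h <- nrow(img); w <- ncol(img)
  P <- matrix(0, h + 1L, w + 1L)
  P[2:(h + 1L), 2:(w + 1L)] <- t(apply(apply(img, 2, cumsum), 1, cumsum))
  r1 <- pmax(seq_len(h) - r, 1L); r2 <- pmin(seq_len(h) + r, h)
  c1 <- pmax(seq_len(w) - r, 1L); c2 <- pmin(seq_len(w) + r, w)
  S <- P[r2 + 1L, c2 + 1L, drop = FALSE] - P[r1, c2 + 1L, drop = FALSE] -
       P[r2 + 1L, c1, drop = FALSE] + P[r1, c1, drop = FALSE]
  S / ((r2 - r1 + 1) %o% (c2 - c1 + 1))
}

#' Per-bundle radial statistics
#'
#' Groups rays into `m` half-open angular sectors (`[b*2*pi/m, (b+1)*2*pi/m)`,
#' boundary rays belong to the lower-index bundle) and computes, at each
#' radial index, the mean, median and standard deviation over the bundle's
#' rays, dropping sentinel (out-of-image) entries. A radial index is defined
#' wherever at least one ray is still inside the image.
#'
#' @param M A `ray_matrix` from [sample_rays()].
#' @param cfg The [ray_config()] used (defaults to the one stored on `M`).
#' @return List of `m` bundle profiles, each with `mean_vec`, `median_vec`,
#'   `std_vec` (NA past the bundle's last valid index), `n_valid`, `r_m`
#'   (filled by [measurement_radius()] downstream), and `sector` angles.
#' @export
bundle_profiles <- function(M, cfg = attr(M, "cfg")) {
  stopifnot(inherits(M, "ray_matrix"))
  ang <- attr(M, "angles")
  if (cfg$m > cfg$n)
    stop_hypoxiafeat("more bundles than rays leaves empty bundles", "hypoxiafeat_config_error")
  lapply(seq_len(cfg$m) - 1L, function(b) {
    lo <- b * 2 * pi / cfg$m; hi <- (b + 1) * 2 * pi / cfg$m
    rows <- which(ang >= lo & ang < hi)
    sub <- M[rows, , drop = FALSE]
    valid <- is.finite(sub)
    nv <- colSums(valid)
    sub[!valid] <- NA
    mean_vec <- suppressWarnings(colMeans(sub, na.rm = TRUE))
    median_vec <- apply(sub, 2, stats::median, na.rm = TRUE)
    std_vec <- apply(sub, 2, stats::sd, na.rm = TRUE)
    std_vec[nv == 1L] <- 0
    mean_vec[nv == 0L] <- NA; median_vec[nv == 0L] <- NA; std_vec[nv == 0L] <- NA
    list(mean_vec = mean_vec, median_vec = median_vec, std_vec = std_vec,
         n_valid = nv, rays = rows, sector = c(lo, hi), d_s = cfg$d_s)
  })
}

#' Measurement radius of a bundle
#'
#' Locates the darkest point of the bundle's median radial profile within
#' the first `l_t` radial indices: the radial distance at which stain
#' density peaks, taken as the outer contour of the hypoxic band. The
#' smallest index wins ties.
#'
#' @param profile A bundle profile from [bundle_profiles()].
#' @param l_t Threshold length in pixels (default 1000).
#' @return Radial index (pixels when `d_s = 1`) of the minimum median
#'   intensity.
#' @export
measurement_radius <- function(profile, l_t = 1000L) {
  med <- profile$median_vec
  win <- seq_len(min(length(med), max(1L, floor(l_t / profile$d_s))))
  med <- med[win]
  if (all(is.na(med)))
    stop_hypoxiafeat("no valid median entries within the threshold length",
                     "hypoxiafeat_empty_window_error")
  which.min(med)   # NA ignored; first minimum wins
}

#' Drop spurious leading segments from a fit
#'
#' Landmarks placed inside a bright vessel lumen (or a dark pixel blob)
#' produce short or positive-slope leading segments that do not belong to
#' the stain gradient. This repeatedly removes the leading segment while it
#' has positive slope or length below `min_len`, never removing the final
#' segment, and records what was dropped.
#'
#' @param fit A `segmented_fit`.
#' @param min_len Minimum credible leading-segment length in pixels
#'   (default 40, roughly the blur support of the default smoothing).
#' @return The filtered `segmented_fit`, with a `dropped` data frame of
#'   removed segments.
#' @export
filter_spurious <- function(fit, min_len = 40) {
  stopifnot(inherits(fit, "segmented_fit"))
  sg <- fit$segments
  dropped <- sg[0, ]
  while (nrow(sg) > 1L && (sg$s[1] > 0 || sg$l[1] < min_len)) {
    dropped <- rbind(dropped, sg[1, ])
    sg <- sg[-1, , drop = FALSE]
  }
  out <- fit
  out$segments <- sg
  out$total_cost <- sum(sg$e) + fit$C * nrow(sg)
  out$dropped <- dropped
  out
}

#' Full gradient analysis around a vessel landmark
#'
#' Runs the radial sampler, computes per-bundle statistics and measurement
#' radius, fits segmented least squares (cost `C`) to both the mean and
#' median profiles restricted to radial indices `1..r_m`, and selects the
#' fit with fewer segments (ties select the mean fit). Optionally applies
#' [filter_spurious()] to the selected fit.
#'
#' @param img Grayscale matrix; smooth it first (see [smooth()]) unless
#'   `presmoothed` data are supplied.
#' @param center `c(x, y)` 0-based landmark coordinates.
#' @param cfg A [ray_config()].
#' @param C Segment cost penalty (default 200).
#' @param filter Apply the spurious-leading-segment filter (default TRUE).
#' @param min_len Passed to [filter_spurious()].
#' @return Object of class `gradient_report`: per-bundle list with `r_m`,
#'   `mean_fit`, `median_fit`, `selected` (`"mean"` or `"median"`), `fit`
#'   (the selected, possibly filtered fit), plus the `center` and `cfg`.
#' @export
gradient_report <- function(img, center, cfg = ray_config(), C = 200,
                            filter = TRUE, min_len = 40) {
  M <- sample_rays(img, center, cfg)
  profs <- bundle_profiles(M, cfg)
  bundles <- lapply(profs, function(p) {
    r_m <- measurement_radius(p, cfg$l_t)
    idx <- seq_len(r_m)
    keep <- idx[!is.na(p$mean_vec[idx]) & !is.na(p$median_vec[idx])]
    xs <- keep * p$d_s
    mean_fit <- segmented_least_squares(xs, p$mean_vec[keep], C)
    median_fit <- segmented_least_squares(xs, p$median_vec[keep], C)
    selected <- if (nrow(median_fit$segments) < nrow(mean_fit$segments)) "median" else "mean"
    fit <- if (selected == "median") median_fit else mean_fit
    if (filter) fit <- filter_spurious(fit, min_len)
    list(r_m = r_m * p$d_s, mean_fit = mean_fit, median_fit = median_fit,
         selected = selected, fit = fit, sector = p$sector)
  })
  structure(list(bundles = bundles, center = center, cfg = cfg, C = C),
            class = "gradient_report")
}

#' @export
print.gradient_report <- function(x, ...) {
  cat(sprintf("Gradient report: %d bundle(s), center (%g, %g), C = %g\n",
              length(x$bundles), x$center[[1]], x$center[[2]], x$C))
  for (i in seq_along(x$bundles)) {
    b <- x$bundles[[i]]
    cat(sprintf(" bundle %d: r_m = %g px, selected %s fit, %d segment(s)\n",
                i, b$r_m, b$selected, nrow(b$fit$segments)))
    print(b$fit$segments[c("start_x", "end_x", "l", "s", "e")], row.names = FALSE)
  }
  invisible(x)
}

#' Read vessel landmarks from CSV
#'
#' One `x,y` pair per line (0-based pixel coordinates), optionally with a
#' header naming the columns `x` and `y`.
#'
#' @param path CSV path.
#' @return Two-column numeric matrix with columns `x`, `y`.
#' @export
read_landmarks <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("[A-Za-z]", first)
  df <- utils::read.csv(path, header = header)
  if (!header) names(df)[1:2] <- c("x", "y")
  as.matrix(df[, c("x", "y")])
}
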