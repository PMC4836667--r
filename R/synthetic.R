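# Seeded synthetic anti-pimonidazole-like lesion generator.
#
# A lesion is a viable core containing a vessel, a dark hypoxic band, and
# bright necrotic surroundings, with a piecewise-linear radial intensity
# decline away from the vessel (two segments with negative slopes, the
# measured low-concentration structure) and additive Gaussian noise. The
# generator is the package's download-free test substrate: every rendered
# scene carries its analytic ground truth.

#' Specify a synthetic lesion
#'
#' Default geometry and slopes are the measured two-segment
#' low-concentration gradient means: slopes (-0.21, -0.06) over segment
#' lengths (172, 267) px, starting from a base intensity of 200 and
#' surrounded by bright necrosis at 230. The default viable/hypoxic
#' boundary (376 px) makes the hypoxic band a narrow ring whose area is
#' 0.36 of the viable core, the measured hypoxic:viable pixel ratio; the
#' stain gradient spans both rings.
#'
#' @param center `c(x, y)` 0-based lesion center (the vessel centroid).
#' @param vessel_radius Vessel radius in px.
#' @param viable_outer Outer radius of the viable core in px.
#' @param hypoxic_outer Outer radius of the hypoxic band in px (defaults to
#'   the total gradient length `l1 + l2`).
#' @param slopes `c(s1, s2)` intensity change per px, both <= 0.
#' @param seg_lengths `c(l1, l2)` segment lengths in px.
#' @param base_intensity Intensity at the center.
#' @param necrotic_level Intensity beyond the gradient.
#' @param noise_sigma Additive Gaussian noise standard deviation.
#' @return List of class `lesion_spec`.
#' @export
lesion_spec <- function(center = c(475, 475), vessel_radius = 15,
                        viable_outer = 376, hypoxic_outer = NULL,
                        slopes = c(-0.21, -0.06), seg_lengths = c(172, 267),
                        base_intensity = 200, necrotic_level = 230,
                        noise_sigma = 5) {
  if (is.null(hypoxic_outer)) hypoxic_outer <- sum(seg_lengths)
  if (!(vessel_radius < viable_outer && viable_outer < hypoxic_outer))
    stop_hypoxiafeat("need vessel_radius < viable_outer < hypoxic_outer",
                     "hypoxiafeat_config_error")
  if (any(slopes > 0))
    stop_hypoxiafeat("radial slopes must be <= 0 (stain darkens outward)",
                     "hypoxiafeat_config_error")
  if (base_intensity < 0 || base_intensity > 255 || necrotic_level < 0 ||
      necrotic_level > 255)
    stop_hypoxiafeat("intensity levels must lie in [0, 255]", "hypoxiafeat_config_error")
  structure(list(center = center, vessel_radius = vessel_radius,
                 viable_outer = viable_outer, hypoxic_outer = hypoxic_outer,
                 slopes = slopes, seg_lengths = seg_lengths,
                 base_intensity = base_intensity,
                 necrotic_level = necrotic_level, noise_sigma = noise_sigma),
            class = "lesion_spec")
}

#' Specify a synthetic scene
#'
#' @param width,height Image size in px.
#' @param lesions List of [lesion_spec()] objects (all inside bounds).
#' @param background_level Intensity outside every lesion.
#' @param seed RNG seed; a fixed seed makes [render_scene()] byte-identical
#'   across runs.
#' @return List of class `scene_spec`.
#' @export
scene_spec <- function(width = 950L, height = 950L,
                       lesions = list(lesion_spec()),
                       background_level = 230, seed = 1L) {
  for (l in lesions) {
    if (l$center[[1]] < 0 || l$center[[1]] > width - 1 ||
        l$center[[2]] < 0 || l$center[[2]] > height - 1)
      stop_hypoxiafeat("lesion center outside scene bounds", "hypoxiafeat_config_error")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 lesions = lesions, background_level = background_level,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Analytic radial intensity profile of a lesion
#'
#' The noiseless piecewise-linear profile: `base_intensity + s1 * r` out to
#' `l1`, continuing at slope `s2` out to `l1 + l2`, then the necrotic level
#' beyond.
#'
#' @param spec A [lesion_spec()].
#' @param r_max Maximum radius to tabulate (default `l1 + l2 + 60`).
#' @return List with `x` (radii 0..r_max) and `y` (intensity), usable as a
#'   series for [segmented_least_squares()].
#' @export
make_profile <- function(spec, r_max = NULL) {
  l1 <- spec$seg_lengths[1]; l2 <- spec$seg_lengths[2]
  if (is.null(r_max)) r_max <- ceiling(l1 + l2 + 60)
  x <- 0:r_max
  y <- profile_at(spec, x)
  list(x = x, y = y)
}

profile_at <- function(spec, r) {
  l1 <- spec$seg_lengths[1]; l2 <- spec$seg_lengths[2]
  s1 <- spec$slopes[1]; s2 <- spec$slopes[2]
  v1 <- spec$base_intensity + s1 * pmin(r, l1)
  y <- v1 + s2 * clamp(r - l1, 0, l2)
  y[r > l1 + l2] <- spec$necrotic_level
  clamp(y, 0, 255)
}

#' Render a synthetic scene with ground truth
#'
#' Rasterizes each lesion's radial profile around its center, adds seeded
#' Gaussian noise (clipped to \[0, 255\] and rounded to the 8-bit grid),
#' and labels every pixel V/H/N by ring membership: viable out to
#' `viable_outer`, hypoxic out to `hypoxic_outer`, necrotic beyond. Where
#' lesions overlap, the nearest center wins (with a warning).
#'
#' @param spec A [scene_spec()].
#' @return List with `image` (grayscale matrix), `labels`
#'   (`tissue_labels`), `ratios` (analytic ground-truth area fractions),
#'   and the `spec`.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width
  xs <- matrix(rep(0:(w - 1L), each = h), h)
  ys <- matrix(rep(0:(h - 1L), w), h)
  img <- matrix(spec$background_level, h, w)
  lab <- matrix(2L, h, w)   # N
  rmin <- matrix(Inf, h, w)
  overlap <- FALSE
  for (l in spec$lesions) {
    r <- sqrt((xs - l$center[[1]])^2 + (ys - l$center[[2]])^2)
    inside <- r <= l$hypoxic_outer
    claimed <- inside & is.finite(rmin) & rmin <= l$hypoxic_outer
    if (any(claimed & rmin < r)) overlap <- TRUE
    take <- inside & r < rmin
    img[take] <- profile_at(l, r[take])
    lab[take & r <= l$hypoxic_outer] <- 1L
    lab[take & r <= l$viable_outer] <- 0L
    rmin[take] <- r[take]
  }
  if (overlap) warning("overlapping lesions: nearest center wins")
  sig <- max(vapply(spec$lesions, function(l) l$noise_sigma, numeric(1)))
  if (sig > 0) img <- img + matrix(stats::rnorm(h * w, 0, sig), h, w)
  img <- clamp(round(img), 0, 255)
  lab_chr <- matrix(c("V", "H", "N")[lab + 1L], h, w)
  truth <- ground_truth_ratios(spec)
  list(image = img, labels = tissue_labels_from_chars(lab_chr),
       ratios = truth, spec = spec)
}

# Analytic ring-area fractions (clipped disks approximated by full disks;
# callers keep lesions inside bounds).
ground_truth_ratios <- function(spec) {
  area <- spec$width * spec$height
  v <- sum(vapply(spec$lesions, function(l) pi * l$viable_outer^2, numeric(1)))
  hyp <- sum(vapply(spec$lesions, function(l)
    pi * (l$hypoxic_outer^2 - l$viable_outer^2), numeric(1)))
  list(v_to_i = v / area, h_to_i = hyp / area,
       n_to_i = 1 - (v + hyp) / area,
       h_to_v = if (v > 0) hyp / v else NA_real_)
}

#' Pseudo-H&E companion rendering
#'
#' A crude hematoxylin-and-eosin-like rendering of the same scene for
#' registration exercises: bright vessel lumina on mid-gray tissue with
#' lightly textured rings. Structural only; no staining realism intended.
#'
#' @param spec A [scene_spec()].
#' @return Grayscale matrix.
#' @export
render_pseudo_he <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed + 1L)
  h <- spec$height; w <- spec$width
  xs <- matrix(rep(0:(w - 1L), each = h), h)
  ys <- matrix(rep(0:(h - 1L), w), h)
  img <- matrix(150, h, w)
  for (l in spec$lesions) {
    r <- sqrt((xs - l$center[[1]])^2 + (ys - l$center[[2]])^2)
    img[r <= l$hypoxic_outer] <- 120
    img[r <= l$viable_outer] <- 140
    img[r <= l$vessel_radius] <- 245   # open lumen
  }
  clamp(round(img + matrix(stats::rnorm(h * w, 0, 6), h, w)), 0, 255)
}

#' Generate a calibration feature set
#'
#' Renders `count` seeded scenes whose lesion parameters are drawn
#' uniformly from `ranges`, extracts [features_from_image()] on each, and
#' returns the feature matrix together with the generating scene specs.
#'
#' @param count Number of calibrating lesions (must be at least the number
#'   of features, 12).
#' @param seed Base RNG seed.
#' @param ranges List of `c(min, max)` ranges for `s1`, `s2`, `l1`, `l2`,
#'   `base`, `necrotic`, `noise`.
#' @param size Scene edge length in px (default 640; lesions are scaled to
#'   fit).
#' @param cfg,C,smooth_cfg,min_len Passed to the gradient extractor.
#' @return List with `features` (count x 12 matrix) and `specs`.
#' @export
make_calibration_set <- function(count, seed = 1L,
                                 ranges = list(s1 = c(-0.30, -0.12),
                                               s2 = c(-0.09, -0.03),
                                               l1 = c(90, 130),
                                               l2 = c(110, 170),
                                               base = c(190, 215),
                                               necrotic = c(220, 245),
                                               noise = c(3, 7)),
                                 size = 640L, cfg = ray_config(), C = 200,
                                 smooth_cfg = smoothing_config(), min_len = 40) {
  n_features <- 12L
  if (count < n_features)
    stop_hypoxiafeat(sprintf("need at least %d calibrating lesions (m >= n)", n_features),
                     "hypoxiafeat_precondition_error")
  set.seed(seed)
  draws <- lapply(seq_len(count), function(i) {
    u <- function(rg) stats::runif(1, rg[1], rg[2])
    l1 <- round(u(ranges$l1)); l2 <- round(u(ranges$l2))
    s1 <- u(ranges$s1)
    # every fourth lesion declines at a single slope: the calibration
    # population mixes one- and two-segment gradients so the segment-count
    # and length-fraction features vary (keeps the feature matrix
    # identifiable rather than structurally collinear)
    s2 <- if (i %% 4L == 0L) s1 else u(ranges$s2)
    lesion_spec(center = c(size %/% 2L, size %/% 2L),
                vessel_radius = 8, viable_outer = l1,
                slopes = c(s1, s2),
                seg_lengths = c(l1, l2),
                base_intensity = u(ranges$base),
                necrotic_level = u(ranges$necrotic),
                noise_sigma = u(ranges$noise))
  })
  seeds <- sample.int(.Machine$integer.max, count)
  specs <- Map(function(l, s) scene_spec(size, size, list(l),
                                         background_level = l$necrotic_level,
                                         seed = s),
               draws, seeds)
  feats <- t(vapply(specs, function(sp) {
    sc <- render_scene(sp)
    features_from_image(sc$image, matrix(unlist(sp$lesions[[1]]$center), 1),
                        cfg = cfg, C = C, smooth_cfg = smooth_cfg,
                        min_len = min_len)
  }, numeric(n_features)))
  list(features = feats, specs = specs)
}

#' Read a scene specification from YAML
#'
#' Top-level keys `width`, `height`, `background_level`, `seed`, and a list
#' `lesions` whose entries hold [lesion_spec()] fields.
#'
#' @param path YAML file path.
#' @return A [scene_spec()].
#' @export
read_scene_spec <- function(path) {
  y <- yaml::read_yaml(path)
  lesions <- lapply(y$lesions, function(l) do.call(lesion_spec, l))
  scene_spec(width = y$width, height = y$height, lesions = lesions,
             background_level = if (is.null(y$background_level)) 230 else y$background_level,
             seed = if (is.null(y$seed)) 1L else y$seed)
}
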