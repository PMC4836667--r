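# Linear-regression hypoxia similarity estimator.
#
# Calibrating lesions are given similarity score 1; solving the
# overdetermined system F a = 1 by least squares yields feature
# coefficients a whose inner product with a new lesion's features scores
# its resemblance to chronic hypoxia. Robust (Beaton-Tukey bisquare)
# reweighting guards the fit against false-positive calibration lesions,
# and James-Stein shrinkage pulls noisy or dependent coefficients toward
# zero.

check_feature_matrix <- function(F) {
  F <- as.matrix(F)
  if (anyNA(F)) stop_hypoxiafeat("feature matrix has missing values", "hypoxiafeat_input_error")
  if (nrow(F) < ncol(F))
    stop_hypoxiafeat("need m >= n observations (rows) for n features (columns)",
                     "hypoxiafeat_input_error")
  F
}

#' Ordinary least-squares training
#'
#' Solves the normal equations `a = (F'F)^{-1} F' 1` for the all-ones
#' target of the calibrating lesions.
#'
#' @param F m x n feature matrix (observations in rows).
#' @return List with `coefficients`, `fitted` (training scores), `weights`
#'   (all 1), `m_prime`, `sigma2` (residual variance estimate).
#' @export
train_ols <- function(F) {
  F <- check_feature_matrix(F)
  fit <- stats::lm.fit(F, rep(1, nrow(F)))
  if (fit$rank < ncol(F))
    stop_hypoxiafeat("feature matrix is rank-deficient", "hypoxiafeat_singular_error")
  a <- fit$coefficients
  res <- fit$residuals
  df <- nrow(F) - ncol(F)
  list(coefficients = a, fitted = drop(F %*% a), weights = rep(1, nrow(F)),
       m_prime = nrow(F), sigma2 = if (df > 0) sum(res^2) / df else 0,
       iterations = 0L, converged = TRUE)
}

bisquare_weight <- function(r, scale, c = 4.685) {
  u <- abs(r) / (c * scale)
  w <- (1 - u^2)^2
  w[u >= 1] <- 0
  w
}

#' Beaton-Tukey robust training
#'
#' Iteratively reweighted least squares with the bisquare weight function
#' `w(r) = (1 - (r / (c s))^2)^2` for `|r| < c s` (0 beyond) and tuning
#' constant `c = 4.685`. Residuals are leverage-adjusted
#' (`r / sqrt(1 - h)`, with `h` the hat values of the design) before
#' weighting, the standard guard against high-leverage contamination
#' masking itself, and the robust scale `s = median(|r|) / 0.6745` is
#' recomputed from the adjusted residuals each iteration. Observations
#' whose final weight is zero are discarded; `m_prime` reports how many
#' calibrating lesions remain. Convergence: maximum weight change below
#' `tol` or `max_iter` sweeps.
#'
#' @param F m x n feature matrix.
#' @param c Bisquare tuning constant (default 4.685).
#' @param max_iter Maximum IRLS sweeps (default 50).
#' @param tol Weight-change convergence tolerance (default 1e-6).
#' @return As [train_ols()], plus the per-observation `weights` in \[0, 1\],
#'   `m_prime`, `iterations`, `converged`.
#' @export
train_robust <- function(F, c = 4.685, max_iter = 50L, tol = 1e-6) {
  F <- check_feature_matrix(F)
  y <- rep(1, nrow(F))
  a <- train_ols(F)$coefficients
  hat <- rowSums(qr.Q(qr(F))^2)
  adj <- 1 / sqrt(pmax(1 - hat, .Machine$double.eps))
  w <- rep(1, nrow(F))
  converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    r <- (y - drop(F %*% a)) * adj
    s <- stats::median(abs(r)) / 0.6745
    if (s < .Machine$double.eps) { converged <- TRUE; break }  # essentially exact fit
    w_new <- bisquare_weight(r, s, c)
    if (all(w_new == 0))
      stop_hypoxiafeat("all observations received zero weight", "hypoxiafeat_degenerate_fit_error")
    sw <- sqrt(w_new)
    fit <- stats::lm.fit(F * sw, y * sw)
    if (fit$rank < ncol(F))
      stop_hypoxiafeat("weighted feature matrix is rank-deficient", "hypoxiafeat_singular_error")
    a <- fit$coefficients
    if (max(abs(w_new - w)) < tol) { w <- w_new; converged <- TRUE; break }
    w <- w_new
  }
  r <- y - drop(F %*% a)
  keep <- w > 0
  dfree <- sum(keep) - ncol(F)
  list(coefficients = a, fitted = drop(F %*% a), weights = w,
       m_prime = sum(keep), sigma2 = if (dfree > 0) sum(w * r^2) / dfree else 0,
       iterations = it, converged = converged)
}

#' James-Stein shrinkage of feature coefficients
#'
#' Pulls estimated coefficients toward the origin so that noisy or
#' dependent features contribute less. `"spherical"` is the positive-part
#' James-Stein estimator `a' = max(0, 1 - (k - 2) v / ||a||^2) a`,
#' requiring `k >= 3` coefficients. A single extreme coefficient inflates
#' `||a||^2` and stalls spherical shrinkage for every coordinate; the
#' `"coordinate"` (truncated) variant instead shrinks each coordinate by
#' its own positive-part factor `max(0, 1 - v / a_i^2)`, so an extreme
#' coefficient is nearly untouched while coefficients within the noise
#' level are truncated to zero. Shrinkage never increases the norm, and
#' `v = 0` leaves coefficients untouched.
#'
#' @param a Numeric coefficient vector.
#' @param method `"spherical"` or `"coordinate"`.
#' @param noise_var Noise variance `v` of the coefficient estimates
#'   (>= 0); e.g. the residual variance from training.
#' @return List of class `shrunken_coefficients` with `coefficients`,
#'   `method`, `factor` (scalar or per-coordinate), `noise_var`.
#' @export
shrink_coefficients <- function(a, method = c("spherical", "coordinate"),
                                noise_var) {
  method <- match.arg(method)
  a <- as.numeric(a)
  k <- length(a)
  if (!is.numeric(noise_var) || noise_var < 0)
    stop_hypoxiafeat("noise_var must be >= 0", "hypoxiafeat_config_error")
  if (method == "spherical") {
    if (k < 3L)
      stop_hypoxiafeat("spherical James-Stein shrinkage requires k >= 3 coefficients",
                       "hypoxiafeat_precondition_error")
    f <- max(0, 1 - (k - 2) * noise_var / sum(a^2))
    out <- f * a
  } else {
    f <- ifelse(a == 0, 0, pmax(0, 1 - noise_var / a^2))
    out <- f * a
  }
  structure(list(coefficients = out, method = method, factor = f,
                 noise_var = noise_var),
            class = "shrunken_coefficients")
}

#' Score a lesion's similarity to chronic hypoxia
#'
#' `S = a'_1 f_1 + ... + a'_n f_n`, clipped to \[0, 1\] (a linear form is
#' unbounded but the similarity score is by construction a unit-interval
#' quantity; calibrating lesions score 1).
#'
#' @param features Numeric feature vector (or m x n matrix of lesions).
#' @param a Coefficient vector, `shrunken_coefficients`, or a fitted
#'   [fit_similarity()] model.
#' @return Data frame with `raw` and clipped `score` per lesion.
#' @export
score_similarity <- function(features, a) {
  if (inherits(a, "hypoxia_similarity")) a <- a$coefficients_shrunk
  if (inherits(a, "shrunken_coefficients")) a <- a$coefficients
  X <- if (is.matrix(features)) features else matrix(features, nrow = 1L)
  if (ncol(X) != length(a))
    stop_hypoxiafeat("feature vector length does not match coefficients",
                     "hypoxiafeat_input_error")
  raw <- drop(X %*% a)
  data.frame(raw = raw, score = clamp(raw, 0, 1))
}

#' Fit the hypoxia similarity estimator
#'
#' The umbrella fitting function: ordinary or robust least squares on the
#' calibrating feature matrix (target score 1 per lesion), optionally
#' followed by James-Stein shrinkage with the noise variance estimated
#' from the training residual variance.
#'
#' @param F m x n feature matrix, observations in rows; column names are
#'   kept as feature names.
#' @param method `"robust"` (default) or `"ols"`.
#' @param shrink `"spherical"`, `"coordinate"`, or `"none"`.
#' @param noise_var Optional override of the shrinkage noise variance.
#' @param standardize Standardize columns (mean 0 within-column scale 1,
#'   intercept-free) before fitting; default off.
#' @param ... Passed to [train_robust()].
#' @return Object of class `hypoxia_similarity` with coefficients, robust
#'   weights, shrinkage info, and training scores.
#' @export
fit_similarity <- function(F, method = c("robust", "ols"),
                           shrink = c("spherical", "coordinate", "none"),
                           noise_var = NULL, standardize = FALSE, ...) {
  method <- match.arg(method)
  shrink <- match.arg(shrink)
  F <- check_feature_matrix(F)
  fnames <- colnames(F)
  scale_ <- rep(1, ncol(F))
  if (standardize) {
    scale_ <- apply(F, 2, stats::sd)
    scale_[scale_ == 0] <- 1
    F <- sweep(F, 2, scale_, "/")
  }
  tr <- if (method == "robust") train_robust(F, ...) else train_ols(F)
  nv <- if (!is.null(noise_var)) noise_var else tr$sigma2
  sh <- if (shrink == "none") NULL else shrink_coefficients(tr$coefficients, shrink, nv)
  a_final <- if (is.null(sh)) tr$coefficients else sh$coefficients
  structure(list(
    coefficients = stats::setNames(tr$coefficients / scale_, fnames),
    coefficients_shrunk = stats::setNames(a_final / scale_, fnames),
    shrinkage = sh, method = method, shrink = shrink,
    weights = tr$weights, m = nrow(F), m_prime = tr$m_prime,
    noise_var = nv, iterations = tr$iterations, converged = tr$converged,
    fitted = tr$fitted, standardize = standardize),
    class = "hypoxia_similarity")
}

#' @export
print.hypoxia_similarity <- function(x, ...) {
  cat(sprintf("Hypoxia similarity estimator (%s fit, %s shrinkage)\n",
              x$method, x$shrink))
  cat(sprintf(" calibrating lesions: %d (retained %d)\n", x$m, x$m_prime))
  cat(" shrunken coefficients:\n")
  print(round(x$coefficients_shrunk, 6))
  invisible(x)
}

#' @export
summary.hypoxia_similarity <- function(object, ...) {
  cat(sprintf("Hypoxia similarity estimator\n method: %s | shrinkage: %s\n",
              object$method, object$shrink))
  cat(sprintf(" observations: m = %d, retained m' = %d\n", object$m, object$m_prime))
  if (object$method == "robust")
    cat(sprintf(" IRLS iterations: %d (converged: %s); weights in [%.3f, %.3f]\n",
                object$iterations, object$converged,
                min(object$weights), max(object$weights)))
  cat(sprintf(" noise variance for shrinkage: %.6g\n", object$noise_var))
  tab <- data.frame(raw = object$coefficients, shrunk = object$coefficients_shrunk)
  print(tab)
  cat(sprintf(" training scores: mean %.4f, range [%.4f, %.4f]\n",
              mean(object$fitted), min(object$fitted), max(object$fitted)))
  invisible(object)
}

#' @export
coef.hypoxia_similarity <- function(object, shrunk = TRUE, ...) {
  if (shrunk) object$coefficients_shrunk else object$coefficients
}

#' @export
predict.hypoxia_similarity <- function(object, newdata, ...) {
  score_similarity(as.matrix(newdata), object)
}

#' @export
residuals.hypoxia_similarity <- function(object, ...) 1 - object$fitted

#' Assemble the image feature vector
#'
#' The deterministic feature vector feeding the similarity estimator, in
#' fixed order: the two Otsu thresholds `t1`, `t2`; the tissue area
#' fractions `h_to_i`, `v_to_i`, `n_to_i` and the ratio `h_to_v`; then
#' gradient features averaged over landmarks and bundles — selected-fit
#' segment count, the first two segments' lengths as fractions of the
#' measurement radius, their slopes, and the measurement radius `r_m`.
#' Quad-tree histograms and EPC curves are deliberately not part of the
#' default feature set (their cross-image variance makes them unusable as
#' features). Fits with a single segment impute the missing second slot
#' with length fraction 0 and slope 0; `h_to_v` with no viable pixels
#' imputes 0.
#'
#' @param gray Grayscale matrix (unsmoothed; smoothing for the gradient
#'   sampler happens internally).
#' @param landmarks Matrix of 0-based `x`, `y` vessel centroids (one row
#'   each).
#' @param cfg A [ray_config()].
#' @param C Segment cost (default 200).
#' @param smooth_cfg A [smoothing_config()] for the gradient sampler.
#' @param min_len Spurious-segment length floor, passed to
#'   [filter_spurious()].
#' @return Named numeric vector of 12 features.
#' @export
features_from_image <- function(gray, landmarks, cfg = ray_config(), C = 200,
                                smooth_cfg = smoothing_config(), min_len = 40) {
  assert_gray(gray)
  th <- otsu_two_thresholds(gray)
  ratios <- tissue_ratios(segment_by_thresholds(gray, th))
  sm <- smooth(gray, smooth_cfg)
  landmarks <- as.matrix(landmarks)
  per <- lapply(seq_len(nrow(landmarks)), function(i) {
    rep_ <- gradient_report(sm, c(landmarks[i, 1], landmarks[i, 2]), cfg, C,
                            min_len = min_len)
    do.call(rbind, lapply(rep_$bundles, function(b) {
      sg <- b$fit$segments
      lf <- sg$l / b$r_m
      c(n_seg = nrow(sg),
        len_frac1 = lf[1], len_frac2 = if (nrow(sg) >= 2) lf[2] else 0,
        slope1 = sg$s[1], slope2 = if (nrow(sg) >= 2) sg$s[2] else 0,
        r_m = b$r_m)
    }))
  })
  gm <- colMeans(do.call(rbind, per))
  c(t1 = unname(th[["t1"]]), t2 = unname(th[["t2"]]),
    h_to_i = ratios$h_to_i, v_to_i = ratios$v_to_i, n_to_i = ratios$n_to_i,
    h_to_v = if (is.na(ratios$h_to_v)) 0 else ratios$h_to_v,
    gm)
}
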