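sim_features <- function(m, n, a_star, noise = 0, seed = 1) {
  set.seed(seed)
  F <- matrix(runif(m * n, 0.2, 2), m, n)
  # rescale rows so each calibrating lesion scores exactly 1 under a_star
  F <- F / drop(F %*% a_star)
  if (noise > 0) F <- F + matrix(rnorm(m * n, 0, noise), m, n)
  F
}

test_that("ordinary least squares solves the normal equations for the all-ones target", {
  set.seed(81)
  Fsq <- diag(4) + matrix(runif(16, 0, 0.2), 4)
  fit <- train_ols(Fsq)
  expect_equal(unname(fit$coefficients), drop(solve(Fsq) %*% rep(1, 4)), tolerance = 1e-10)

  a_star <- c(0.5, -0.2, 1.1, 0.3, 0.8, -0.6)
  F <- sim_features(40, 6, a_star)
  fit <- train_ols(F)
  expect_equal(unname(fit$coefficients), a_star, tolerance = 1e-8)
  expect_equal(fit$fitted, rep(1, 40), tolerance = 1e-8)

  # closed-form normal-equation oracle on a generic matrix
  set.seed(82)
  G <- matrix(rnorm(60), 15, 4)
  expect_equal(unname(train_ols(G)$coefficients),
               drop(solve(t(G) %*% G) %*% t(G) %*% rep(1, 15)), tolerance = 1e-8)

  expect_error(train_ols(cbind(G, G[, 1])), class = "hypoxiafeat_singular_error")
  expect_error(train_ols(t(G)), class = "hypoxiafeat_input_error")  # m < n
})

test_that("bisquare reweighting matches OLS on clean data and downweights planted outliers", {
  a_star <- c(0.7, 0.4, -0.3, 0.9)
  F <- sim_features(24, 4, a_star, noise = 0.002, seed = 83)
  ro <- train_robust(F)
  ols <- train_ols(F)
  expect_lt(max(abs(ro$coefficients - ols$coefficients)), 1e-3)
  expect_true(all(ro$weights >= 0 & ro$weights <= 1))

  Fo <- sim_features(22, 4, a_star, noise = 0.01, seed = 84)
  out_rows <- c(3, 17)
  Fo[out_rows, ] <- Fo[out_rows, ] * 10       # gross outliers
  ro <- train_robust(Fo)
  expect_true(all(ro$weights[out_rows] < 0.1))
  expect_equal(ro$m_prime, sum(ro$weights > 0))
  err_rob <- sum((ro$coefficients - a_star)^2)
  err_ols <- sum((train_ols(Fo)$coefficients - a_star)^2)
  expect_lt(err_rob, err_ols)
  expect_equal(formals(train_robust)$c, 4.685)

  # refitting the weighted system at the converged weights is a fixed point
  keep <- ro$weights > 0
  sw <- sqrt(ro$weights[keep])
  refit <- stats::lm.fit(Fo[keep, ] * sw, sw)
  expect_equal(unname(refit$coefficients), unname(ro$coefficients), tolerance = 1e-4)
})

test_that("robust coefficients agree with an independent M-estimation routine", {
  skip_if_not_installed("MASS")
  a_star <- c(0.6, 0.3, -0.4, 1.0)
  F <- sim_features(30, 4, a_star, noise = 0.02, seed = 85)
  F[c(5, 22), ] <- F[c(5, 22), ] / 5   # low-leverage contamination
  ours <- train_robust(F)
  ref <- MASS::rlm(F, rep(1, 30), psi = MASS::psi.bisquare, c = 4.685,
                   maxit = 100)
  expect_equal(unname(ours$coefficients), unname(coef(ref)), tolerance = 0.05)
})

test_that("James-Stein shrinkage contracts, is idempotent at zero noise, and dominates", {
  a <- c(2, -1, 0.5, 3, -2)
  s0 <- shrink_coefficients(a, "spherical", 0)
  expect_equal(s0$coefficients, a)
  s <- shrink_coefficients(a, "spherical", 2)
  expect_lte(sqrt(sum(s$coefficients^2)), sqrt(sum(a^2)))
  sc <- shrink_coefficients(a, "coordinate", 2)
  expect_lte(sqrt(sum(sc$coefficients^2)), sqrt(sum(a^2)))
  expect_true(all(abs(sc$coefficients) <= abs(a)))
  expect_error(shrink_coefficients(c(1, 2), "spherical", 1),
               class = "hypoxiafeat_precondition_error")
  expect_error(shrink_coefficients(a, "spherical", -1), class = "hypoxiafeat_config_error")

  # dominance under squared-error loss, k = 10, unit-noise observations
  set.seed(86)
  k <- 10
  reps <- 500
  mse_raw <- mse_js <- numeric(reps)
  for (r in seq_len(reps)) {
    mu <- rnorm(k)
    x <- mu + rnorm(k)
    js <- shrink_coefficients(x, "spherical", 1)$coefficients
    mse_raw[r] <- sum((x - mu)^2)
    mse_js[r] <- sum((js - mu)^2)
  }
  expect_lt(mean(mse_js), mean(mse_raw))

  # truncation: an extreme coordinate is nearly untouched while
  # coordinates within the noise level are zeroed
  a_ext <- c(50, 0.4, -0.3, 0.5, 1.8)
  coo <- shrink_coefficients(a_ext, "coordinate", 1)
  expect_gt(coo$coefficients[1] / a_ext[1], 0.999)
  expect_equal(coo$coefficients[2:4], c(0, 0, 0))
  expect_gt(coo$coefficients[5], 0)
  expect_identical(shrink_coefficients(a_ext, "coordinate", 0)$coefficients, a_ext)
})

test_that("similarity scores are clipped inner products", {
  a <- structure(list(coefficients = c(0.5, 0.5), method = "spherical",
                      factor = 1, noise_var = 0), class = "shrunken_coefficients")
  expect_equal(score_similarity(c(1, 1), a)$score, 1)
  expect_equal(score_similarity(c(0, 0), a)$score, 0)
  expect_equal(score_similarity(c(4, 4), a)$raw, 4)
  expect_equal(score_similarity(c(4, 4), a)$score, 1)
  expect_equal(score_similarity(c(-1, 0), a)$score, 0)
  expect_error(score_similarity(c(1, 2, 3), a), class = "hypoxiafeat_input_error")
})

test_that("the fitted estimator separates calibration-like lesions from scrambled ones", {
  a_star <- c(0.5, 0.3, 0.9, -0.2, 0.6, 0.4)
  F <- sim_features(40, 6, a_star, noise = 0.01, seed = 87)
  model <- fit_similarity(F, method = "robust", shrink = "spherical")
  expect_equal(unname(coef(model)), a_star, tolerance = 0.05)
  expect_lt(max(abs(unname(coef(model, shrunk = FALSE)) - a_star)) / max(abs(a_star)),
            0.05)

  set.seed(88)
  held <- sim_features(50, 6, a_star, noise = 0.02, seed = 89)
  scrambled <- t(apply(held, 1, sample))
  s_h <- predict(model, held)$score
  s_s <- predict(model, scrambled)$score
  expect_gt(median(s_h), median(s_s))
  expect_equal(median(s_h), 1, tolerance = 0.05)

  expect_output(print(model), "similarity estimator")
  expect_length(residuals(model), 40)
})

test_that("image feature vectors are deterministic with a stable layout", {
  sc <- render_scene(small_lesion_scene(seed = 7, noise = 2))
  lm <- matrix(c(120, 120), 1)
  f1 <- features_from_image(sc$image, lm, C = 30, min_len = 15,
                            smooth_cfg = smoothing_config(iterations = 5))
  f2 <- features_from_image(sc$image, lm, C = 30, min_len = 15,
                            smooth_cfg = smoothing_config(iterations = 5))
  expect_identical(f1, f2)
  expect_named(f1, c("t1", "t2", "h_to_i", "v_to_i", "n_to_i", "h_to_v",
                     "n_seg", "len_frac1", "len_frac2", "slope1", "slope2", "r_m"))
  expect_equal(length(f1), 12L)
  expect_true(f1[["t1"]] < f1[["t2"]])
  expect_true(abs(f1[["slope1"]] - (-0.4)) < 0.1)
})
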