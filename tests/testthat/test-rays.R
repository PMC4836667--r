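test_that("ray sampling covers the exact in-bounds step counts with inert sentinels", {
  img <- matrix(137, 50, 70)
  cfg <- ray_config(n = 80, m = 1)
  expect_equal(diff(attr(sample_rays(img, c(30, 25), cfg), "angles"))[1], pi / 40)

  M <- sample_rays(img, c(30, 25), cfg)
  expect_equal(ncol(M), ceiling(sqrt(50^2 + 70^2)))
  expect_true(all(M[is.finite(M)] == 137))

  # valid sample counts equal a direct step-count oracle
  ang <- attr(M, "angles")
  for (j in seq_len(nrow(M))) {
    k <- 1L
    while (TRUE) {
      px <- round(31 + k * cos(ang[j])); py <- round(26 + k * sin(ang[j]))
      if (px < 1 || px > 70 || py < 1 || py > 50) break
      k <- k + 1L
    }
    expect_equal(sum(is.finite(M[j, ])), k - 1L)
  }

  # corner center: the longest ray approaches the diagonal
  Mc <- sample_rays(img, c(0, 0), cfg)
  expect_gt(max(rowSums(is.finite(Mc))), 0.95 * sqrt(50^2 + 70^2) - 2)
  expect_error(sample_rays(img, c(70, 25)), class = "hypoxiafeat_coordinate_error")
})

test_that("bundle statistics mask sentinels exactly as a direct oracle does", {
  set.seed(41)
  img <- matrix(runif(60 * 60, 0, 255), 60)
  cfg <- ray_config(n = 16, m = 4)
  M <- sample_rays(img, c(10, 45), cfg)   # off-center: many sentinels
  profs <- bundle_profiles(M, cfg)
  expect_length(profs, 4L)
  ang <- attr(M, "angles")
  for (b in 1:4) {
    rows <- which(ang >= (b - 1) * pi / 2 & ang < b * pi / 2)
    expect_equal(profs[[b]]$rays, rows)
    sub <- M[rows, , drop = FALSE]
    for (col in sample(ncol(M), 25)) {
      v <- sub[, col]; v <- v[is.finite(v)]
      if (length(v) == 0) {
        expect_true(is.na(profs[[b]]$mean_vec[col]))
      } else {
        expect_equal(profs[[b]]$mean_vec[col], mean(v))
        expect_equal(profs[[b]]$median_vec[col], median(v))
        expect_equal(profs[[b]]$std_vec[col], if (length(v) > 1) sd(v) else 0)
      }
    }
  }

  # single bundle holds every ray; identical rays collapse the spread
  cfg1 <- ray_config(n = 8, m = 1)
  const <- sample_rays(matrix(42, 30, 30), c(15, 15), cfg1)
  p <- bundle_profiles(const, cfg1)[[1]]
  expect_equal(p$rays, 1:8)
  valid <- !is.na(p$std_vec)
  expect_true(all(p$std_vec[valid] == 0))
  expect_equal(p$mean_vec[valid], p$median_vec[valid])
  expect_true(all(p$mean_vec[valid] == 42))
})

test_that("sentinel handling is inert when every ray stays in bounds", {
  set.seed(42)
  img <- matrix(runif(100 * 100, 0, 255), 100)
  cfg <- ray_config(n = 12, m = 1)
  M <- sample_rays(img, c(50, 50), cfg)
  p <- bundle_profiles(M, cfg)[[1]]
  K <- 40  # every ray is valid through the first 40 steps
  expect_true(all(is.finite(M[, 1:K])))
  direct_mean <- colMeans(M[, 1:K])
  expect_equal(p$mean_vec[1:K], direct_mean)
})

test_that("the measurement radius is the argmin of the median profile within l_t", {
  v <- c(seq(200, 101, length.out = 150), seq(102, 180, length.out = 100))
  prof <- list(median_vec = v, d_s = 1)
  expect_equal(measurement_radius(prof, 1000), 150L)

  dec <- list(median_vec = seq(255, 6, length.out = 250), d_s = 1)
  expect_equal(measurement_radius(dec, 1000), 250L)
  expect_equal(measurement_radius(dec, 100), 100L)   # window truncation

  expect_equal(formals(measurement_radius)$l_t, 1000L)
  expect_equal(ray_config()$l_t, 1000L)
  expect_error(measurement_radius(list(median_vec = rep(NA_real_, 5), d_s = 1), 5),
               class = "hypoxiafeat_empty_window_error")
})

test_that("spurious leading segments are dropped but the final segment survives", {
  mk <- function(df, C = 200) structure(list(segments = df, C = C,
                                             total_cost = sum(df$e) + C * nrow(df)),
                                        class = "segmented_fit")
  sg <- data.frame(start_x = c(1, 21, 101), end_x = c(21, 101, 300),
                   l = c(20, 80, 199), s = c(0.3, -0.2, -0.05),
                   b = c(0, 0, 0), e = c(5, 10, 20), n = c(21, 81, 200),
                   mse = 0)
  f <- filter_spurious(mk(sg), min_len = 40)
  expect_equal(nrow(f$segments), 2L)
  expect_equal(f$segments$s, c(-0.2, -0.05))
  expect_equal(nrow(f$dropped), 1L)

  good <- sg; good$s <- c(-0.3, -0.2, -0.05); good$l <- c(50, 80, 199)
  expect_equal(filter_spurious(mk(good), 40)$segments, good)

  allbad <- sg; allbad$s <- c(0.5, 0.2, 0.1); allbad$l <- c(5, 5, 5)
  expect_equal(nrow(filter_spurious(mk(allbad), 40)$segments), 1L)  # last kept
})

test_that("gradient reports recover planted radial slopes", {
  # noiseless analytic radial field (no rasterized rounding): single slope
  h <- 121; w <- 121
  xs <- matrix(rep(0:(w - 1), each = h), h); ys <- matrix(rep(0:(h - 1), w), h)
  r <- sqrt((xs - 60)^2 + (ys - 60)^2)
  img <- pmax(200 - 0.8 * r, 0)
  rep1 <- gradient_report(img, c(60, 60), ray_config(n = 80, m = 1), C = 200,
                          filter = FALSE)
  b <- rep1$bundles[[1]]
  expect_equal(nrow(b$fit$segments), 1L)
  expect_equal(b$fit$segments$s, -0.8, tolerance = 2e-3)

  # rendered small lesion with two planted slopes, light noise
  sc <- render_scene(small_lesion_scene(seed = 5, noise = 2))
  sm <- smooth(sc$image, smoothing_config(iterations = 5))
  rep2 <- gradient_report(sm, c(120, 120), ray_config(n = 80, m = 1),
                          C = 30, min_len = 15)   # cost scaled to the short profile
  sel <- rep2$bundles[[1]]$fit$segments
  expect_equal(nrow(sel), 2L)
  expect_lt(abs(sel$s[1] - (-0.4)), 0.05)
  expect_lt(abs(sel$s[2] - (-0.1)), 0.05)
  # the fewer-segments selection rule, with ties going to the mean fit
  bb <- rep2$bundles[[1]]
  nm <- nrow(bb$mean_fit$segments); nd <- nrow(bb$median_fit$segments)
  expect_equal(bb$selected, if (nd < nm) "median" else "mean")
})
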