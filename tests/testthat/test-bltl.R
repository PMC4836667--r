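test_that("predicates and connectives evaluate pointwise", {
  tr <- bltl_trace(data.frame(a = c(1, 2, 3), b = c(0, 0, 5)))
  for (k in 1:3) expect_true(bltl_evaluate(tr, bltl_pred("a", "=", tr$values$a[k]), k))
  expect_true(bltl_evaluate(tr, bltl_pred("a", ">=", 1), 1))
  expect_false(bltl_evaluate(tr, bltl_pred("b", ">=", 1), 1))
  expect_true(bltl_evaluate(tr, bltl_not(bltl_pred("b", ">=", 1)), 1))
  expect_true(bltl_evaluate(tr, bltl_or(bltl_pred("b", ">=", 1), bltl_pred("a", "<=", 2)), 1))
  # tolerance form u = v +/- w desugars to the interval
  expect_true(bltl_evaluate(tr, bltl_pred("a", "=", 1.5, tol = 0.6), 1))
  expect_false(bltl_evaluate(tr, bltl_pred("a", "=", 1.5, tol = 0.4), 1))
  expect_error(bltl_evaluate(tr, bltl_pred("zz", ">=", 0), 1),
               class = "hypoxiafeat_evaluation_error")
  expect_error(bltl_until(bltl_pred("a", ">=", 0), bltl_pred("a", ">=", 0),
                          c(q = 1)), class = "hypoxiafeat_formula_error")
})

test_that("the evaluator agrees with the exhaustive-witness oracle on random cases", {
  set.seed(71)
  mismatches <- 0L
  for (rep in 1:400) {
    tr <- random_trace()
    phi <- random_formula(3)
    for (k in seq_len(tr$n)) {
      got <- bltl_evaluate(tr, phi, k)
      want <- bltl_oracle(tr, phi, k)
      if (!identical(got, want)) mismatches <- mismatches + 1L
    }
  }
  expect_equal(mismatches, 0L)
})

test_that("finally and globally equal their until expansions", {
  set.seed(72)
  truepred <- bltl_pred("a", ">=", -Inf)
  for (rep in 1:500) {
    tr <- random_trace(len = sample(1:6, 1))
    inner <- random_formula(2)
    dims <- sample(c("x1", "t", "arc"), 1)
    bound <- setNames(sample(0:5, 1), dims)
    Fphi <- bltl_finally(inner, bound)
    Fexp <- bltl_until(truepred, inner, bound)
    Gphi <- bltl_globally(inner, bound)
    Gexp <- bltl_not(bltl_finally(bltl_not(inner), bound))
    k <- sample(tr$n, 1)
    expect_identical(bltl_evaluate(tr, Fphi, k), bltl_evaluate(tr, Fexp, k))
    expect_identical(bltl_evaluate(tr, Gphi, k), bltl_evaluate(tr, Gexp, k))
  }
})

test_that("loosening an until bound preserves satisfaction", {
  set.seed(73)
  checked <- 0L
  for (rep in 1:300) {
    tr <- random_trace(len = sample(2:6, 1))
    phi1 <- random_formula(1); phi2 <- random_formula(1)
    a <- sample(0:4, 1)
    ua <- bltl_until(phi1, phi2, c(t = a))
    ub <- bltl_until(phi1, phi2, c(t = a + sample(1:3, 1)))
    if (bltl_evaluate(tr, ua, 1)) {
      checked <- checked + 1L
      expect_true(bltl_evaluate(tr, ub, 1))
    }
  }
  expect_gt(checked, 20L)
})

test_that("strict until demands a witness strictly ahead", {
  tr <- bltl_trace(data.frame(a = c(2, 1, 0)))
  p2 <- bltl_pred("a", "=", 2); p1 <- bltl_pred("a", "=", 1)
  expect_true(bltl_evaluate(tr, bltl_until(p1, p2), 1))          # immediate witness
  expect_false(bltl_evaluate(tr, bltl_until(p1, p2, strict = TRUE), 1))
  expect_true(bltl_evaluate(tr, bltl_until(p2, p1, strict = TRUE), 1))
})

test_that("probability estimation counts satisfying traces against theta", {
  mk <- function(v) bltl_trace(data.frame(a = v))
  traces <- list(mk(c(1, 2)), mk(c(1, 3)), mk(c(1, 4)), mk(c(0, 1)))
  phi <- bltl_pred("a", ">=", 1)
  all4 <- estimate_probability(traces[1:3], bltl_prob(phi, 0.99))
  expect_equal(all4$fraction, 1.0)
  expect_true(all4$verdict)

  r <- estimate_probability(traces, bltl_prob(phi, 0.5))
  expect_equal(r$fraction, 0.75)
  expect_true(r$verdict)
  expect_false(estimate_probability(traces, bltl_prob(phi, 0.8))$verdict)
  expect_error(bltl_prob(phi, 1), class = "hypoxiafeat_formula_error")
  expect_error(bltl_prob(phi, 0), class = "hypoxiafeat_formula_error")
  expect_error(estimate_probability(list(), bltl_prob(phi, 0.5)),
               class = "hypoxiafeat_input_error")
})

test_that("formulas survive the s-expression round trip", {
  set.seed(74)
  for (rep in 1:40) {
    phi <- random_formula(3)
    phi2 <- bltl_from_sexp(bltl_to_sexp(phi))
    expect_equal(bltl_to_sexp(phi2), bltl_to_sexp(phi))
    tr <- random_trace()
    expect_identical(bltl_evaluate(tr, phi, 1), bltl_evaluate(tr, phi2, 1))
  }
  expect_error(bltl_from_sexp("(nonsense 1 2)"), class = "hypoxiafeat_formula_error")
})

test_that("gradient walks ascend to the peak and never increase radius on a concave field", {
  const <- matrix(5, 20, 20)
  wk <- walk_gradient(const, c(10, 10), "ascent")
  expect_equal(nrow(wk$path), 1L)
  expect_equal(wk$halted, "optimum")

  n <- 81
  xs <- matrix(rep(0:(n - 1), each = n), n); ys <- matrix(rep(0:(n - 1), n), n)
  r <- sqrt((xs - 40)^2 + (ys - 40)^2)
  dome <- 1000 - r^2 / 10          # strictly concave radial field
  wk <- walk_gradient(dome, c(5, 40), "ascent")
  endp <- wk$path[nrow(wk$path), ]
  expect_lte(sqrt(sum((endp - c(40, 40))^2)), 1)
  rad <- sqrt((wk$path[, 1] - 40)^2 + (wk$path[, 2] - 40)^2)
  expect_true(all(diff(rad) <= 1e-9))

  # descent from the rim of a bowl reaches the bottom
  wk2 <- walk_gradient(-dome, c(70, 40), "descent")
  expect_lte(sqrt(sum((wk2$path[nrow(wk2$path), ] - c(40, 40))^2)), 1)
})

test_that("traces built from trajectories agree with the grammar reading and carry arc lengths", {
  sc <- render_scene(small_lesion_scene(seed = 4, noise = 0))
  n <- nrow(sc$labels)
  traj <- cbind(x = (n %/% 2):(n - 1), y = rep(n %/% 2, n - n %/% 2))
  tr <- trace_from_trajectory(sc$labels, sc$image, traj)
  expect_equal(tr$n, nrow(traj))

  runs <- rle(tr$values$T)$values
  s <- string_along_path(sc$labels, traj)
  expect_equal(c("V", "H", "N")[runs], as.character(s))

  steps <- diff(traj)
  expect_equal(sum(sqrt(rowSums(steps^2))),
               sum(vapply(seq_len(tr$n - 1),
                          function(i) sqrt(sum((tr$coords[i + 1, ] - tr$coords[i, ])^2)),
                          numeric(1))))

  single <- trace_from_trajectory(sc$labels, sc$image, cbind(5, 5))
  expect_equal(single$n, 1L)
  expect_error(trace_from_trajectory(sc$labels, sc$image, cbind(-1, 5)),
               class = "hypoxiafeat_coordinate_error")
})

test_that("the hypoxia proposition accepts a canonical lesion and rejects a label swap", {
  expect_error(build_hypoxia_proposition(gradient = list(s1 = 1)),
               class = "hypoxiafeat_construction_error")

  sc <- render_scene(small_lesion_scene(seed = 6, noise = 1,
                                        slopes = c(-0.4, -0.1),
                                        seg_lengths = c(40, 60)))
  sm <- smooth(sc$image, smoothing_config(iterations = 20))
  phi <- build_hypoxia_proposition(
    gradient = list(s1 = -0.4, s1_sd = 0.3, l1 = 40, l1_sd = 20,
                    s2 = -0.1, s2_sd = 0.08, l2 = 60, l2_sd = 30),
    ratio = list(mean = unname(tissue_ratios(sc$labels)$h_to_v), sd = 0.2))
  res <- check_hypoxia(sc$labels, sm, c(120, 120), phi)
  expect_true(res$verdict)

  swapped_chr <- matrix(c("H", "N", "V")[as.integer(sc$labels) + 1L],
                        nrow(sc$labels))   # V <-> N swap (H fixed)
  swapped <- tissue_labels_from_chars(swapped_chr)
  res2 <- check_hypoxia(swapped, sm, c(120, 120), phi)
  expect_false(res2$verdict)
})
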