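# Independent oracles used across the suite. These deliberately take the
# most naive route available (flood fill, exhaustive enumeration, direct
# per-case recomputation) and share no code with the implementation paths
# they check.

## ---- connected components / Euler characteristic ----

flood_label <- function(mask, conn) {
  lab <- matrix(0L, nrow(mask), ncol(mask)); k <- 0L
  nb <- if (conn == 8) cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
        else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      k <- k + 1L; st <- list(c(i, j)); lab[i, j] <- k
      while (length(st)) {
        p <- st[[length(st)]]; st[[length(st)]] <- NULL
        for (q in seq_len(nrow(nb))) {
          ii <- p[1] + nb[q, 1]; jj <- p[2] + nb[q, 2]
          if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- k; st[[length(st) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

epc_oracle <- function(B) {
  B <- B != 0
  ncomp <- max(flood_label(B, 8), 0L)
  labbg <- flood_label(!B, 4)
  border <- unique(c(labbg[1, ], labbg[nrow(labbg), ], labbg[, 1], labbg[, ncol(labbg)]))
  holes <- length(setdiff(unique(labbg[labbg > 0]), border))
  ncomp - holes
}

## ---- segmented least squares: exhaustive enumeration ----

# All segmentations of indices 1..n into contiguous runs of length >= 2,
# each segment refit from scratch with lm().
sls_bruteforce <- function(x, y, C) {
  n <- length(x)
  best <- list(cost = Inf)
  for (mask in 0:(2^(n - 1) - 1)) {
    bp <- which(bitwAnd(mask, 2^(seq_len(n - 1) - 1)) > 0)
    starts <- c(1, bp + 1); ends <- c(bp, n)
    if (any(ends - starts + 1 < 2)) next
    cost <- C * length(starts)
    for (s in seq_along(starts)) {
      idx <- starts[s]:ends[s]
      f <- stats::lm(y[idx] ~ x[idx])
      cost <- cost + sum(stats::residuals(f)^2)
    }
    if (cost < best$cost - 1e-12) best <- list(cost = cost, starts = starts, ends = ends)
  }
  best
}

## ---- two-threshold Otsu: direct per-pair maximization ----

otsu_bruteforce <- function(img) {
  v <- as.integer(pmin(pmax(round(img), 0), 255))
  h <- tabulate(v + 1L, nbins = 256L)
  lev <- 0:255
  n <- sum(h)
  mu <- sum(h * lev) / n
  best <- -Inf; pair <- c(NA, NA)
  for (t1 in 0:254) for (t2 in (t1 + 1):255) {
    g0 <- h[lev <= t1]; l0 <- lev[lev <= t1]
    g1 <- h[lev > t1 & lev <= t2]; l1 <- lev[lev > t1 & lev <= t2]
    g2 <- h[lev > t2]; l2 <- lev[lev > t2]
    sb <- 0
    for (cls in list(list(g0, l0), list(g1, l1), list(g2, l2))) {
      wk <- sum(cls[[1]]) / n
      if (wk > 0) sb <- sb + wk * (sum(cls[[1]] * cls[[2]]) / sum(cls[[1]]) - mu)^2
    }
    if (sb > best + 1e-12) { best <- sb; pair <- c(t1, t2) }
  }
  pair
}

## ---- extended BLTL: naive witness-enumeration evaluator ----

oracle_accum <- function(trace, k, i, d) {
  if (i == 0) return(0)
  if (d == "t") return(sum(trace$durations[k + 0:(i - 1)]))
  if (d == "arc") {
    tot <- 0
    for (l in 1:i) tot <- tot + sqrt(sum((trace$coords[k + l, ] - trace$coords[k + l - 1, ])^2))
    return(tot)
  }
  tot <- 0
  for (l in 1:i) tot <- tot + trace$coords[k + l, d] - trace$coords[k + l - 1, d]
  tot
}

oracle_bound_ok <- function(trace, k, i, bound) {
  if (is.null(bound)) return(TRUE)
  for (d in names(bound)) if (oracle_accum(trace, k, i, d) > bound[[d]] + 1e-9) return(FALSE)
  TRUE
}

bltl_oracle <- function(trace, phi, k) {
  op <- phi$op
  if (op == "pred") {
    val <- trace$values[[phi$var]][k]
    return(switch(phi$rel, ">=" = val >= phi$v, "<=" = val <= phi$v, "=" = val == phi$v))
  }
  if (op == "not") return(!bltl_oracle(trace, phi$phi, k))
  if (op == "and") return(bltl_oracle(trace, phi$phi1, k) && bltl_oracle(trace, phi$phi2, k))
  if (op == "or") return(bltl_oracle(trace, phi$phi1, k) || bltl_oracle(trace, phi$phi2, k))
  imax <- trace$n - k
  if (op == "until") {
    i0 <- if (isTRUE(phi$strict)) 1 else 0
    i <- i0
    while (i <= imax) {
      cond1 <- oracle_bound_ok(trace, k, i, phi$bound)
      cond2 <- bltl_oracle(trace, phi$phi2, k + i)
      cond3 <- i == 0 || all(vapply(0:(i - 1), function(j) bltl_oracle(trace, phi$phi1, k + j), NA))
      if (cond1 && cond2 && cond3) return(TRUE)
      i <- i + 1
    }
    return(FALSE)
  }
  if (op == "finally") {
    for (i in 0:imax)
      if (oracle_bound_ok(trace, k, i, phi$bound) && bltl_oracle(trace, phi$phi, k + i)) return(TRUE)
    return(FALSE)
  }
  if (op == "globally") {
    for (i in 0:imax)
      if (oracle_bound_ok(trace, k, i, phi$bound) && !bltl_oracle(trace, phi$phi, k + i)) return(FALSE)
    return(TRUE)
  }
  stop("unknown op in oracle")
}

## ---- random generators for property tests ----

random_trace <- function(len = sample(1:5, 1), vars = c("a", "b")) {
  vals <- as.data.frame(setNames(lapply(vars, function(v) sample(0:3, len, TRUE)), vars))
  bltl_trace(vals,
             durations = sample(0:2, len, TRUE),
             coords = cbind(x1 = cumsum(sample(-1:2, len, TRUE)),
                            x2 = cumsum(sample(-1:2, len, TRUE))))
}

random_formula <- function(depth = 3, vars = c("a", "b")) {
  if (depth <= 0 || stats::runif(1) < 0.3) {
    return(bltl_pred(sample(vars, 1), sample(c(">=", "<=", "="), 1), sample(0:3, 1)))
  }
  op <- sample(c("not", "and", "or", "until", "finally", "globally"), 1)
  rb <- function() {
    if (stats::runif(1) < 0.4) return(NULL)
    dims <- sample(c("x1", "x2", "t", "arc"), sample(1:2, 1))
    stats::setNames(sample(0:6, length(dims), TRUE), dims)
  }
  switch(op,
    not = bltl_not(random_formula(depth - 1, vars)),
    and = bltl_and(random_formula(depth - 1, vars), random_formula(depth - 1, vars)),
    or = bltl_or(random_formula(depth - 1, vars), random_formula(depth - 1, vars)),
    until = bltl_until(random_formula(depth - 1, vars), random_formula(depth - 1, vars),
                       rb(), strict = stats::runif(1) < 0.3),
    finally = bltl_finally(random_formula(depth - 1, vars), rb()),
    globally = bltl_globally(random_formula(depth - 1, vars), rb()))
}

## ---- small synthetic fixtures ----

# Small lesion whose full geometry fits a compact frame: keeps module tests
# fast while the acceptance suite exercises the full-size study geometry.
small_lesion_scene <- function(seed = 1L, noise = 0, slopes = c(-0.4, -0.1),
                               seg_lengths = c(40, 60), size = 240L) {
  scene_spec(size, size,
             list(lesion_spec(center = c(size %/% 2L, size %/% 2L),
                              vessel_radius = 5, viable_outer = seg_lengths[1],
                              slopes = slopes, seg_lengths = seg_lengths,
                              base_intensity = 200, necrotic_level = 230,
                              noise_sigma = noise)),
             background_level = 230, seed = seed)
}

# Same enumeration as sls_bruteforce but with the segment SSE computed from
# centered moments (fast enough for n = 14); still independent of the DP's
# prefix-sum path.
sls_bruteforce_fast <- function(x, y, C) {
  n <- length(x)
  seg_sse <- function(idx) {
    xx <- x[idx]; yy <- y[idx]
    dx <- xx - mean(xx); dy <- yy - mean(yy)
    sum(dy^2) - (sum(dx * dy))^2 / sum(dx^2)
  }
  best <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    bp <- which(bitwAnd(mask, 2^(seq_len(n - 1) - 1)) > 0)
    starts <- c(1, bp + 1); ends <- c(bp, n)
    if (any(ends - starts + 1 < 2)) next
    cost <- C * length(starts)
    for (s in seq_along(starts)) {
      cost <- cost + seg_sse(starts[s]:ends[s])
      if (cost >= best) break
    }
    if (cost < best) best <- cost
  }
  best
}
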