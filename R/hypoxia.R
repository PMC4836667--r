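# Gradient-walk trajectory generation and the ready-made hypoxia
# proposition that ties tissue labels, gradient slopes and the
# hypoxic:viable ratio together.

#' Walk a concentration gradient
#'
#' From `start`, repeatedly steps to the 8-neighbor with the greatest
#' (ascent) or smallest (descent) concentration, recording the per-step
#' concentration change. Halts at a local optimum (no strictly better
#' neighbor), when all in-bounds neighbors are exhausted at the field edge,
#' or after `max_steps`. Ties between equally good neighbors resolve to the
#' first in a fixed clockwise ordering starting east
#' (E, SE, S, SW, W, NW, N, NE with y downward).
#'
#' @param field Numeric matrix of concentration values (e.g. stain density
#'   `255 - intensity` for a dark-is-dense stain).
#' @param start `c(x, y)` 0-based start pixel.
#' @param direction `"ascent"` or `"descent"`.
#' @param max_steps Step budget (default 10000).
#' @return List with `path` (steps+1 x 2 matrix of 0-based `x`, `y`),
#'   `rho` (concentration at each visited pixel), and `halted`
#'   (`"optimum"`, `"max_steps"`).
#' @export
walk_gradient <- function(field, start, direction = c("ascent", "descent"),
                          max_steps = 10000L) {
  direction <- match.arg(direction)
  rc <- center_to_rc(start, field)
  h <- nrow(field); w <- ncol(field)
  nb <- rbind(c(1, 0), c(1, 1), c(0, 1), c(-1, 1),
              c(-1, 0), c(-1, -1), c(0, -1), c(1, -1))  # (dx, dy), clockwise from east
  x <- rc[["col"]]; y <- rc[["row"]]
  path <- matrix(NA_real_, max_steps + 1L, 2L)
  rho <- numeric(max_steps + 1L)
  path[1L, ] <- c(x, y); rho[1L] <- field[y, x]
  halted <- "max_steps"; np <- 1L
  better <- if (direction == "ascent") `>` else `<`
  for (s in seq_len(max_steps)) {
    nx <- x + nb[, 1]; ny <- y + nb[, 2]
    ok <- nx >= 1 & nx <= w & ny >= 1 & ny <= h
    if (!any(ok)) { halted <- "optimum"; break }
    vals <- rep(if (direction == "ascent") -Inf else Inf, 8L)
    vals[ok] <- field[cbind(ny[ok], nx[ok])]
    best <- if (direction == "ascent") which.max(vals) else which.min(vals)
    if (!better(vals[best], field[y, x])) { halted <- "optimum"; break }
    x <- nx[best]; y <- ny[best]
    np <- np + 1L
    path[np, ] <- c(x, y); rho[np] <- field[y, x]
  }
  list(path = cbind(x = path[seq_len(np), 1] - 1, y = path[seq_len(np), 2] - 1),
       rho = rho[seq_len(np)], halted = halted)
}

#' Build a logic trace from an image trajectory
#'
#' Binds image content to the logic's state variables along an ordered
#' pixel path: per state, the tissue label `T` (coded `V = 1, H = 2,
#' N = 3`), the local `intensity`, the per-step intensity change per unit
#' arc length `slope` (the gradient-walker's measure; the first state
#' repeats the first step's value), and the hypoxic:viable ratio `C`
#' (constant along the trace). Coordinates carry `x1 = x`, `x2 = y`;
#' durations default to 1 per state.
#'
#' @param labels A `tissue_labels` matrix.
#' @param intensity Grayscale matrix (use the smoothed image so slopes are
#'   not dominated by quantization).
#' @param trajectory Two-column matrix of 0-based `x`, `y` positions.
#' @param durations Optional per-state durations.
#' @return A [bltl_trace()].
#' @export
trace_from_trajectory <- function(labels, intensity, trajectory, durations = NULL) {
  trajectory <- as.matrix(trajectory)
  tis <- label_at(labels, trajectory[, 1], trajectory[, 2])
  rc <- cbind(trajectory[, 2] + 1, trajectory[, 1] + 1)
  if (any(rc[, 1] < 1 | rc[, 1] > nrow(intensity) | rc[, 2] < 1 | rc[, 2] > ncol(intensity)))
    stop_hypoxiafeat("trajectory leaves the intensity image", "hypoxiafeat_coordinate_error")
  iv <- intensity[rc]
  n <- nrow(trajectory)
  slope <- rep(0, n)
  if (n > 1L) {
    steps <- diff(trajectory)
    arc <- sqrt(rowSums(steps^2))
    slope[-1L] <- diff(iv) / pmax(arc, .Machine$double.eps)
    slope[1L] <- slope[2L]
  }
  ratio <- tissue_ratios(labels)
  cvar <- if (is.na(ratio$h_to_v)) Inf else ratio$h_to_v
  bltl_trace(values = data.frame(T = match(tis, c("V", "H", "N")),
                                 intensity = iv, slope = slope, C = cvar),
             durations = durations,
             coords = cbind(x1 = trajectory[, 1], x2 = trajectory[, 2]))
}

tissue_is <- function(sym)
  bltl_pred("T", "=", match(sym, c("V", "H", "N")))

#' The hypoxia proposition
#'
#' Builds the spatiotemporal proposition characterizing a chronically
#' hypoxic lesion as the conjunction, under a temporal globally bound
#' `tau`, of: (a) the neighbor-axiom terms — along `x1` and along `x2`, no
#' viable region runs directly into a necrotic one or vice versa; (b) the
#' tissue-order term — viable until hypoxic until necrotic along the
#' gradient-ascent trajectory; (c) the gradient term — a first-segment
#' slope of `s1 +/- s1_sd` within arc length `l1 + l1_sd`, until a
#' second-segment slope of `s2 +/- s2_sd` within arc length `l2 + l2_sd`,
#' the whole within `l1 + l1_sd + l2 + l2_sd`; and (d) the ratio term —
#' the hypoxic:viable pixel ratio equals `ratio_mean +/- ratio_sd`.
#'
#' Defaults are the measured two-segment low-concentration gradient
#' statistics (slopes -0.21 +/- 0.19 over 172 + 83 px, then -0.06 +/- 0.03
#' over 267 + 126 px) and the unsmoothed hypoxic:viable ratio 0.36 +/-
#' 0.24. All constants are overridable.
#'
#' The region-transition untils are built strict (witness strictly ahead),
#' since the non-strict reading is vacuously true whenever the target
#' tissue is already present at the start state; see the module notes in
#' the logic documentation.
#'
#' @param gradient List with `s1`, `s1_sd`, `l1`, `l1_sd`, `s2`, `s2_sd`,
#'   `l2`, `l2_sd`.
#' @param ratio List with `mean`, `sd`.
#' @param tau Temporal bound of the outer globally (default 0: a single
#'   snapshot state).
#' @param extent Named numeric `c(x1 = ..., x2 = ...)` spatial extents for
#'   the neighbor-axiom and tissue-order bounds (defaults to unbounded,
#'   i.e. the full trace).
#' @return A `bltl_formula`.
#' @export
build_hypoxia_proposition <- function(
    gradient = list(s1 = -0.21, s1_sd = 0.19, l1 = 172, l1_sd = 83,
                    s2 = -0.06, s2_sd = 0.03, l2 = 267, l2_sd = 126),
    ratio = list(mean = 0.36, sd = 0.24),
    tau = 0,
    extent = NULL) {
  need <- c("s1", "s1_sd", "l1", "l1_sd", "s2", "s2_sd", "l2", "l2_sd")
  if (!all(need %in% names(gradient)) || !all(c("mean", "sd") %in% names(ratio)))
    stop_hypoxiafeat("missing gradient or ratio parameters", "hypoxiafeat_construction_error")
  b1 <- if (!is.null(extent) && "x1" %in% names(extent)) c(x1 = unname(extent[["x1"]])) else NULL
  b2 <- if (!is.null(extent) && "x2" %in% names(extent)) c(x2 = unname(extent[["x2"]])) else NULL
  barc <- if (!is.null(extent)) c(arc = sqrt(sum(extent^2))) else NULL
  V <- tissue_is("V"); H <- tissue_is("H"); N <- tissue_is("N")
  a1_x1 <- bltl_and(bltl_not(bltl_until(N, V, b1, strict = TRUE)),
                    bltl_not(bltl_until(V, N, b1, strict = TRUE)))
  a1_x2 <- bltl_and(bltl_not(bltl_until(N, V, b2, strict = TRUE)),
                    bltl_not(bltl_until(V, N, b2, strict = TRUE)))
  order_term <- bltl_until(V, bltl_until(H, N, barc, strict = TRUE), barc,
                           strict = TRUE)
  g <- gradient
  seg1 <- bltl_finally(bltl_pred("slope", "=", g$s1, tol = g$s1_sd),
                       c(arc = g$l1 + g$l1_sd))
  seg2 <- bltl_finally(bltl_pred("slope", "=", g$s2, tol = g$s2_sd),
                       c(arc = g$l2 + g$l2_sd))
  grad_term <- bltl_until(seg1, seg2,
                          c(arc = g$l1 + g$l1_sd + g$l2 + g$l2_sd))
  ratio_term <- bltl_pred("C", "=", ratio$mean, tol = ratio$sd)
  body <- bltl_and(bltl_and(a1_x1, a1_x2),
                   bltl_and(bltl_and(order_term, grad_term), ratio_term))
  bltl_globally(body, c(t = tau))
}

#' Check the hypoxia proposition on a segmented image
#'
#' Convenience driver: builds the gradient-ascent trajectory of the stain
#' density (`255 - intensity`) from the vessel landmark, converts it to a
#' logic trace, and evaluates the hypoxia proposition on it. The trajectory
#' is extended through the necrotic rim by continuing radially if the walk
#' halts at the stain-density optimum before reaching necrosis.
#'
#' @param labels A `tissue_labels` matrix.
#' @param intensity Smoothed grayscale matrix.
#' @param center `c(x, y)` vessel landmark, 0-based.
#' @param phi Optional formula (default [build_hypoxia_proposition()]).
#' @param use_walk Use the gradient walker for the trajectory (default);
#'   otherwise a straight horizontal ray from the center.
#' @return List with `verdict`, the `trace`, the `trajectory`, and `phi`.
#' @export
check_hypoxia <- function(labels, intensity, center, phi = NULL,
                          use_walk = TRUE) {
  if (is.null(phi)) phi <- build_hypoxia_proposition()
  traj <- if (use_walk) {
    wk <- walk_gradient(255 - intensity, center, "ascent")
    extend_radially(wk$path, labels)
  } else {
    rc <- center_to_rc(center, intensity)
    x <- seq(center[[1]], ncol(intensity) - 1L)
    cbind(x = x, y = rep(center[[2]], length(x)))
  }
  tr <- trace_from_trajectory(labels, intensity, traj)
  list(verdict = bltl_evaluate(tr, phi, 1L), trace = tr, trajectory = traj,
       phi = phi)
}

# Continue a walk outward along its mean direction until the field edge or
# two necrotic-labelled steps, so the trace witnesses the tissue beyond the
# stain-density peak.
extend_radially <- function(path, labels) {
  n <- nrow(path)
  if (n < 2L) return(path)
  d <- path[n, ] - path[1, ]
  nrm <- sqrt(sum(d^2))
  if (nrm == 0) return(path)
  d <- d / nrm
  x <- path[n, 1]; y <- path[n, 2]
  extra <- NULL; seen_n <- 0L
  for (s in seq_len(max(dim(labels)))) {
    x <- x + d[1]; y <- y + d[2]
    xi <- round(x); yi <- round(y)
    if (xi < 0 || yi < 0 || xi > ncol(labels) - 1 || yi > nrow(labels) - 1) break
    prev <- if (is.null(extra)) path[n, ] else extra[nrow(extra), ]
    if (xi == prev[1] && yi == prev[2]) next
    extra <- rbind(extra, c(xi, yi))
    if (label_at(labels, xi, yi) == "N") seen_n <- seen_n + 1L
    if (seen_n >= 2L) break
  }
  if (is.null(extra)) path else rbind(path, extra)
}
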