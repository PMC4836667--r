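# Extended (spatial + temporal) Bounded Linear Temporal Logic.
#
# Formulas are ASTs over Boolean predicates `u ~ v` (~ in >=, <=, =, with
# an optional tolerance half-width for "= v +/- w"), the Boolean
# connectives, and bounded until / finally / globally. A bound is a named
# nonnegative rational limit over one or more accumulation dimensions:
#   x1, x2, x3 - signed coordinate increments summed along the trace,
#   t          - state durations summed along the trace,
#   arc        - Euclidean step lengths summed along the trace (the arc
#                length of a curvilinear trajectory; a diagonal pixel step
#                contributes sqrt(2)).
# Semantics are finite-trace: the witness index of an until ranges over the
# remaining states only, and an until with no witness before the trace end
# is false.
#
# Until carries a `strict` flag. The standard (non-strict) reading admits
# the witness i = 0, so `phi1 U phi2` is true whenever `phi2` holds
# immediately. Propositions that encode *region transitions* (e.g. "N
# tissue until V tissue" as a violation of the neighbor axiom) are
# vacuously satisfied by that immediate witness; the strict reading
# (witness at i >= 1, so phi1 must hold at the current state) expresses
# their evident intent and is what the ready-made hypoxia proposition uses.

new_formula <- function(op, ...) structure(list(op = op, ...), class = "bltl_formula")

#' Boolean predicate over a state variable
#'
#' @param var State-variable name.
#' @param rel One of `">="`, `"<="`, `"="`.
#' @param v Rational constant.
#' @param tol Optional tolerance half-width: `bltl_pred(u, "=", v, w)` is
#'   the interval predicate `u = v +/- w`, desugared to
#'   `(u >= v - w) & (u <= v + w)`.
#' @return A `bltl_formula`.
#' @export
bltl_pred <- function(var, rel = c(">=", "<=", "="), v, tol = NULL) {
  rel <- match.arg(rel)
  if (!is.null(tol)) {
    if (rel != "=" || tol < 0)
      stop_hypoxiafeat("tolerance form requires relation '=' and tol >= 0",
                       "hypoxiafeat_formula_error")
    return(bltl_and(bltl_pred(var, ">=", v - tol), bltl_pred(var, "<=", v + tol)))
  }
  new_formula("pred", var = var, rel = rel, v = v)
}

#' @rdname bltl_ops
#' @export
bltl_not <- function(phi) new_formula("not", phi = phi)

#' Boolean and temporal connectives
#'
#' Constructors for the formula AST: negation, conjunction, disjunction,
#' bounded until (optionally strict), and the derived bounded finally
#' (`F phi = True U phi`) and globally (`G phi = !F !phi`) operators.
#'
#' @param phi,phi1,phi2 Subformulas.
#' @param bound Named nonnegative numeric vector over dimensions `x1`,
#'   `x2`, `x3`, `t`, `arc`; an empty/NULL bound means unbounded.
#' @param strict For until: require the witness strictly after the current
#'   state (see the module notes).
#' @return A `bltl_formula`.
#' @name bltl_ops
#' @export
bltl_and <- function(phi1, phi2) new_formula("and", phi1 = phi1, phi2 = phi2)

#' @rdname bltl_ops
#' @export
bltl_or <- function(phi1, phi2) new_formula("or", phi1 = phi1, phi2 = phi2)

check_bound <- function(bound) {
  if (is.null(bound) || length(bound) == 0L) return(NULL)
  if (is.null(names(bound)) || !all(names(bound) %in% c("x1", "x2", "x3", "t", "arc")))
    stop_hypoxiafeat("bound dimensions must be named among x1, x2, x3, t, arc",
                     "hypoxiafeat_formula_error")
  if (any(bound < 0)) stop_hypoxiafeat("bounds must be nonnegative", "hypoxiafeat_formula_error")
  bound
}

#' @rdname bltl_ops
#' @export
bltl_until <- function(phi1, phi2, bound = NULL, strict = FALSE)
  new_formula("until", phi1 = phi1, phi2 = phi2, bound = check_bound(bound),
              strict = isTRUE(strict))

#' @rdname bltl_ops
#' @export
bltl_finally <- function(phi, bound = NULL)
  new_formula("finally", phi = phi, bound = check_bound(bound))

#' @rdname bltl_ops
#' @export
bltl_globally <- function(phi, bound = NULL)
  new_formula("globally", phi = phi, bound = check_bound(bound))

#' Probabilistic wrapper
#'
#' @param phi A `bltl_formula`.
#' @param theta Probability threshold, strictly inside (0, 1).
#' @return A `bltl_pformula`.
#' @export
bltl_prob <- function(phi, theta) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta >= 1)
    stop_hypoxiafeat("theta must lie strictly in (0, 1)", "hypoxiafeat_formula_error")
  structure(list(phi = phi, theta = theta), class = "bltl_pformula")
}

#' Construct an execution trace
#'
#' A trace is a finite sequence of states: per-state values of named state
#' variables, a nonnegative duration per state, and spatial coordinates.
#'
#' @param values Data frame (one row per state) of state-variable values.
#' @param durations Nonnegative numeric vector (default 1 per state).
#' @param coords Matrix/data frame with columns `x1`, `x2` (optionally
#'   `x3`); defaults to zeros.
#' @return Object of class `bltl_trace`.
#' @export
bltl_trace <- function(values, durations = NULL, coords = NULL) {
  values <- as.data.frame(values)
  n <- nrow(values)
  if (n < 1L) stop_hypoxiafeat("trace must be nonempty", "hypoxiafeat_input_error")
  if (is.null(durations)) durations <- rep(1, n)
  if (any(durations < 0) || length(durations) != n)
    stop_hypoxiafeat("durations must be nonnegative, one per state", "hypoxiafeat_input_error")
  if (is.null(coords)) coords <- matrix(0, n, 2, dimnames = list(NULL, c("x1", "x2")))
  coords <- as.matrix(coords)
  if (nrow(coords) != n) stop_hypoxiafeat("coords must have one row per state", "hypoxiafeat_input_error")
  structure(list(values = values, durations = durations, coords = coords, n = n),
            class = "bltl_trace")
}

# Accumulated amount of dimension d over steps k..k+i (i >= 0).
# Spatial dims: signed coordinate increments; t: durations of states
# k..k+i-1; arc: Euclidean step lengths.
trace_accum <- function(trace, k, i, d) {
  if (i == 0L) return(0)
  idx <- (k + 1L):(k + i)
  switch(d,
    t = sum(trace$durations[k:(k + i - 1L)]),
    arc = {
      steps <- trace$coords[idx, , drop = FALSE] - trace$coords[idx - 1L, , drop = FALSE]
      sum(sqrt(rowSums(steps^2)))
    },
    sum(trace$coords[idx, d] - trace$coords[idx - 1L, d]))
}

within_bound <- function(trace, k, i, bound) {
  if (is.null(bound)) return(TRUE)
  all(vapply(names(bound), function(d) trace_accum(trace, k, i, d) <= bound[[d]] + 1e-9,
             NA))
}

#' Evaluate a formula on a trace
#'
#' Finite-trace semantics of the extended BLTL, starting at state `k`
#' (1-based). Until: there must exist a witness index `i` (`i >= 1` when
#' strict) with the accumulated spatial/temporal amounts within every bound
#' dimension, `phi2` holding at `k + i`, and `phi1` holding at all states
#' from `k` up to (excluding) `k + i`.
#'
#' @param trace A [bltl_trace()].
#' @param phi A `bltl_formula`.
#' @param k Start state, 1-based.
#' @return Logical.
#' @export
bltl_evaluate <- function(trace, phi, k = 1L) {
  stopifnot(inherits(trace, "bltl_trace"), inherits(phi, "bltl_formula"))
  if (k < 1L || k > trace$n)
    stop_hypoxiafeat("start state outside trace", "hypoxiafeat_input_error")
  eval_at(trace, phi, as.integer(k))
}

eval_at <- function(trace, phi, k) {
  switch(phi$op,
    pred = {
      if (!phi$var %in% names(trace$values))
        stop_hypoxiafeat(sprintf("unknown state variable '%s'", phi$var),
                         "hypoxiafeat_evaluation_error")
      val <- trace$values[[phi$var]][k]
      switch(phi$rel, ">=" = val >= phi$v, "<=" = val <= phi$v, "=" = val == phi$v)
    },
    not = !eval_at(trace, phi$phi, k),
    and = eval_at(trace, phi$phi1, k) && eval_at(trace, phi$phi2, k),
    or  = eval_at(trace, phi$phi1, k) || eval_at(trace, phi$phi2, k),
    until = {
      # phi1 holds at k .. k+i-1 whenever the loop reaches index i, because
      # the loop exits the first time phi1 fails (after phi2 had its chance
      # there: the witness state itself need not satisfy phi1). Bounds are
      # re-tested per witness since signed spatial sums are not monotone.
      imax <- trace$n - k
      i0 <- if (phi$strict) 1L else 0L
      for (i in 0:imax) {
        if (i >= i0 && within_bound(trace, k, i, phi$bound) &&
            eval_at(trace, phi$phi2, k + i)) return(TRUE)
        if (!eval_at(trace, phi$phi1, k + i)) return(FALSE)
      }
      FALSE
    },
    finally = {
      imax <- trace$n - k
      for (i in 0:imax) {
        if (within_bound(trace, k, i, phi$bound) &&
            eval_at(trace, phi$phi, k + i)) return(TRUE)
      }
      FALSE
    },
    globally = {
      imax <- trace$n - k
      for (i in 0:imax) {
        if (within_bound(trace, k, i, phi$bound) &&
            !eval_at(trace, phi$phi, k + i)) return(FALSE)
      }
      TRUE
    },
    stop_hypoxiafeat(sprintf("unknown operator '%s'", phi$op),
                     "hypoxiafeat_evaluation_error"))
}

#' Estimate the satisfaction probability over traces
#'
#' Evaluates `phi` from the initial state of each trace and compares the
#' satisfaction fraction against the threshold of a probabilistic formula
#' `P_{>= theta}(phi)`.
#'
#' @param traces List of [bltl_trace()] objects.
#' @param pf A [bltl_prob()] formula (or a plain formula plus `theta`).
#' @param theta Threshold when `pf` is a plain formula.
#' @return List with `fraction`, `verdict` (`fraction >= theta`),
#'   `n_traces`, `theta`.
#' @export
estimate_probability <- function(traces, pf, theta = NULL) {
  if (inherits(pf, "bltl_formula")) pf <- bltl_prob(pf, theta)
  stopifnot(inherits(pf, "bltl_pformula"))
  if (length(traces) < 1L)
    stop_hypoxiafeat("need at least one trace", "hypoxiafeat_input_error")
  sat <- vapply(traces, function(tr) bltl_evaluate(tr, pf$phi, 1L), NA)
  frac <- mean(sat)
  list(fraction = frac, verdict = frac >= pf$theta,
       n_traces = length(traces), theta = pf$theta)
}

#' @export
print.bltl_formula <- function(x, ...) {
  cat(bltl_to_sexp(x), "\n")
  invisible(x)
}

#' Serialize a formula to an s-expression string
#'
#' @param phi A `bltl_formula`.
#' @return Character scalar, e.g.
#'   `"(until (pred T = 1) (pred T = 2) :bound (arc 255) :strict)"`.
#' @export
bltl_to_sexp <- function(phi) {
  bnd <- function(b, strict = FALSE) {
    out <- ""
    if (!is.null(b) && length(b))
      out <- paste0(" :bound (", paste(names(b), b, collapse = " "), ")")
    if (strict) out <- paste0(out, " :strict")
    out
  }
  switch(phi$op,
    pred = sprintf("(pred %s %s %s)", phi$var, phi$rel, format(phi$v, digits = 12)),
    not = sprintf("(not %s)", bltl_to_sexp(phi$phi)),
    and = sprintf("(and %s %s)", bltl_to_sexp(phi$phi1), bltl_to_sexp(phi$phi2)),
    or = sprintf("(or %s %s)", bltl_to_sexp(phi$phi1), bltl_to_sexp(phi$phi2)),
    until = sprintf("(until %s %s%s)", bltl_to_sexp(phi$phi1), bltl_to_sexp(phi$phi2),
                    bnd(phi$bound, phi$strict)),
    finally = sprintf("(finally %s%s)", bltl_to_sexp(phi$phi), bnd(phi$bound)),
    globally = sprintf("(globally %s%s)", bltl_to_sexp(phi$phi), bnd(phi$bound)))
}

#' Parse a formula from an s-expression string
#'
#' Inverse of [bltl_to_sexp()].
#'
#' @param text S-expression string.
#' @return A `bltl_formula`.
#' @export
bltl_from_sexp <- function(text) {
  toks <- regmatches(text, gregexpr("\\(|\\)|[^()[:space:]]+", text))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  expect <- function(t) if (!identical(take(), t))
    stop_hypoxiafeat(sprintf("malformed s-expression near token %d", pos - 1L),
                     "hypoxiafeat_formula_error")
  parse_bound <- function() {
    expect("(")
    b <- numeric(0)
    while (!identical(peek(), ")")) {
      d <- take(); v <- as.numeric(take())
      b[d] <- v
    }
    expect(")")
    b
  }
  parse_tail <- function() {
    bound <- NULL; strict <- FALSE
    while (!identical(peek(), ")")) {
      kw <- take()
      if (identical(kw, ":bound")) bound <- parse_bound()
      else if (identical(kw, ":strict")) strict <- TRUE
      else stop_hypoxiafeat(sprintf("unknown keyword '%s'", kw), "hypoxiafeat_formula_error")
    }
    list(bound = bound, strict = strict)
  }
  parse_expr <- function() {
    expect("(")
    op <- take()
    out <- switch(op,
      pred = {
        var <- take(); rel <- take(); v <- as.numeric(take())
        new_formula("pred", var = var, rel = rel, v = v)
      },
      not = new_formula("not", phi = parse_expr()),
      and = new_formula("and", phi1 = parse_expr(), phi2 = parse_expr()),
      or = new_formula("or", phi1 = parse_expr(), phi2 = parse_expr()),
      until = {
        p1 <- parse_expr(); p2 <- parse_expr(); tl <- parse_tail()
        new_formula("until", phi1 = p1, phi2 = p2,
                    bound = check_bound(tl$bound), strict = tl$strict)
      },
      finally = {
        p <- parse_expr(); tl <- parse_tail()
        new_formula("finally", phi = p, bound = check_bound(tl$bound))
      },
      globally = {
        p <- parse_expr(); tl <- parse_tail()
        new_formula("globally", phi = p, bound = check_bound(tl$bound))
      },
      stop_hypoxiafeat(sprintf("unknown operator '%s'", op), "hypoxiafeat_formula_error"))
    expect(")")
    out
  }
  out <- parse_expr()
  if (!is.na(peek()))
    stop_hypoxiafeat("trailing tokens after formula", "hypoxiafeat_formula_error")
  out
}
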