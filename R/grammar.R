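# The V/H/N tissue-transformation grammar.
#
# Two axioms govern how viable (V), hypoxic (H) and necrotic (N) regions
# are arranged and evolve: A1 (spatial) — V and N are invalid neighbors, H
# must separate them; A2 (temporal) — a region progresses V -> H -> N with
# N absorbing. Production rules are *derived* from the axioms here, not
# hard-coded, so the valid/invalid split is a checkable consequence.

TISSUE_SYMBOLS <- c("V", "H", "N")

#' Successor map of tissue states
#'
#' The temporal monotonicity axiom: V becomes H, H becomes N, and N is
#' absorbing (no successor).
#'
#' @return Named character vector; `NA` marks the absorbing state.
#' @export
tissue_successor <- function() c(V = "H", H = "N", N = NA_character_)

#' Construct a run-length-encoded tissue string
#'
#' Tissue strings abstract region widths away: adjacent repeats collapse,
#' so `c("V","V","H")` becomes `V H`.
#'
#' @param symbols Character vector over `"V"`, `"H"`, `"N"`.
#' @return Character vector of class `tissue_string`.
#' @export
tissue_string <- function(symbols) {
  if (length(symbols) == 0L || !all(symbols %in% TISSUE_SYMBOLS))
    stop_hypoxiafeat("tissue strings are nonempty sequences over {V, H, N}",
                     "hypoxiafeat_input_error")
  r <- rle(symbols)$values
  structure(r, class = "tissue_string")
}

#' @export
print.tissue_string <- function(x, ...) {
  cat(paste(unclass(x), collapse = ""), "\n")
  invisible(x)
}

#' Check the spatial axiom A1
#'
#' @param s A [tissue_string()] (or plain character vector).
#' @return TRUE iff no adjacent pair of symbols is `{V, N}` in either order.
#' @export
satisfies_A1 <- function(s) {
  s <- as.character(s)
  if (length(s) < 2L) return(TRUE)
  a <- s[-length(s)]; b <- s[-1]
  !any((a == "V" & b == "N") | (a == "N" & b == "V"))
}

#' Build a production rule
#'
#' Two template shapes exist: origination `X -> X Y X` (context-free; a new
#' region of type Y appears inside an X region) and elimination
#' `X Y X -> X` (context-sensitive; a Y region enclosed in X disappears).
#'
#' @param X,Y Distinct symbols from `"V"`, `"H"`, `"N"`.
#' @param kind `"origination"` or `"elimination"`.
#' @return List of class `production_rule` with `lhs`, `rhs`, `kind`, `X`,
#'   `Y`.
#' @export
production_rule <- function(X, Y, kind = c("origination", "elimination")) {
  kind <- match.arg(kind)
  if (!X %in% TISSUE_SYMBOLS || !Y %in% TISSUE_SYMBOLS || X == Y)
    stop_hypoxiafeat("rule templates need two distinct symbols from {V, H, N}",
                     "hypoxiafeat_shape_error")
  sandwich <- c(X, Y, X)
  if (kind == "origination")
    structure(list(lhs = X, rhs = sandwich, kind = kind, X = X, Y = Y),
              class = "production_rule")
  else
    structure(list(lhs = sandwich, rhs = X, kind = kind, X = X, Y = Y),
              class = "production_rule")
}

#' @export
print.production_rule <- function(x, ...) {
  cat(sprintf("%s -> %s  (%s of %s in %s)\n",
              paste(x$lhs, collapse = " "), paste(x$rhs, collapse = " "),
              x$kind, x$Y, x$X))
  invisible(x)
}

#' Classify a production rule as valid or invalid
#'
#' Validity is derived from the axioms. An origination `X -> X Y X` is
#' valid iff Y is the temporal successor of X (A2) and the result respects
#' A1; an elimination `X Y X -> X` is valid iff X is the temporal successor
#' of Y (the enclosed region finishes its progression) and the context
#' respects A1. The attributed `reason` for an invalid rule is `"A1"` when
#' the sandwich itself places V next to N, else `"A2"`.
#'
#' @param rule A [production_rule()].
#' @return TRUE/FALSE, with attribute `reason` (`NA` for valid rules).
#' @export
is_valid_production <- function(rule) {
  if (!inherits(rule, "production_rule"))
    stop_hypoxiafeat("not a production rule", "hypoxiafeat_shape_error")
  succ <- tissue_successor()
  sandwich_ok <- satisfies_A1(c(rule$X, rule$Y, rule$X))
  a2_ok <- if (rule$kind == "origination")
    identical(succ[[rule$X]], rule$Y)
  else
    identical(succ[[rule$Y]], rule$X)
  valid <- sandwich_ok && isTRUE(a2_ok)
  reason <- if (valid) NA_character_ else if (!sandwich_ok) "A1" else "A2"
  structure(valid, reason = reason)
}

#' Enumerate all twelve template rules
#'
#' All origination and elimination templates over distinct symbol pairs
#' (6 + 6), each classified by [is_valid_production()]. Exactly four are
#' valid: `V -> VHV`, `H -> HNH`, `HVH -> H`, `NHN -> N`.
#'
#' @return Data frame with `lhs`, `rhs`, `kind`, `X`, `Y`, `valid`,
#'   `reason`, plus a `rules` attribute holding the rule objects.
#' @export
enumerate_production_rules <- function() {
  combos <- expand.grid(X = TISSUE_SYMBOLS, Y = TISSUE_SYMBOLS,
                        kind = c("origination", "elimination"),
                        stringsAsFactors = FALSE)
  combos <- combos[combos$X != combos$Y, ]
  rules <- Map(production_rule, combos$X, combos$Y, combos$kind)
  cls <- lapply(rules, is_valid_production)
  out <- data.frame(
    lhs = vapply(rules, function(r) paste(r$lhs, collapse = ""), ""),
    rhs = vapply(rules, function(r) paste(r$rhs, collapse = ""), ""),
    kind = combos$kind, X = combos$X, Y = combos$Y,
    valid = vapply(cls, function(v) as.logical(v), NA),
    reason = vapply(cls, function(v) attr(v, "reason"), ""),
    stringsAsFactors = FALSE)
  attr(out, "rules") <- rules
  rownames(out) <- NULL
  out
}

#' Apply a production rule to a tissue string
#'
#' @param s A [tissue_string()].
#' @param rule A [production_rule()].
#' @param at 1-based position in the run-length symbol sequence where the
#'   rule's left-hand side must occur.
#' @return The rewritten (re-run-length-encoded) `tissue_string`.
#' @export
apply_rule <- function(s, rule, at) {
  s <- as.character(s)
  lhs <- rule$lhs
  span <- at + length(lhs) - 1L
  if (at < 1L || span > length(s) || !identical(s[at:span], lhs))
    stop_hypoxiafeat("rule left-hand side does not occur at the given position",
                     "hypoxiafeat_application_error")
  tissue_string(c(if (at > 1L) s[seq_len(at - 1L)], rule$rhs,
                  if (span < length(s)) s[(span + 1L):length(s)]))
}

#' Tissue string along an image trajectory
#'
#' Reads tissue labels along an ordered pixel path and run-length encodes
#' them, turning a spatial trajectory (e.g. a lesion diameter) into a
#' grammar-level string such as `N H V H N`.
#'
#' @param field A `tissue_labels` matrix.
#' @param path Two-column matrix/data frame of 0-based `x`, `y` pixel
#'   coordinates, in traversal order.
#' @return A [tissue_string()].
#' @export
string_along_path <- function(field, path) {
  path <- as.matrix(path)
  tissue_string(label_at(field, path[, 1], path[, 2]))
}
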