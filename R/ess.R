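#' Payoff of a rare mutant against a resident type
#'
#' Expected objective game payoff of a single focal of type `X` whose
#' `g - 1` groupmates are all of type `Y` (the infinite-population
#' rare-mutant convention). The base payoff is excluded; it cancels in all
#' stability comparisons.
#'
#' @param X,Y Type labels (e.g. `"010"`), indices, or rows of
#'   [binary_types()].
#' @param params A [pgg_params()] object.
#' @param types Type table, defaults to the eight [binary_types()].
#' @return The expected payoff `Pi(X | Y)`.
#' @export
payoff_against_resident <- function(X, Y, params, types = binary_types()) {
  Yrow <- resolve_type(Y, types)
  comp <- integer(nrow(types))
  comp[match(Yrow$label, types$label)] <- params$g - 1L
  group_payoff(X, comp, params, types)
}

#' Evolutionary stability of one resident type
#'
#' Checks Maynard Smith's two conditions for a resident `Y` against every
#' mutant `X`: either `Pi(Y|Y) > Pi(X|Y)`, or, on a tie, `Pi(Y|X) > Pi(X|X)`.
#' Payoffs here are rational functions of `r` with small integer
#' denominators, so ties are detected with a tight tolerance.
#'
#' @param Y Resident type (label, index, or row of [binary_types()]).
#' @param params A [pgg_params()] object; stability is asserted by the
#'   theory only in the social-dilemma regime `1 < r < g`.
#' @param types Type table.
#' @param tol Tolerance for payoff ties.
#' @return A list of class `pgg_ess_verdict` with `resident`, `is_ess`,
#'   and a data.frame `violations` of mutants that pass one of the two
#'   conditions against the resident.
#' @export
is_ess <- function(Y, params, types = binary_types(), tol = 1e-12) {
  Yrow <- resolve_type(Y, types)
  p_yy <- payoff_against_resident(Yrow, Yrow, params, types)
  viol <- list()
  for (i in seq_len(nrow(types))) {
    Xrow <- types[i, , drop = FALSE]
    if (Xrow$label == Yrow$label) next
    p_xy <- payoff_against_resident(Xrow, Yrow, params, types)
    if (p_xy > p_yy + tol) {
      viol[[length(viol) + 1L]] <- data.frame(
        mutant = Xrow$label, condition = "first",
        pi_yy = p_yy, pi_xy = p_xy, pi_yx = NA_real_, pi_xx = NA_real_)
    } else if (abs(p_xy - p_yy) <= tol) {
      p_yx <- payoff_against_resident(Yrow, Xrow, params, types)
      p_xx <- payoff_against_resident(Xrow, Xrow, params, types)
      if (p_yx <= p_xx + tol) {
        viol[[length(viol) + 1L]] <- data.frame(
          mutant = Xrow$label, condition = "second",
          pi_yy = p_yy, pi_xy = p_xy, pi_yx = p_yx, pi_xx = p_xx)
      }
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(mutant = character(), condition = character(),
               pi_yy = numeric(), pi_xy = numeric(),
               pi_yx = numeric(), pi_xx = numeric())
  structure(list(resident = Yrow$label, is_ess = nrow(violations) == 0L,
                 violations = violations, params = params),
            class = "pgg_ess_verdict")
}

#' @export
print.pgg_ess_verdict <- function(x, ...) {
  cat(sprintf("Resident %s at r = %g: %s\n", x$resident, x$params$r,
              if (x$is_ess) "evolutionarily stable" else "NOT an ESS"))
  if (!x$is_ess) print(x$violations)
  invisible(x)
}

#' Scan all binary types for evolutionary stability across r
#'
#' @param g Group size.
#' @param r_values Enhancement factors to test; should lie strictly inside
#'   the dilemma regime `(1, g)` and avoid knife-edge values where payoff
#'   ties are exact.
#' @param pi0 Base payoff (cancels in the comparisons).
#' @param sociality `FALSE` restricts the scan to the four asocial types.
#' @return A list of class `pgg_ess_scan`: a verdict table (`resident`,
#'   `r`, `is_ess`, certificate mutant and condition) and the headline
#'   flag `any_ess`.
#' @export
ess_scan <- function(g = 5L, r_values = c(1.5, 2, 2.5, 3, 3.5, 4, 4.5),
                     pi0 = 1, sociality = TRUE) {
  types <- binary_types(sociality)
  rows <- list()
  for (r in r_values) {
    params <- pgg_params(g = g, r = r, pi0 = pi0, variant = "binary")
    for (i in seq_len(nrow(types))) {
      v <- is_ess(types[i, , drop = FALSE], params, types)
      cert <- if (v$is_ess) NA_character_ else v$violations$mutant[1L]
      cond <- if (v$is_ess) NA_character_ else v$violations$condition[1L]
      rows[[length(rows) + 1L]] <- data.frame(
        r = r, resident = types$label[i], is_ess = v$is_ess,
        certificate_mutant = cert, condition = cond)
    }
  }
  tab <- do.call(rbind, rows)
  structure(list(verdicts = tab, any_ess = any(tab$is_ess), g = g),
            class = "pgg_ess_scan")
}

#' @export
print.pgg_ess_scan <- function(x, ...) {
  cat(sprintf("ESS scan, g = %d, %d (r, resident) pairs: %s\n",
              x$g, nrow(x$verdicts),
              if (x$any_ess) "ESS found" else "no ESS anywhere on the grid"))
  invisible(x)
}

#' Pairwise invasion structure of the binary types
#'
#' Edge `X -> Y` means a rare `X` mutant invades a `Y` resident:
#' `Pi(X|Y) > Pi(Y|Y)`, or equality with `Pi(X|X) > Pi(Y|X)`.
#'
#' @param params A [pgg_params()] object.
#' @param types Type table.
#' @param tol Tolerance for ties.
#' @return A logical matrix `inv` with `inv[X, Y]` = `X` invades `Y`.
#' @export
invasion_matrix <- function(params, types = binary_types(), tol = 1e-12) {
  n <- nrow(types)
  P <- matrix(0, n, n, dimnames = list(types$label, types$label))
  for (i in seq_len(n)) for (j in seq_len(n))
    P[i, j] <- payoff_against_resident(types[i, , drop = FALSE],
                                       types[j, , drop = FALSE], params, types)
  inv <- matrix(FALSE, n, n, dimnames = dimnames(P))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (P[i, j] > P[j, j] + tol) inv[i, j] <- TRUE
    else if (abs(P[i, j] - P[j, j]) <= tol && P[i, i] > P[j, i] + tol)
      inv[i, j] <- TRUE
  }
  attr(inv, "payoffs") <- P
  inv
}
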