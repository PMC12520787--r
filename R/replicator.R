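#' The binary rationality types
#'
#' In the binary-trait model each agent is one of eight types `(c, b, s)`
#' with perceived cost, perceived benefit and sociality each 0 or 1. The
#' four economic perceptions are Neutral (c = 0, b = 0), Harmony (0, 1),
#' Anti-harmony (1, 0) and Public good (1, 1), each either asocial (s = 0)
#' or social (s = 1). Dropping sociality gives the four-type reduction.
#'
#' @param sociality If `FALSE`, return the four `(c, b)` types of the
#'   model without a social trait.
#' @return A data.frame with columns `c`, `b` (and `s`), `label` and the
#'   economic-perception `name`.
#' @export
binary_types <- function(sociality = TRUE) {
  econ <- c("00" = "Neutral", "01" = "Harmony",
            "10" = "Anti-harmony", "11" = "Public good")
  if (sociality) {
    tt <- expand.grid(s = 0:1, b = 0:1, c = 0:1)[, c("c", "b", "s")]
    tt$label <- paste0(tt$c, tt$b, tt$s)
  } else {
    tt <- expand.grid(b = 0:1, c = 0:1)[, c("c", "b")]
    tt$label <- paste0(tt$c, tt$b)
  }
  tt$name <- econ[paste0(tt$c, tt$b)]
  rownames(tt) <- tt$label
  tt
}

#' Trait-wise mutation kernel
#'
#' Mutations change each binary trait independently with probability `nu`,
#' so the probability that a parent of type `x'` yields an offspring of
#' type `x` at Hamming distance `k` is `nu^k * (1 - nu)^(n_traits - k)`.
#' The diagonal is `(1 - nu)^n_traits`, i.e. `1 - 3 nu + 3 nu^2 - nu^3`
#' for three traits.
#'
#' @param nu Per-trait mutation probability in `[0, 1]`.
#' @param n_traits Number of binary traits (3, or 2 for the no-sociality
#'   reduction).
#' @return An `2^n_traits` square matrix whose entry `[x, x']` is the
#'   probability that a parent of type `x'` produces an offspring of type
#'   `x`; every column sums to 1.
#' @export
mutation_kernel <- function(nu, n_traits = 3L) {
  if (nu < 0 || nu > 1) stop("nu must lie in [0, 1]", call. = FALSE)
  n_types <- 2L^n_traits
  bits <- as.matrix(expand.grid(rep(list(0:1), n_traits)))[, n_traits:1, drop = FALSE]
  ham <- matrix(0L, n_types, n_types)
  for (k in seq_len(n_traits))
    ham <- ham + outer(bits[, k], bits[, k], FUN = function(a, b) as.integer(a != b))
  K <- nu^ham * (1 - nu)^(n_traits - ham)
  K
}

# all weak compositions of n into k parts, as a (choose(n+k-1, k-1) x k) matrix
compositions_of <- function(n, k) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  out <- vector("list", n + 1L)
  for (first in 0:n) {
    rest <- compositions_of(n - first, k - 1L)
    out[[first + 1L]] <- cbind(first, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

# cooperation probability of every member position in a binary-type group:
# focal of type `type` (row of binary_types()) with `comp` groupmates
binary_group_probs <- function(type, comp, params, types) {
  g <- params$g
  if (sum(comp) != g - 1L)
    stop(sprintf("composition must sum to g - 1 = %d", g - 1L), call. = FALSE)
  has_s <- "s" %in% names(types)
  # integer counts of c = 1 and b = 1 in the whole group (focal included)
  n_c1 <- sum(comp * types$c) + type$c
  n_b1 <- sum(comp * types$b) + type$b
  member_prob <- function(c, b, s) {
    # social members act on the group average including themselves; the
    # sign of b_eff - c_eff equals the sign of the integer n_b1 - n_c1
    net_num <- if (has_s && s == 1) n_b1 - n_c1 else b - c
    as.numeric(net_num > 0) + 0.5 * (net_num == 0)
  }
  p_focal <- member_prob(type$c, type$b, if (has_s) type$s else 0)
  p_types <- vapply(seq_len(nrow(types)), function(i)
    member_prob(types$c[i], types$b[i], if (has_s) types$s[i] else 0),
    numeric(1))
  list(p_focal = p_focal, p_types = p_types,
       p_sum = p_focal + sum(comp * p_types))
}

#' Expected payoff of a focal type in a fixed group composition
#'
#' Resolves the subjective Nash equilibrium of a `g`-member binary-trait
#' group (one focal of type `focal`, plus `comp[x]` members of each type
#' `x`), averaging uniformly over all equilibria when members are
#' indifferent, and returns the focal member's expected *objective* game
#' payoff. The base payoff `pi0` is not included; it is added at the
#' dynamics level.
#'
#' @param focal Focal type: a label like `"010"`, an index, or a row of
#'   [binary_types()].
#' @param comp Integer vector of groupmate counts over the types, summing
#'   to `g - 1`.
#' @param params A [pgg_params()] object (the variant is ignored; play is
#'   binary by construction).
#' @param types Type table, defaults to the eight [binary_types()].
#' @return Expected objective payoff of the focal member.
#' @export
group_payoff <- function(focal, comp, params, types = binary_types()) {
  type <- resolve_type(focal, types)
  pr <- binary_group_probs(type, comp, params, types)
  # E[payoff] = r * E[nC] / g - P(focal cooperates), by linearity
  params$r * pr$p_sum / params$g - pr$p_focal
}

resolve_type <- function(x, types) {
  if (is.data.frame(x)) return(x[1, , drop = FALSE])
  if (is.character(x)) {
    i <- match(x, types$label)
    if (is.na(i)) stop("unknown type label: ", x, call. = FALSE)
    return(types[i, , drop = FALSE])
  }
  types[x, , drop = FALSE]
}

#' Precompute the exact group-composition tables for the replicator map
#'
#' Enumerates every composition of `g - 1` groupmates over the types and
#' caches, per focal type, the focal's expected objective payoff and
#' cooperation probability together with the multinomial coefficients.
#' These are independent of the type frequencies, so the per-step cost of
#' the replicator map reduces to reweighting the cached tables.
#'
#' @param params A [pgg_params()] object.
#' @param sociality `FALSE` selects the four-type no-sociality reduction.
#' @return A list used by [expected_type_payoffs()] and friends.
#' @export
replicator_cache <- function(params, sociality = TRUE) {
  types <- binary_types(sociality)
  n_types <- nrow(types)
  comps <- compositions_of(params$g - 1L, n_types)
  n_comp <- nrow(comps)
  log_mult <- lfactorial(params$g - 1L) - rowSums(lfactorial(comps))
  pay <- matrix(0, n_types, n_comp)
  coop <- matrix(0, n_types, n_comp)
  for (x in seq_len(n_types)) {
    tx <- types[x, , drop = FALSE]
    for (j in seq_len(n_comp)) {
      pr <- binary_group_probs(tx, comps[j, ], params, types)
      pay[x, j] <- params$r * pr$p_sum / params$g - pr$p_focal
      coop[x, j] <- pr$p_focal
    }
  }
  list(params = params, types = types, comps = comps, log_mult = log_mult,
       payoff = pay, coop = coop)
}

comp_weights <- function(rho, cache) {
  lr <- log(rho)
  lr[rho == 0] <- -1e6  # exact zero after exponentiation unless exponent is 0
  w <- exp(cache$log_mult + as.vector(cache$comps %*% lr))
  w
}

#' Expected payoffs of all binary types under random group formation
#'
#' Implements the exact multinomial average of the focal payoff over all
#' group compositions drawn from the type-frequency vector `rho`; the base
#' payoff `pi0` is included so all expected payoffs are positive.
#'
#' @param rho Frequency vector over the types (non-negative, sums to 1).
#' @param params A [pgg_params()] object.
#' @param cache Optional [replicator_cache()]; built on the fly if missing.
#' @return Named vector of expected payoffs, one per type.
#' @export
expected_type_payoffs <- function(rho, params, cache = NULL) {
  if (is.null(cache)) cache <- replicator_cache(params, sociality = length(rho) == 8L)
  stopifnot(length(rho) == nrow(cache$types))
  w <- comp_weights(rho, cache)
  out <- as.vector(cache$payoff %*% w) + params$pi0
  names(out) <- cache$types$label
  out
}

#' Expected cooperation frequency under a type distribution
#'
#' Probability that a randomly drawn individual cooperates when groups are
#' formed at random from `rho`, with indifferent members counted as
#' cooperating with probability 1/2.
#'
#' @inheritParams expected_type_payoffs
#' @return A single probability.
#' @export
expected_cooperation <- function(rho, params, cache = NULL) {
  if (is.null(cache)) cache <- replicator_cache(params, sociality = length(rho) == 8L)
  w <- comp_weights(rho, cache)
  sum(rho * as.vector(cache$coop %*% w))
}

#' One step of the discrete replicator-mutator map
#'
#' Types reproduce in proportion to frequency times expected payoff
#' (including the base payoff), offspring are redistributed by the mutation
#' kernel, and the result is renormalized on the simplex.
#'
#' @param rho Current frequency vector.
#' @param params A [pgg_params()] object.
#' @param nu Per-trait mutation probability.
#' @param cache Optional [replicator_cache()].
#' @param kernel Optional precomputed [mutation_kernel()].
#' @return The next frequency vector.
#' @export
replicator_step <- function(rho, params, nu, cache = NULL, kernel = NULL) {
  if (is.null(cache)) cache <- replicator_cache(params, sociality = length(rho) == 8L)
  if (is.null(kernel)) kernel <- mutation_kernel(nu, log2(length(rho)))
  pibar <- expected_type_payoffs(rho, params, cache)
  if (any(pibar <= 0)) stop("expected payoffs must be positive", call. = FALSE)
  w <- rho * pibar
  out <- as.vector(kernel %*% w) / sum(w)
  stats::setNames(out / sum(out), names(pibar))
}

#' Iterate the replicator-mutator dynamics
#'
#' @param rho0 Initial frequency vector; `"uniform"` for equal frequencies
#'   (the homogeneous initial condition), or a numeric vector on the
#'   simplex.
#' @param steps Number of steps.
#' @param params A [pgg_params()] object.
#' @param nu Per-trait mutation probability.
#' @param sociality `FALSE` for the four-type reduction.
#' @return An object of class `pgg_replicator` with the frequency
#'   trajectory (`steps + 1` rows), expected cooperation and sociality per
#'   step.
#' @export
replicator_run <- function(rho0 = "uniform", steps, params, nu,
                           sociality = TRUE) {
  cache <- replicator_cache(params, sociality)
  n_types <- nrow(cache$types)
  kernel <- mutation_kernel(nu, as.integer(log2(n_types)))
  if (identical(rho0, "uniform")) rho0 <- rep(1 / n_types, n_types)
  stopifnot(length(rho0) == n_types, abs(sum(rho0) - 1) < 1e-9, all(rho0 >= 0))
  traj <- matrix(NA_real_, steps + 1L, n_types,
                 dimnames = list(NULL, cache$types$label))
  coop <- numeric(steps + 1L)
  rho <- rho0 / sum(rho0)
  traj[1L, ] <- rho
  coop[1L] <- expected_cooperation(rho, params, cache)
  if (steps > 0) for (t in seq_len(steps)) {
    rho <- replicator_step(rho, params, nu, cache, kernel)
    traj[t + 1L, ] <- rho
    coop[t + 1L] <- expected_cooperation(rho, params, cache)
  }
  social <- if ("s" %in% names(cache$types))
    as.vector(traj %*% cache$types$s) else rep(0, steps + 1L)
  structure(list(rho = traj, cooperation = coop, sociality = social,
                 params = params, nu = nu, types = cache$types),
            class = "pgg_replicator")
}

#' @export
print.pgg_replicator <- function(x, ...) {
  n <- nrow(x$rho)
  cat(sprintf("Replicator-mutator trajectory: %d types, %d steps (g = %d, r = %g, nu = %g)\n",
              ncol(x$rho), n - 1L, x$params$g, x$params$r, x$nu))
  cat(sprintf("final cooperation %.4f, sociality %.4f\n",
              x$cooperation[n], x$sociality[n]))
  invisible(x)
}

#' @export
as.data.frame.pgg_replicator <- function(x, ...) {
  data.frame(step = seq_len(nrow(x$rho)) - 1L, x$rho,
             cooperation = x$cooperation, sociality = x$sociality,
             check.names = FALSE)
}
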