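#' Public goods game parameters
#'
#' Bundles the parameters of a single public goods game among perceptually
#' rational agents. Cooperators pay a unit cost into a common pool; the pool
#' is multiplied by the enhancement factor `r` and shared equally among the
#' `g` group members, so the objective per-capita return of one contribution
#' is `r/g`. A social dilemma exists for `1 < r < g`.
#'
#' @param g Group size (integer, at least 3).
#' @param r Enhancement factor (typically `1 < r <= g`).
#' @param pi0 Base payoff added to the game payoff before reproduction;
#'   must satisfy `pi0 + r/g - 1 > 0` so that fitness stays positive even
#'   for a lone cooperator.
#' @param variant Model variant. `"simple"`: private perceptions
#'   `c_hat, b_hat` in `[0,1]`, no sociality. `"social"`: additionally a
#'   sociality trait `s` in `[0,1]` blending private perception with the
#'   groupmates' average. `"binary"`: all three traits in `{0,1}`, social
#'   agents average over the whole group including themselves.
#'   `"cost_only"` / `"benefit_only"`: social variant with one perception
#'   pinned to its objective value (cost 1, benefit `r/g`) and the other
#'   evolvable in `[0,2]`.
#' @return An object of class `pgg_params`.
#' @export
pgg_params <- function(g = 5L, r, pi0 = 1,
                       variant = c("simple", "social", "binary",
                                   "cost_only", "benefit_only")) {
  variant <- match.arg(variant)
  g <- as.integer(g)
  if (is.na(g) || g < 3L)
    stop("group size g must be an integer >= 3", call. = FALSE)
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r))
    stop("r must be a finite number", call. = FALSE)
  if (pi0 + r / g - 1 <= 0)
    stop("pi0 + r/g - 1 must be positive so reproduction weights stay positive",
         call. = FALSE)
  structure(list(g = g, r = r, pi0 = pi0, variant = variant),
            class = "pgg_params")
}

#' @export
print.pgg_params <- function(x, ...) {
  cat(sprintf("Perceptual public goods game: g = %d, r = %g, pi0 = %g, variant = %s\n",
              x$g, x$r, x$pi0, x$variant))
  invisible(x)
}

#' Agent trait bundle
#'
#' @param c_hat Perceived personal cost of contributing.
#' @param b_hat Perceived per-capita benefit of the public good.
#' @param s Sociality: weight on the group's perception when forming the
#'   perception the agent acts on (0 = fully private, 1 = fully collective).
#' @return A data.frame with one row per agent and columns
#'   `c_hat`, `b_hat`, `s`.
#' @export
agent_traits <- function(c_hat, b_hat, s = 0) {
  n <- max(length(c_hat), length(b_hat), length(s))
  data.frame(c_hat = rep_len(c_hat, n),
             b_hat = rep_len(b_hat, n),
             s = rep_len(s, n))
}

trait_bounds <- function(params) {
  switch(params$variant,
         simple = ,
         social = ,
         binary = c(0, 1),
         cost_only = ,
         benefit_only = c(0, 2))
}

check_trait_domain <- function(traits, params) {
  v <- params$variant
  bounds <- trait_bounds(params)
  if (v == "binary") {
    ok <- all(traits$c_hat %in% c(0, 1)) && all(traits$b_hat %in% c(0, 1)) &&
      all(traits$s %in% c(0, 1))
    if (!ok) stop("binary variant requires traits in {0, 1}", call. = FALSE)
  } else {
    evolv <- switch(v,
                    cost_only = traits$c_hat,
                    benefit_only = traits$b_hat,
                    c(traits$c_hat, traits$b_hat))
    if (any(evolv < bounds[1] | evolv > bounds[2]))
      stop(sprintf("traits outside [%g, %g] for variant '%s'",
                   bounds[1], bounds[2], v), call. = FALSE)
    if (any(traits$s < 0 | traits$s > 1))
      stop("sociality must lie in [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Socially effective perception of a focal agent
#'
#' Computes the cost and benefit perception an agent actually acts on. In
#' the continuous variants the agent blends its private perception with the
#' average perception of its `g - 1` groupmates, weighted by its sociality:
#' `c_eff = (1 - s) * c_hat + s * mean(others' c_hat)` and likewise for the
#' benefit. In the binary variant a social agent (`s = 1`) adopts the plain
#' average over the whole group *including itself*, while an asocial agent
#' (`s = 0`) keeps its private perception.
#'
#' @param focal One-row data.frame of the focal agent's traits
#'   (see [agent_traits()]).
#' @param group Traits of the other `g - 1` group members for continuous
#'   variants; for the binary variant, the full group of `g` members
#'   including the focal agent.
#' @param params A [pgg_params()] object.
#' @return A list with `c_eff`, `b_eff` and `net = b_eff - c_eff` (the
#'   perceived payoff difference between cooperating and defecting).
#' @export
effective_perception <- function(focal, group, params) {
  g <- params$g
  if (params$variant == "binary") {
    if (nrow(group) != g)
      stop(sprintf("binary variant expects the full group of %d members", g),
           call. = FALSE)
    check_trait_domain(group, params)
    if (focal$s == 1) {
      c_eff <- sum(group$c_hat) / g
      b_eff <- sum(group$b_hat) / g
    } else {
      c_eff <- focal$c_hat
      b_eff <- focal$b_hat
    }
  } else {
    if (nrow(group) != g - 1L)
      stop(sprintf("expected %d groupmates, got %d", g - 1L, nrow(group)),
           call. = FALSE)
    check_trait_domain(rbind(focal, group), params)
    s <- if (params$variant == "simple") 0 else focal$s
    c_eff <- (1 - s) * focal$c_hat + s * mean(group$c_hat)
    b_eff <- (1 - s) * focal$b_hat + s * mean(group$b_hat)
  }
  list(c_eff = c_eff, b_eff = b_eff, net = b_eff - c_eff)
}

#' Rational decision from a perceived payoff difference
#'
#' A perceptually rational agent cooperates when the perceived payoff of
#' cooperation exceeds that of defection (`net > 0`), defects when it is
#' lower, and randomizes with probability 1/2 when indifferent (`net = 0`,
#' the default tie rule), since both actions are then best responses.
#'
#' @param net Perceived cooperate-minus-defect payoff difference(s).
#' @param tie_rule How to resolve indifference: `"randomize"` (default),
#'   `"cooperate"`, or `"defect"`.
#' @return Character vector of actions, `"C"` or `"D"`.
#' @export
decide <- function(net, tie_rule = c("randomize", "cooperate", "defect")) {
  tie_rule <- match.arg(tie_rule)
  if (any(is.na(net)))
    stop("net perceived payoff must not be NA/NaN", call. = FALSE)
  out <- ifelse(net > 0, "C", "D")
  tie <- net == 0
  if (any(tie)) {
    out[tie] <- switch(tie_rule,
                       randomize = ifelse(stats::runif(sum(tie)) < 0.5, "C", "D"),
                       cooperate = "C",
                       defect = "D")
  }
  out
}

#' Objective public goods payoffs for an action profile
#'
#' Each cooperator pays a unit cost; all contributions are multiplied by
#' `r` and shared equally, so member `i` receives `r * nC / g - [i cooperates]`
#' where `nC` is the number of cooperators in the whole group. The base
#' payoff `pi0` is *not* included here.
#'
#' @param actions Character vector of `g` actions (`"C"`/`"D"`).
#' @param params A [pgg_params()] object.
#' @return Numeric vector of `g` objective payoffs.
#' @export
objective_payoffs <- function(actions, params) {
  if (length(actions) != params$g)
    stop(sprintf("expected %d actions, got %d", params$g, length(actions)),
         call. = FALSE)
  coop <- actions == "C"
  n_c <- sum(coop)
  params$r * n_c / params$g - as.numeric(coop)
}

#' Perceived payoff ("happiness") of one agent
#'
#' The subjective gain from the game, evaluated with the perceptions the
#' agent acts on: `[action == C] * (b_eff - c_eff) + n_C_others * b_eff`.
#'
#' @param action `"C"` or `"D"`.
#' @param n_c_others Number of *other* group members who cooperate.
#' @param ep Effective perception, as returned by [effective_perception()].
#' @return The perceived payoff.
#' @export
perceived_payoff <- function(action, n_c_others, ep) {
  if (n_c_others < 0)
    stop("n_c_others must be non-negative", call. = FALSE)
  as.numeric(action == "C") * (ep$b_eff - ep$c_eff) + n_c_others * ep$b_eff
}

group_coop_probs <- function(members, params) {
  # per-member cooperation probability at the subjective Nash equilibrium;
  # the perceived C-minus-D difference never depends on others' actions, so
  # the equilibrium factorizes: strict sign -> pure best response,
  # indifference -> both actions are equilibria (prob 1/2 under uniform
  # averaging over the equilibrium set)
  g <- params$g
  if (nrow(members) != g)
    stop(sprintf("expected %d group members, got %d", g, nrow(members)),
         call. = FALSE)
  check_trait_domain(members, params)
  v <- params$variant
  if (v == "binary") {
    mc <- sum(members$c_hat) / g
    mb <- sum(members$b_hat) / g
    c_eff <- ifelse(members$s == 1, mc, members$c_hat)
    b_eff <- ifelse(members$s == 1, mb, members$b_hat)
  } else {
    s <- if (v == "simple") rep(0, g) else members$s
    others_c <- (sum(members$c_hat) - members$c_hat) / (g - 1)
    others_b <- (sum(members$b_hat) - members$b_hat) / (g - 1)
    c_eff <- (1 - s) * members$c_hat + s * others_c
    b_eff <- (1 - s) * members$b_hat + s * others_b
  }
  net <- b_eff - c_eff
  list(p = as.numeric(net > 0) + 0.5 * (net == 0),
       c_eff = c_eff, b_eff = b_eff, net = net)
}

#' Play one group at the subjective Nash equilibrium
#'
#' Resolves the subjective Nash equilibrium of a single group. Because an
#' agent's perceived payoff difference between cooperation and defection is
#' independent of what others do, the equilibrium factorizes over members:
#' agents with a strict perceived preference play it, indifferent agents can
#' play either action. In `exact` mode the outcome is averaged uniformly
#' over the whole equilibrium set (equivalently, indifferent members
#' cooperate independently with probability 1/2); otherwise one equilibrium
#' is sampled.
#'
#' @param members Traits of the `g` group members (see [agent_traits()]).
#' @param params A [pgg_params()] object.
#' @param exact If `TRUE`, return expected actions and payoffs under uniform
#'   averaging over all Nash equilibria; if `FALSE` (default), sample.
#' @return A list of class `pgg_group_outcome` with elements
#'   `actions` (sampled mode), `coop_prob`, `objective_payoffs`,
#'   `perceived_payoffs` and `n_cooperators` (expected in exact mode).
#' @export
nash_play_group <- function(members, params, exact = FALSE) {
  g <- params$g
  eq <- group_coop_probs(members, params)
  p <- eq$p
  if (exact) {
    # expectation is exact by linearity of both payoffs in action indicators
    n_c <- sum(p)
    obj <- params$r * n_c / g - p
    perc <- p * eq$net + (n_c - p) * eq$b_eff
    out <- list(actions = NULL, coop_prob = p, n_cooperators = n_c,
                objective_payoffs = obj, perceived_payoffs = perc)
  } else {
    coop <- stats::runif(g) < p
    n_c <- sum(coop)
    obj <- params$r * n_c / g - as.numeric(coop)
    perc <- as.numeric(coop) * eq$net + (n_c - as.numeric(coop)) * eq$b_eff
    out <- list(actions = ifelse(coop, "C", "D"), coop_prob = p,
                n_cooperators = n_c, objective_payoffs = obj,
                perceived_payoffs = perc)
  }
  class(out) <- "pgg_group_outcome"
  out
}
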