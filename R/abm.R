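#' Simulation configuration for the agent-based model
#'
#' @param N Population size (divisible by the group size for well-mixed
#'   runs; equal to `L^2` on the lattice).
#' @param generations Number of non-overlapping generations to run.
#' @param nu Per-trait mutation probability per reproduction event.
#' @param topology `"wellmixed"` (random groups of `g` each generation) or
#'   `"lattice"` (periodic square lattice, von Neumann neighbourhoods, one
#'   game centred on every site).
#' @param L Lattice linear dimension (required for `topology = "lattice"`).
#' @param fitness_map `"linear"` (fitness = `pi0` + game payoff, the
#'   default) or `"exponential"` (fitness = `exp(payoff)`, exposed as an
#'   optional alternative reproduction weighting).
#' @param record_every Record observables every this many generations ...
#' @param burn_in ... once at least this many generations have been played.
#' @param track_species Track lineages ("species"): a mutation in a tracked
#'   trait founds a new species.
#' @param species_log Also keep the full per-generation long table of
#'   species population sizes (memory-heavy; small runs only).
#' @param snapshots Store trait vectors at every recorded generation.
#' @param record_actions Store the per-agent action vector at every
#'   recorded generation.
#' @param decision_rule `"rational"`: agents play the Nash equilibrium of
#'   their perceived game each time they play. `"fixed_at_birth"`: each
#'   agent's action is frozen at birth from its traits (the
#'   bounded-rationality relabelling of the simple variant, where the two
#'   coincide).
#' @param seed Optional integer seed set by [run_abm()].
#' @param verbose Print progress every 1000 generations.
#' @return An object of class `pgg_sim_config`.
#' @export
sim_config <- function(N = 10000L, generations, nu = 1e-3,
                       topology = c("wellmixed", "lattice"), L = NULL,
                       fitness_map = c("linear", "exponential"),
                       record_every = 10L, burn_in = 0L,
                       track_species = FALSE, species_log = FALSE,
                       snapshots = FALSE, record_actions = FALSE,
                       decision_rule = c("rational", "fixed_at_birth"),
                       seed = NULL, verbose = FALSE) {
  topology <- match.arg(topology)
  fitness_map <- match.arg(fitness_map)
  decision_rule <- match.arg(decision_rule)
  if (nu < 0 || nu > 1) stop("nu must lie in [0, 1]", call. = FALSE)
  if (topology == "lattice") {
    if (is.null(L)) L <- as.integer(round(sqrt(N)))
    if (L * L != N) stop("lattice requires N = L^2", call. = FALSE)
  }
  structure(list(N = as.integer(N), generations = as.integer(generations),
                 nu = nu, topology = topology, L = L,
                 fitness_map = fitness_map,
                 record_every = as.integer(record_every),
                 burn_in = as.integer(burn_in),
                 track_species = isTRUE(track_species),
                 species_log = isTRUE(species_log),
                 snapshots = isTRUE(snapshots),
                 record_actions = isTRUE(record_actions),
                 decision_rule = decision_rule,
                 seed = seed, verbose = isTRUE(verbose)),
            class = "pgg_sim_config")
}

evolvable_traits <- function(params) {
  switch(params$variant,
         simple = c("c_hat", "b_hat"),
         social = ,
         binary = c("c_hat", "b_hat", "s"),
         cost_only = c("c_hat", "s"),
         benefit_only = c("b_hat", "s"))
}

# lineages are keyed on the perceived-benefit trait in the simple variant
# and on the full evolvable trait tuple otherwise
species_traits <- function(params) {
  if (params$variant == "simple") "b_hat" else evolvable_traits(params)
}

#' Initial population: the hardest starting point for cooperation
#'
#' Every agent starts with zero perceived benefit, an independently uniform
#' perceived cost on the admissible interval, and (where present) zero
#' sociality. Each initial agent is its own lineage root.
#'
#' @param config A [sim_config()] object.
#' @param params A [pgg_params()] object.
#' @return An object of class `pgg_population`.
#' @export
init_population <- function(config, params) {
  N <- config$N
  if (config$topology == "wellmixed" && N %% params$g != 0L)
    stop("N must be divisible by g in a well-mixed population", call. = FALSE)
  v <- params$variant
  c_hat <- switch(v,
                  binary = as.numeric(stats::runif(N) < 0.5),
                  benefit_only = rep(1, N),
                  cost_only = stats::runif(N, 0, 2),
                  stats::runif(N))
  b_hat <- if (v == "cost_only") rep(params$r / params$g, N) else rep(0, N)
  s <- rep(0, N)
  pop <- list(c_hat = c_hat, b_hat = b_hat, s = s,
              species = seq_len(N), next_species = N + 1L,
              generation = 0L)
  class(pop) <- "pgg_population"
  pop
}

#' @export
print.pgg_population <- function(x, ...) {
  cat(sprintf("Population of %d agents at generation %d (%d species present)\n",
              length(x$c_hat), x$generation, length(unique(x$species))))
  invisible(x)
}

# vectorized cooperation probabilities for consecutive groups of g agents
# (after permutation); returns per-agent net and cooperation probability
wellmixed_nets <- function(c_hat, b_hat, s, gid, g, variant) {
  if (variant == "simple") return(b_hat - c_hat)
  gs_c <- as.vector(rowsum.default(c_hat, gid, reorder = FALSE))
  gs_b <- as.vector(rowsum.default(b_hat, gid, reorder = FALSE))
  if (variant == "binary") {
    c_eff <- ifelse(s == 1, gs_c[gid] / g, c_hat)
    b_eff <- ifelse(s == 1, gs_b[gid] / g, b_hat)
  } else {
    c_eff <- (1 - s) * c_hat + s * (gs_c[gid] - c_hat) / (g - 1)
    b_eff <- (1 - s) * b_hat + s * (gs_b[gid] - b_hat) / (g - 1)
  }
  attr_net <- b_eff - c_eff
  attr(attr_net, "b_eff") <- b_eff
  attr_net
}

draw_actions <- function(net) {
  coop <- net > 0
  tie <- which(net == 0)
  if (length(tie)) coop[tie] <- stats::runif(length(tie)) < 0.5
  coop
}

mutate_vector <- function(x, nu, interval, binary = FALSE) {
  n <- length(x)
  idx <- which(stats::runif(n) < nu)
  if (length(idx)) {
    x[idx] <- if (binary) as.numeric(stats::runif(length(idx)) < 0.5)
              else stats::runif(length(idx), interval[1], interval[2])
  }
  list(x = x, mutated = idx)
}

#' Mutate agent traits
#'
#' Each evolvable trait is independently redrawn uniformly on its
#' admissible interval with probability `nu`; fixed traits (the pinned
#' cost or benefit of the `cost_only`/`benefit_only` variants) are never
#' touched.
#'
#' @param traits A data.frame of agent traits (see [agent_traits()]).
#' @param nu Per-trait mutation probability.
#' @param params A [pgg_params()] object.
#' @return A data.frame of mutated traits with attribute `"mutated"`, the
#'   indices of agents whose tracked traits changed identity.
#' @export
mutate <- function(traits, nu, params) {
  ev <- evolvable_traits(params)
  binary <- params$variant == "binary"
  bounds <- trait_bounds(params)
  mutated <- integer(0)
  for (tr in ev) {
    m <- mutate_vector(traits[[tr]], nu, bounds, binary)
    traits[[tr]] <- m$x
    mutated <- union(mutated, m$mutated)
  }
  attr(traits, "mutated") <- sort(mutated)
  traits
}

# one generation: play, reproduce, mutate; returns list(pop, play) where
# play summarizes the generation that was just played
step_wellmixed <- function(pop, config, params) {
  N <- config$N
  g <- params$g
  idx <- sample.int(N)
  n_groups <- N %/% g
  gid <- rep.int(seq_len(n_groups), rep.int(g, n_groups))
  c_hat <- pop$c_hat[idx]; b_hat <- pop$b_hat[idx]; s <- pop$s[idx]
  if (config$decision_rule == "fixed_at_birth" && !is.null(pop$strategy)) {
    net <- wellmixed_nets(c_hat, b_hat, s, gid, g, params$variant)
    coop <- pop$strategy[idx]
    tie <- which(net == 0)  # keep RNG stream aligned with rational play
    if (length(tie)) stats::runif(length(tie))
  } else {
    net <- wellmixed_nets(c_hat, b_hat, s, gid, g, params$variant)
    coop <- draw_actions(net)
  }
  b_eff <- attr(net, "b_eff")
  if (is.null(b_eff)) b_eff <- b_hat
  n_c <- as.vector(rowsum.default(as.numeric(coop), gid, reorder = FALSE))
  pay <- params$r * n_c[gid] / g - as.numeric(coop)
  happy <- as.numeric(coop) * as.numeric(net) +
    (n_c[gid] - as.numeric(coop)) * b_eff
  fitness <- if (config$fitness_map == "linear") params$pi0 + pay else exp(pay)
  parents <- idx[sample.int(N, N, replace = TRUE, prob = fitness)]
  play <- list(cooperation = mean(coop),
               mean_payoff = mean(pay),
               mean_happiness = mean(happy),
               actions = if (config$record_actions) {
                 a <- logical(N); a[idx] <- coop; a
               } else NULL)
  pop2 <- inherit_and_mutate(pop, parents, config, params)
  list(pop = pop2, play = play)
}

inherit_and_mutate <- function(pop, parents, config, params) {
  traits <- data.frame(c_hat = pop$c_hat[parents],
                       b_hat = pop$b_hat[parents],
                       s = pop$s[parents])
  traits <- mutate(traits, config$nu, params)
  mutated <- attr(traits, "mutated")
  # species identity is lineage-based: a mutation in a *tracked* trait
  # founds a new species even if the value coincides with an existing one
  sp_tr <- species_traits(params)
  old <- data.frame(c_hat = pop$c_hat[parents], b_hat = pop$b_hat[parents],
                    s = pop$s[parents])
  changed <- rep(FALSE, length(parents))
  for (tr in sp_tr) changed <- changed | (traits[[tr]] != old[[tr]])
  changed_idx <- which(changed)
  species <- pop$species[parents]
  next_id <- pop$next_species
  if (length(changed_idx)) {
    species[changed_idx] <- next_id + seq_along(changed_idx) - 1L
    next_id <- next_id + length(changed_idx)
  }
  pop2 <- list(c_hat = traits$c_hat, b_hat = traits$b_hat, s = traits$s,
               species = species, next_species = next_id,
               generation = pop$generation + 1L)
  if (config$decision_rule == "fixed_at_birth")
    pop2$strategy <- strategy_at_birth(pop2, config, params)
  class(pop2) <- "pgg_population"
  pop2
}

strategy_at_birth <- function(pop, config, params) {
  # the behavioural phenotype frozen at birth; for the simple variant this
  # is the full decision rule (actions never depend on the group)
  net <- pop$b_hat - pop$c_hat
  strat <- net > 0
  tie <- which(net == 0)
  if (length(tie)) strat[tie] <- stats::runif(length(tie)) < 0.5
  strat
}

lattice_neighbors <- function(L) {
  N <- L * L
  i <- seq_len(N) - 1L
  row <- i %/% L
  col <- i %% L
  up    <- ((row - 1L) %% L) * L + col + 1L
  down  <- ((row + 1L) %% L) * L + col + 1L
  left  <- row * L + (col - 1L) %% L + 1L
  right <- row * L + (col + 1L) %% L + 1L
  cbind(seq_len(N), up, down, left, right, deparse.level = 0)
}

step_lattice <- function(pop, config, params, nb) {
  N <- config$N
  g <- params$g  # 5: the site plus its four von Neumann neighbours
  M <- nb        # N x 5 membership matrix of the game centred on each site
  cM <- matrix(pop$c_hat[M], nrow = N)
  bM <- matrix(pop$b_hat[M], nrow = N)
  sM <- matrix(pop$s[M], nrow = N)
  if (params$variant == "simple") {
    net <- bM - cM
    b_eff <- bM
  } else if (params$variant == "binary") {
    mc <- rowSums(cM) / g
    mb <- rowSums(bM) / g
    c_eff <- (1 - sM) * cM + sM * mc
    b_eff <- (1 - sM) * bM + sM * mb
    net <- b_eff - c_eff
  } else {
    oc <- (rowSums(cM) - cM) / (g - 1)
    ob <- (rowSums(bM) - bM) / (g - 1)
    c_eff <- (1 - sM) * cM + sM * oc
    b_eff <- (1 - sM) * bM + sM * ob
    net <- b_eff - c_eff
  }
  if (config$decision_rule == "fixed_at_birth" && !is.null(pop$strategy)) {
    coop <- matrix(pop$strategy[M], nrow = N)
    tie <- which(net == 0)
    if (length(tie)) stats::runif(length(tie))
  } else {
    coop <- net > 0
    tie <- which(net == 0)
    if (length(tie)) coop[tie] <- stats::runif(length(tie)) < 0.5
  }
  n_c <- rowSums(coop)
  pay <- params$r * n_c / g - coop           # N x 5, column = member slot
  happy <- coop * net + (n_c - coop) * b_eff
  # each agent plays in the 5 games of its closed neighbourhood; its game
  # payoff is the average over those games
  mean_pay <- as.vector(rowsum.default(as.vector(pay), as.vector(M))) / g
  mean_happy <- as.vector(rowsum.default(as.vector(happy), as.vector(M))) / g
  fitness <- if (config$fitness_map == "linear") params$pi0 + mean_pay
             else exp(mean_pay)
  # synchronous replacement: the next occupant of each site descends from a
  # member of the site's closed neighbourhood, chosen with prob ~ fitness
  FM <- matrix(fitness[M], nrow = N)
  cum <- FM
  for (k in 2:g) cum[, k] <- cum[, k - 1L] + FM[, k]
  u <- stats::runif(N) * cum[, g]
  slot <- rep.int(1L, N)
  for (k in 1:(g - 1L)) slot <- slot + (u > cum[, k])
  parents <- M[cbind(seq_len(N), slot)]
  play <- list(cooperation = mean(coop),
               mean_payoff = mean(mean_pay),
               mean_happiness = mean(mean_happy),
               actions = if (config$record_actions) coop[, 1] else NULL)
  pop2 <- inherit_and_mutate(pop, parents, config, params)
  list(pop = pop2, play = play)
}

#' Advance a well-mixed population by one generation
#'
#' The population is partitioned into random groups of `g`, every group is
#' played at its subjective Nash equilibrium, fitness is the base payoff
#' plus the game payoff, `N` offspring are drawn with probability
#' proportional to fitness, inherit their parent's traits exactly, and
#' mutate.
#'
#' @param pop A `pgg_population`.
#' @param config A [sim_config()] object.
#' @param params A [pgg_params()] object.
#' @return The next-generation population; the attribute `"play"` holds
#'   the summary (cooperation frequency, mean payoff, mean happiness) of
#'   the generation just played.
#' @export
run_generation_wellmixed <- function(pop, config, params) {
  res <- step_wellmixed(pop, config, params)
  out <- res$pop
  attr(out, "play") <- res$play
  out
}

#' Advance a lattice population by one generation
#'
#' One public goods game is centred on every site; each agent plays in the
#' five games of its closed von Neumann neighbourhood and its game payoff
#' is the average across them. Sites are replaced synchronously by the
#' offspring of a parent drawn from the site's closed neighbourhood with
#' probability proportional to fitness.
#'
#' @inheritParams run_generation_wellmixed
#' @return The next-generation population, with attribute `"play"` as in
#'   [run_generation_wellmixed()].
#' @export
run_generation_lattice <- function(pop, config, params) {
  nb <- lattice_neighbors(config$L)
  res <- step_lattice(pop, config, params, nb)
  out <- res$pop
  attr(out, "play") <- res$play
  out
}

#' Run the agent-based evolutionary dynamics
#'
#' Iterates non-overlapping generations from the worst-case initial
#' condition (zero perceived benefit, uniform perceived cost, zero
#' sociality), recording observables on the configured schedule and,
#' optionally, lineage ("species") birth/death events and per-generation
#' population sizes.
#'
#' @param config A [sim_config()] object.
#' @param params A [pgg_params()] object.
#' @param pop Optional starting population (defaults to
#'   [init_population()]).
#' @return An object of class `pgg_abm` with elements `trajectory` (a
#'   data.frame of recorded observables), `snapshots`, `actions`,
#'   `species` (accumulated per-lineage statistics), `species_counts`
#'   (species richness per generation), `species_log` (optional long
#'   table) and the final `population`.
#' @export
run_abm <- function(config, params, pop = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(pop)) pop <- init_population(config, params)
  if (config$decision_rule == "fixed_at_birth" && is.null(pop$strategy))
    pop$strategy <- strategy_at_birth(pop, config, params)
  nb <- if (config$topology == "lattice") lattice_neighbors(config$L) else NULL
  TT <- config$generations
  sp <- if (config$track_species) new_species_tracker() else NULL
  sp_counts <- if (config$track_species) integer(TT + 1L) else NULL
  sp_log <- if (config$species_log) vector("list", TT + 1L) else NULL
  if (config$track_species) {
    st <- species_update(sp, pop$species, 0L)
    sp_counts[1L] <- st
    if (config$species_log) sp_log[[1L]] <- species_snapshot(sp, 0L)
  }
  rec <- list(); snaps <- list(); acts <- list()
  record_gen <- function(t) t >= config$burn_in && (t %% config$record_every == 0L)
  if (TT == 0L) {
    # nothing is played: record the initial state only
    rec[[1L]] <- data.frame(
      generation = 0L, cooperation = NA_real_,
      mean_sociality = mean(pop$s),
      mean_net_perception = mean(pop$b_hat - pop$c_hat),
      mean_payoff = NA_real_, mean_happiness = NA_real_,
      n_species = if (config$track_species) sp_counts[1L] else NA_integer_)
    if (config$snapshots)
      snaps[[1L]] <- list(generation = 0L, c_hat = pop$c_hat,
                          b_hat = pop$b_hat, s = pop$s)
  }
  for (t in seq_len(TT)) {
    res <- if (config$topology == "wellmixed")
      step_wellmixed(pop, config, params)
    else step_lattice(pop, config, params, nb)
    played <- pop          # the generation that just played is generation t - 1
    pop <- res$pop
    if (config$track_species) {
      st <- species_update(sp, pop$species, t)
      sp_counts[t + 1L] <- st
      if (config$species_log) sp_log[[t + 1L]] <- species_snapshot(sp, t)
    }
    tg <- t - 1L
    if (record_gen(tg)) {
      rec[[length(rec) + 1L]] <- data.frame(
        generation = tg,
        cooperation = res$play$cooperation,
        mean_sociality = mean(played$s),
        mean_net_perception = mean(played$b_hat - played$c_hat),
        mean_payoff = res$play$mean_payoff,
        mean_happiness = res$play$mean_happiness,
        n_species = if (config$track_species) sp_counts[t] else NA_integer_)
      if (config$snapshots)
        snaps[[length(snaps) + 1L]] <- list(generation = tg,
                                            c_hat = played$c_hat,
                                            b_hat = played$b_hat,
                                            s = played$s)
      if (config$record_actions)
        acts[[length(acts) + 1L]] <- res$play$actions
    }
    if (config$verbose && t %% 1000L == 0L)
      message(sprintf("generation %d / %d; cooperation %.3f",
                      t, TT, res$play$cooperation))
  }
  out <- list(trajectory = if (length(rec)) do.call(rbind, rec) else NULL,
              snapshots = if (config$snapshots) snaps else NULL,
              actions = if (config$record_actions) acts else NULL,
              species = if (config$track_species)
                species_finalize(sp, TT) else NULL,
              species_counts = sp_counts,
              species_log = if (config$species_log)
                do.call(rbind, sp_log) else NULL,
              population = pop, config = config, params = params)
  class(out) <- "pgg_abm"
  out
}

#' @export
print.pgg_abm <- function(x, ...) {
  cat(sprintf("ABM run: %s %s, N = %d, g = %d, r = %g, nu = %g, %d generations\n",
              x$params$variant, x$config$topology, x$config$N, x$params$g,
              x$params$r, x$config$nu, x$config$generations))
  if (!is.null(x$trajectory))
    cat(sprintf("recorded %d generations; mean cooperation %.4f\n",
                nrow(x$trajectory), mean(x$trajectory$cooperation)))
  invisible(x)
}

# --- lineage bookkeeping -----------------------------------------------
# accumulators indexed by species id, grown geometrically

new_species_tracker <- function() {
  e <- new.env(parent = emptyenv())
  e$cap <- 0L
  e$birth <- integer(0)
  e$death <- integer(0)   # NA while alive / never seen
  e$life <- integer(0)    # generations observed alive
  e$sum_n <- numeric(0)
  e$sum_n2 <- numeric(0)
  e$alive_prev <- integer(0)
  e
}

species_ensure <- function(e, n) {
  if (n > e$cap) {
    new_cap <- max(n, 2L * max(e$cap, 256L))
    grow <- function(x, fill) c(x, rep(fill, new_cap - length(x)))
    e$birth <- grow(e$birth, NA_integer_)
    e$death <- grow(e$death, NA_integer_)
    e$life <- grow(e$life, 0L)
    e$sum_n <- grow(e$sum_n, 0)
    e$sum_n2 <- grow(e$sum_n2, 0)
    e$cap <- new_cap
  }
}

species_update <- function(e, species, gen) {
  counts <- tabulate(species)
  alive <- which(counts > 0L)
  species_ensure(e, max(alive))
  newborn <- alive[is.na(e$birth[alive])]
  if (length(newborn)) e$birth[newborn] <- gen
  n <- counts[alive]
  e$life[alive] <- e$life[alive] + 1L
  e$sum_n[alive] <- e$sum_n[alive] + n
  e$sum_n2[alive] <- e$sum_n2[alive] + n * n
  dead <- setdiff(e$alive_prev, alive)
  if (length(dead)) e$death[dead] <- gen
  e$alive_prev <- alive
  e$counts_last <- counts
  length(alive)
}

species_snapshot <- function(e, gen) {
  alive <- e$alive_prev
  data.frame(generation = gen, species_id = alive, n = e$counts_last[alive])
}

species_finalize <- function(e, last_gen) {
  ids <- which(!is.na(e$birth[seq_len(e$cap)]))
  data.frame(species_id = ids,
             birth = e$birth[ids],
             death = e$death[ids],          # NA = still alive at the end
             lifespan = e$life[ids],
             total_pop = e$sum_n[ids],
             mean_pop = e$sum_n[ids] / e$life[ids],
             var_pop = ifelse(e$life[ids] > 1,
                              (e$sum_n2[ids] - e$sum_n[ids]^2 / e$life[ids]) /
                                (e$life[ids] - 1), NA_real_))
}
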