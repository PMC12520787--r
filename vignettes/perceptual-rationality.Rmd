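---
title: "Perceptually rational agents in public goods games: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perceptually rational agents in public goods games: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perceptgg)
set.seed(1)
```

## The model

`perceptgg` studies public goods games played by *perceptually rational*
agents. Each of the `g` members of a group chooses to cooperate (pay a
unit cost into a common pool) or defect. The pool is multiplied by the
enhancement factor `r` and divided equally, so the objective payoff of
member `i` is `r * nC / g - 1{i cooperates}`; a social dilemma exists for
`1 < r < g`, where the objectively rational outcome is universal
defection.

Agents here are rational, but with respect to a *subjective* game: each
carries an evolvable perception of the contribution cost (`c_hat`) and of
the per-capita benefit (`b_hat`), and maximizes its perceived payoff
`[C] * (b_eff - c_eff) + nC_others * b_eff`. Because the perceived
difference between cooperating and defecting, `b_eff - c_eff`, does not
depend on what anyone else does, the subjective Nash equilibrium
factorizes over group members: an agent cooperates if its effective net
perception is positive, defects if negative, and is indifferent at
exactly zero, in which case every mixture of its actions is an
equilibrium. `nash_play_group()` exploits this: exact mode averages
uniformly over the whole equilibrium set (equivalent, by linearity of the
payoffs in the action indicators, to independent 1/2 randomization of the
indifferent members), and sampling mode draws one equilibrium. A
brute-force enumeration over all `2^g` action profiles is kept in the
test suite as an independent oracle.

Sociality enters through the *effective* perception. In the continuous
social variant an agent blends its private perception with the mean
perception of its `g - 1` groupmates, weighted by its sociality trait
`s ∈ [0, 1]`. In the binary-trait variant (all of `c`, `b`, `s` in
`{0, 1}`) a social agent adopts the plain average over the whole group,
itself included; with binary sociality the agent can no longer weight
itself continuously, and including the focal member restores a
contribution of its own view. The `cost_only` and `benefit_only`
variants pin one perception to its objective value (cost 1, benefit
`r/g`) and let the other evolve on `[0, 2]`.

## Evolutionary dynamics

The agent-based model (`run_abm()`) uses non-overlapping generations:
random groups (or, on the lattice, one game centred on every site of a
periodic von Neumann lattice, each agent's payoff averaged over the five
games it joins), fitness `pi0 + payoff` with `pi0 = 1`, multinomial
reproduction proportional to fitness, exact trait inheritance, and
per-trait mutation that redraws the trait uniformly on its admissible
interval with probability `nu`. All runs start from the configuration
hardest for cooperation: zero perceived benefit, uniform perceived cost,
zero sociality.

Two choices were genuinely open and are resolved as follows.

* **Offspring placement on the lattice.** The lattice model specifies the
  game structure but not who competes for a site. We use synchronous
  site-wise replacement: the next occupant of each site is the offspring
  of a member of the site's closed neighbourhood, drawn with probability
  proportional to fitness. This is the standard non-overlapping-
  generations rule that keeps competition local; the base payoff is added
  after averaging the five games (equivalent for a constant `pi0`).
* **Species identity.** "Species" are lineages: every initial agent is a
  root, and a mutation in a tracked trait founds a new species even if
  the mutated value coincides with an existing one. The simple variant
  tracks the perceived-benefit lineage; the other variants track the full
  evolvable trait tuple. Trait values are copied bit-exactly, so all
  members of a species are identical in their tracked traits.

The replicator–mutator map (`replicator_run()`) is the infinite-population
limit for the binary-trait model: type frequencies are reweighted by
exact expected payoffs — a multinomial sum over all compositions of
`g - 1` groupmates, with the focal payoff resolved at the factorized
equilibrium and cached per `(g, r)` — then mixed by the trait-wise
mutation kernel `nu^k (1 - nu)^(3 - k)` at Hamming distance `k`. The base
payoff `pi0` is added inside the expected payoffs so the reproduction
weights stay positive even though game payoffs can be negative.

One parameterization subtlety matters when comparing the two engines: the
kernel's `nu` is the probability that a trait *changes*, while the
agent-based mutation redraws a binary trait uniformly and therefore
changes it with probability `nu/2`. Cross-engine comparisons must match
the effective change rates (kernel rate `nu/2` against an agent-based run
at `nu`); with that correspondence the binary social ABM at `N = 25600`
agrees with the replicator map to within sampling error across the
dilemma range.

### Cyclic dynamics in small groups

In groups of three, the type space carries a rock–paper–scissors-like
invasion structure (unconditional defectors are exploited by social
randomizers, which lose to pro-social types, which in turn are exploited
by defectors; see `invasion_matrix()`). In the deterministic map this
shows up as a weakly damped rotational mode: at `nu = 5e-5` the
oscillation persists for tens of thousands of steps, and the damping
vanishes as `nu` decreases; at `g = 4` or `5` the same parameters are
overdamped and the map settles immediately. At `nu = 1e-3` our map
spirals into a mixed fixed point in which all eight types coexist,
whereas finite populations at the same parameters show sustained
noise-excited quasi-cycles with a pronounced spectral peak — demographic
noise continually re-excites the weakly damped mode. The deterministic-map oscillation at mutation
rate `1e-3` itself is therefore *not* reproduced here: the fixed point is
stable, and the sustained-oscillation check in the acceptance suite
records that discrepancy rather than papering over it.

## Evolutionary stability

`is_ess()` checks the two textbook stability conditions for a resident
type against every mutant, using the rare-mutant convention (a single
mutant whose `g - 1` groupmates are all residents). Payoffs are rational
functions of `r` with denominator `g`, so ties are detected reliably at
tolerance `1e-12`; knife-edge values of `r` where ties are exact are
excluded from the default scan grid. Across `r ∈ {1.5, ..., 4.5}` (and
the corresponding interior grids for `g = 3, 4`) no type passes both
conditions: every resident is either beaten outright or tied and then
out-competed in the mutant's own population, which is what sustains the
persistent polymorphism seen in the dynamics.

## Observables and estimation

`perception_powerlaws()` summarizes perceptual diversity by four tail
exponents: the decaying (right) and rising (left) tails of the perceived
benefit-to-cost ratio, and the tails of the inverse perceived cost and
benefit. Conventions, all fixed before any comparison:

* Densities are log-binned (default base 1.3) and fitted by ordinary
  least squares of log density on log bin centre.
* Fits use bins with at least 10 counts, start half a decade away from
  the tent apex (the apex of the ratio distribution is placed at 1, the
  boundary between perceiving the good as beneficial and as costly),
  drop the extreme half-decade, and keep only the contiguous
  well-populated run of bins — isolated far bins that clear the count
  threshold only by upward fluctuation otherwise bias slopes shallow.
* Small-value tails are fitted through the inverse variable (a density
  exponent `tau` for a variable corresponds to `tau - 2` for its
  inverse); the rising branch of the tent is reported with a positive
  sign as `2 - tau`. This suppresses the small-bin noise of log-binned
  histograms.
* The reported confidence interval adds, to the regression interval, the
  spread of the slope across binning bases 1.2 and 1.5, which dominates
  the uncertainty at large sample sizes.
* Distribution statistics are pooled over independent replicate runs.
  Single runs are dominated by a handful of long-lived lineages whose
  trait values imprint visible lumps on the log-binned densities; the
  per-run exponent estimates scatter by several tenths, and pooling the
  replicate densities before fitting is markedly more stable than
  aggregating per-run fits.

Species-level statistics come from the lineage tracker: lifespan, total
and mean population over the lifespan, species richness per generation
(whose spectrum `species_count_psd()` fits over the lowest 1.5 decades of
frequency, averaged over eight non-overlapping windows), and Taylor
fluctuation scaling. `taylor_exponent()` reports, by default, the
exponent `alpha` in `sd(n) ~ mean(n)^alpha` — the convention under which
empirical fluctuation scaling lies between 1/2 and 1 — with
`scale = "var"` doubling the slope for the variance convention.

## What the simulations do and do not show

At `r = 2` the simple game keeps cooperation essentially at zero, so
lineage dynamics is nearly neutral: reproduction is a fair multinomial
and species follow a critical branching process. The measured patterns
agree with that picture — species lifespan density close to `t^-2`,
species-richness spectrum close to `1/f`, Taylor exponent slightly above
1 — and the perceived benefit-to-cost ratio develops its tent-shaped
power law with exponents near 2 despite the behavioural monotony,
because selection on perception is weak wherever behaviour does not
change. Two published eco-evolutionary exponents are *not* recovered at
these study conditions: the distributions of total and mean population
size over a species' lifespan come out at the critical-branching values
(density exponents near -1.5 and -2.1 respectively, stable across
population sizes and run lengths) rather than the printed -2.5 and -2.6.
The acceptance suite reports the measured values unmodified.

The generator emulates the study conditions (N = 1e4, nu = 1e-3, g = 5,
worst-case start, the published run lengths and recording schedules). It
does not emulate finite observation effects of real ecological data —
overlapping generations, measurement error, age structure — so passing
tests speak to the model's internal regularities, not to empirical
populations.

## Problem sizes used by the checks

The test suite runs reduced problem sizes chosen to keep each check's
sampling error well inside its tolerance: 6 pooled replicates at
`N = 2000` for the perceptual exponents, one `N = 5000` run of 10^4
generations for the species patterns, `N = 25600` for the
replicator-ABM comparison, and 10^6-draw Pareto samples for fitter
recovery. The acceptance script uses 8 pooled replicates at the full
`N = 10^4`, 15000-generation protocol for the trait exponents and an
`N = 10^4`, 2 x 10^4-generation species run.

## A worked example

```{r example, eval = FALSE}
params <- pgg_params(g = 5, r = 2, variant = "simple")
cfg <- sim_config(N = 2000, generations = 8000, nu = 1e-3,
                  burn_in = 4000, record_every = 10, snapshots = TRUE,
                  seed = 1)
run <- run_abm(cfg, params)
mean(run$trajectory$cooperation)        # ~0.001: no cooperation at r = 2
c_hat <- unlist(lapply(run$snapshots, `[[`, "c_hat"))
b_hat <- unlist(lapply(run$snapshots, `[[`, "b_hat"))
perception_powerlaws(c_hat, b_hat)$exponents
```

## Known limitations

* The deterministic replicator map does not reproduce the published
  sustained cycles at `g = 3`, `nu = 1e-3` (see above); the cyclic
  phenomenology appears in the finite-population simulation and, in the
  map, at mutation rates below roughly `1e-4`.
* Tail-exponent estimates for a single run carry lineage-clump noise of
  several tenths; treat per-run exponents as indicative only and pool
  replicates for quantitative work.
* The exponential fitness mapping is exposed (`fitness_map =
  "exponential"`) but not validated against published results.
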