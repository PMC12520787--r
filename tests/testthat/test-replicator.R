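test_that("mutation kernel has the trait-independence structure", {
  expect_equal(mutation_kernel(0), diag(8))
  K <- mutation_kernel(1e-3)
  expect_equal(colSums(K), rep(1, 8))
  expect_equal(K[1, 1], (1 - 1e-3)^3)            # 1 - 3nu + 3nu^2 - nu^3
  # distance-1 entry
  expect_equal(K[2, 1], (1 - 1e-3)^2 * 1e-3)
  # distance-3 entry: types 000 and 111
  tt <- binary_types()
  i000 <- match("000", tt$label); i111 <- match("111", tt$label)
  expect_equal(K[i111, i000], 1e-9)
  K2 <- mutation_kernel(0.2, n_traits = 2)
  expect_equal(dim(K2), c(4, 4))
  expect_equal(colSums(K2), rep(1, 4))
})

test_that("group payoffs match the brute-force equilibrium oracle", {
  tt <- binary_types()
  p <- pgg_params(g = 5, r = 3, variant = "binary")
  comp_of <- function(label, n = 4) {
    cmp <- integer(8); cmp[match(label, tt$label)] <- n; cmp
  }
  expect_equal(group_payoff("010", comp_of("100"), p), 3 / 5 - 1)
  expect_equal(group_payoff("100", comp_of("010"), p), 4 * 3 / 5)
  expect_equal(group_payoff("001", comp_of("001"), p), 1)
  # random compositions against the enumeration oracle
  set.seed(7)
  for (r in c(1.7, 2.5, 3.8)) {
    pr <- pgg_params(g = 5, r = r, variant = "binary")
    for (k in 1:20) {
      members <- random_binary_group(5)
      oracle <- oracle_nash_set(members, pr)
      cmp <- group_composition(members[-1, ])
      focal <- paste0(members$c_hat[1], members$b_hat[1], members$s[1])
      expect_equal(group_payoff(focal, cmp, pr),
                   unname(oracle$mean_payoffs[1]), tolerance = 1e-12)
    }
  }
  expect_error(group_payoff("010", rep(1L, 8), p), "sum to g - 1")
})

test_that("expected type payoffs are exact for point masses", {
  p <- pgg_params(g = 5, r = 3, variant = "binary")
  tt <- binary_types()
  point <- function(label) {
    rho <- numeric(8); rho[match(label, tt$label)] <- 1; rho
  }
  pb <- expected_type_payoffs(point("010"), p)
  expect_equal(unname(pb["010"]), 1 + 2)            # pi0 + (r - 1)
  pb <- expected_type_payoffs(point("100"), p)
  expect_equal(unname(pb["100"]), 1 + 0)
})

test_that("expected type payoffs agree with Monte-Carlo group sampling", {
  set.seed(11)
  p <- pgg_params(g = 5, r = 2.3, variant = "binary")
  cache <- replicator_cache(p)
  tt <- binary_types()
  rho <- rep(1 / 8, 8)
  exact <- expected_type_payoffs(rho, p, cache)
  n_mc <- 20000
  for (x in c(1, 4, 7)) {
    others <- matrix(sample.int(8, 4 * n_mc, replace = TRUE, prob = rho), ncol = 4)
    pays <- vapply(seq_len(n_mc), function(i) {
      cmp <- tabulate(others[i, ], nbins = 8)
      group_payoff(x, cmp, p, tt)
    }, numeric(1))
    mc <- mean(pays) + p$pi0
    se <- stats::sd(pays) / sqrt(n_mc)
    expect_lt(abs(mc - exact[x]), 3 * se + 1e-9)
  }
})

test_that("replicator step is the discrete selection-mutation map", {
  p <- pgg_params(g = 5, r = 3, variant = "binary")
  # nu = 0, uniform rho, payoffs equal across a symmetric pair stays put is
  # hard to arrange; instead verify the arithmetic directly on a hand-made
  # cache-free two-type computation via the full map with nu = 0:
  rho <- rep(1 / 8, 8)
  pibar <- expected_type_payoffs(rho, p)
  manual <- rho * pibar / sum(rho * pibar)
  expect_equal(replicator_step(rho, p, nu = 0), manual, tolerance = 1e-14,
               ignore_attr = TRUE)
  # point mass with mutation: off-type mass after one step = 1 - (1-nu)^3
  tt <- binary_types()
  rho0 <- numeric(8); rho0[match("100", tt$label)] <- 1
  nxt <- replicator_step(rho0, p, nu = 1e-3)
  expect_equal(unname(1 - nxt[match("100", tt$label)]), 1 - (1 - 1e-3)^3,
               tolerance = 1e-12)
})

test_that("trajectories conserve the simplex and settle sensibly", {
  p <- pgg_params(g = 5, r = 4.99, variant = "binary")
  run <- replicator_run("uniform", 2000, p, nu = 1e-3)
  expect_true(all(abs(rowSums(run$rho) - 1) < 1e-12))
  expect_true(all(run$rho >= -1e-15))
  # as r approaches g the dilemma vanishes and cooperation should be high
  expect_gt(mean(tail(run$cooperation, 50)), 0.9)
  # steps = 0 returns the initial state only
  run0 <- replicator_run("uniform", 0, p, nu = 1e-3)
  expect_equal(nrow(run0$rho), 1L)
})

test_that("the no-sociality reduction matches the 8-type system restricted to s = 0", {
  p <- pgg_params(g = 5, r = 2.6, variant = "binary")
  tt <- binary_types()
  run4 <- replicator_run(rep(1 / 4, 4), 200, p, nu = 0, sociality = FALSE)
  # embed: s = 0 types carry all mass; sociality mutations disabled (nu = 0
  # keeps mass off s = 1 types entirely)
  rho8 <- numeric(8)
  rho8[match(c("000", "010", "100", "110"), tt$label)] <- 1 / 4
  run8 <- replicator_run(rho8, 200, p, nu = 0)
  asoc <- match(c("000", "010", "100", "110"), tt$label)
  tt4 <- binary_types(sociality = FALSE)
  ord <- match(c("00", "01", "10", "11"), tt4$label)
  expect_equal(unname(run8$rho[201, asoc]),
               unname(run4$rho[201, ord]), tolerance = 1e-10)
  expect_equal(run8$cooperation, run4$cooperation, tolerance = 1e-10)
})

test_that("only triads carry the rotational (cyclic-dominance) mode", {
  # at low mutation the g = 3 dynamics oscillates for thousands of steps
  # (the rock-paper-scissors-like structure among anti-social, social
  # randomizing and pro-social types); g = 5 is overdamped and settles
  # immediately at the same parameters
  osc_amp <- function(g, nu) {
    p <- pgg_params(g = g, r = 2.3, variant = "binary")
    run <- replicator_run("uniform", 12000, p, nu)
    diff(range(run$cooperation[10000:12000]))
  }
  expect_gt(osc_amp(3, 5e-5), 0.01)
  expect_lt(osc_amp(5, 5e-5), 1e-8)
  # with mutation at 1e-3 the map spirals into a mixed fixed point in
  # which all eight types coexist
  p3 <- pgg_params(g = 3, r = 2.3, variant = "binary")
  run <- replicator_run("uniform", 5000, p3, 1e-3)
  expect_true(all(run$rho[5001, ] > 1e-3))
})
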