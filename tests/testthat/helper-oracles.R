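# Independent brute-force oracles used across the test files.

# Effective perceptions written directly from the model definitions,
# independently of the package internals.
oracle_effective <- function(members, params) {
  g <- params$g
  v <- params$variant
  if (v == "binary") {
    mc <- sum(members$c_hat) / g
    mb <- sum(members$b_hat) / g
    c_eff <- ifelse(members$s == 1, mc, members$c_hat)
    b_eff <- ifelse(members$s == 1, mb, members$b_hat)
  } else {
    s <- if (v == "simple") rep(0, g) else members$s
    c_eff <- b_eff <- numeric(g)
    for (i in seq_len(g)) {
      c_eff[i] <- (1 - s[i]) * members$c_hat[i] +
        s[i] * mean(members$c_hat[-i])
      b_eff[i] <- (1 - s[i]) * members$b_hat[i] +
        s[i] * mean(members$b_hat[-i])
    }
  }
  list(c_eff = c_eff, b_eff = b_eff)
}

# Enumerate all 2^g action profiles, keep those satisfying the subjective
# Nash condition (no member can raise its perceived payoff by deviating),
# and return the equilibrium set plus the mean objective payoffs over it.
oracle_nash_set <- function(members, params) {
  g <- params$g
  ep <- oracle_effective(members, params)
  profiles <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), g)))
  perceived <- function(coop, i) {
    n_others <- sum(coop[-i])
    as.numeric(coop[i]) * (ep$b_eff[i] - ep$c_eff[i]) + n_others * ep$b_eff[i]
  }
  is_ne <- apply(profiles, 1, function(coop) {
    for (i in seq_len(g)) {
      dev <- coop; dev[i] <- !dev[i]
      if (perceived(dev, i) > perceived(coop, i)) return(FALSE)
    }
    TRUE
  })
  ne <- profiles[is_ne, , drop = FALSE]
  payoff <- function(coop) params$r * sum(coop) / g - as.numeric(coop)
  mean_payoffs <- colMeans(t(apply(ne, 1, payoff)))
  list(ne = ne, mean_payoffs = mean_payoffs,
       mean_coop = colMeans(ne), n_ne = nrow(ne))
}

# random binary-type group of g members
random_binary_group <- function(g) {
  tt <- binary_types()
  idx <- sample.int(8, g, replace = TRUE)
  agent_traits(tt$c[idx], tt$b[idx], tt$s[idx])
}

# composition counts (over the 8 types) of a binary trait data.frame
group_composition <- function(traits) {
  tt <- binary_types()
  lab <- paste0(traits$c_hat, traits$b_hat, traits$s)
  as.integer(table(factor(lab, levels = tt$label)))
}

# 1/f^alpha noise by spectral synthesis (for the PSD fitter test)
synth_powerlaw_noise <- function(n, alpha) {
  freq <- 1:(n %/% 2)
  amp <- freq^(-alpha / 2)
  phase <- stats::runif(length(freq), 0, 2 * pi)
  half <- amp * exp(1i * phase)
  spec <- c(0, half, rev(Conj(half[-(n %/% 2)])))[1:n]
  Re(stats::fft(spec, inverse = TRUE))
}
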