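# Independent oracles, written case-by-case and kept deliberately separate
# from the package implementation.

# Case-enumeration payoff oracle: explicit if/else over every threshold
# case, no shared code with group_payoff().
oracle_group_payoff <- function(focal, n_C, n_D, n_P, n_M, G, r, c, alpha,
                                beta, gamma, H) {
  contributors_among_others <- n_C + n_P + n_M
  if (focal == "D") {
    pool <- r * c * contributors_among_others / G
    # punishers among co-players fine the focal defector
    if (n_P >= H) {
      fine <- (n_P + n_M) * alpha  # conditional punishers triggered
    } else {
      fine <- n_P * alpha
    }
    return(pool - fine)
  }
  # focal contributes
  pool <- r * c * (contributors_among_others + 1) / G
  base <- pool - c
  if (focal == "C") return(base)
  if (focal == "P") {
    # focal P always punishes; it counts itself toward the threshold
    if (n_P + 1 >= H) {
      sharers <- n_P + 1 + n_M
    } else {
      sharers <- n_P + 1
    }
    return(base - n_D * beta / sharers)
  }
  # focal M: punishes only if unconditional co-punishers reach H
  if (n_P >= H) {
    return(base - n_D * beta / (n_P + n_M + 1) - gamma)
  }
  base - gamma
}

# Exhaustive multinomial-sum oracle for infinite-population expected
# payoffs, built directly on the oracle payoff above.
oracle_expected_payoffs <- function(state, G, r, c, alpha, beta, gamma, H) {
  n <- G - 1
  pay <- c(C = 0, D = 0, P = 0, M = 0)
  for (a in 0:n) for (b in 0:(n - a)) for (d in 0:(n - a - b)) {
    m <- n - a - b - d
    w <- exp(lgamma(n + 1) - lgamma(a + 1) - lgamma(b + 1) -
               lgamma(d + 1) - lgamma(m + 1)) *
      state[1]^a * state[2]^b * state[3]^d * state[4]^m
    if (w == 0) next
    for (f in c("C", "D", "P", "M"))
      pay[f] <- pay[f] + w * oracle_group_payoff(f, a, b, d, m, G, r, c,
                                                 alpha, beta, gamma, H)
  }
  pay
}

# Vectorised single-group payoff for Monte Carlo sampling oracles.
oracle_payoff_vec <- function(focal, n_C, n_D, n_P, n_M, G, r, c, alpha,
                              beta, gamma, H) {
  trig_m <- as.numeric(n_P >= H)
  pi_C <- r * c * (G - n_D) / G - c
  switch(focal,
    C = pi_C,
    D = r * c * (G - n_D - 1) / G - (n_P + trig_m * n_M) * alpha,
    P = pi_C - n_D * beta / (n_P + as.numeric(n_P + 1 >= H) * n_M + 1),
    M = pi_C - trig_m * n_D * beta / (n_P + n_M + 1) - gamma)
}

# Plain spatial public goods game (no punishment), independent
# implementation: total payoff of one site over the 5 overlapping von
# Neumann groups.
oracle_plain_pgg_site <- function(grid, i, j, r, c) {
  L <- nrow(grid)
  wrap <- function(k) (k - 1) %% L + 1
  nbrs <- function(a, b) rbind(c(wrap(a - 1), b), c(wrap(a + 1), b),
                               c(a, wrap(b - 1)), c(a, wrap(b + 1)))
  contributes <- grid != 2  # everyone but defectors contributes
  centres <- rbind(c(i, j), nbrs(i, j))
  tot <- 0
  for (k in seq_len(nrow(centres))) {
    members <- rbind(centres[k, , drop = FALSE],
                     nbrs(centres[k, 1], centres[k, 2]))
    n_contrib <- sum(contributes[members])
    pool <- r * c * n_contrib / 5
    tot <- tot + pool - if (contributes[i, j]) c else 0
  }
  tot
}

wm_params <- function(H = 1) {
  game_params(G = 5, r = 3, c = 1, alpha = 1.0, beta = 0.7, gamma = 0.05,
              H = H)
}

lat_params <- function(H = 1) {
  game_params(G = 5, r = 2.0, c = 1, alpha = 1.0, beta = 0.8, gamma = 0.05,
              H = H)
}
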