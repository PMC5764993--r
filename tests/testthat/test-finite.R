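test_that("finite expected payoffs: identities and sampling oracle", {
  p <- wm_params()
  # all cooperators
  pay <- finite_expected_payoffs(c(100, 0, 0, 0), p)
  expect_equal(pay[["C"]], 2.0)
  expect_true(all(is.na(pay[c("D", "P", "M")])))
  # no defectors: P earns like C, M pays gamma extra
  pay <- finite_expected_payoffs(c(40, 0, 30, 30), p)
  expect_equal(pay[["P"]], pay[["C"]])
  expect_equal(pay[["M"]], pay[["C"]] - p$gamma)
  # hypergeometric Monte Carlo oracle at a balanced composition
  cnt <- c(25, 25, 25, 25)
  pay <- finite_expected_payoffs(cnt, p)
  set.seed(99)
  n_draw <- 2e5
  for (f in 1:4) {
    pool <- cnt; pool[f] <- pool[f] - 1
    # sequential conditional hypergeometric draws of the 4 co-players
    nC <- rhyper(n_draw, pool[1], 99 - pool[1], 4)
    nD <- rhyper(n_draw, pool[2], 99 - pool[1] - pool[2], 4 - nC)
    nP <- rhyper(n_draw, pool[3], pool[4], 4 - nC - nD)
    nM <- 4 - nC - nD - nP
    sim <- oracle_payoff_vec(strategies()[f], nC, nD, nP, nM, 5, 3, 1,
                             1.0, 0.7, 0.05, 1)
    se <- sd(sim) / sqrt(n_draw)
    expect_lt(abs(mean(sim) - pay[[f]]), 3.5 * se)
  }
})

test_that("finite payoffs converge to the infinite-population payoffs", {
  p <- wm_params()
  st <- c(0.25, 0.25, 0.25, 0.25)
  inf <- expected_payoffs(st, p)
  fin <- finite_expected_payoffs(4000 * st, p)
  expect_lt(max(abs(fin - inf)), 1e-2)
})

test_that("fermi rule is symmetric, monotone and saturates safely", {
  expect_equal(fermi(0, 2), 0.5)
  expect_equal(fermi(123.4, 0), 0.5)
  expect_equal(fermi(1e6, 2), 1)
  expect_equal(fermi(-1e6, 2), 0)
  dp <- seq(-3, 3, by = 0.5)
  expect_true(all(diff(fermi(dp, 1.7)) > 0))
  # detailed-balance identity of the pairwise comparison rule
  expect_equal(fermi(1.3, 2) / fermi(-1.3, 2), exp(2 * 1.3),
               tolerance = 1e-12)
})

test_that("pairwise transitions vanish at the absorbing boundaries and are
           neutral without payoff differences", {
  p <- wm_params()
  expect_equal(pairwise_transition(c(0, 10, 0, 0), "C", "D", p, 2), 0)
  expect_equal(pairwise_transition(c(10, 0, 0, 0), "C", "D", p, 2), 0)
  # C vs P with no defectors is exactly neutral
  expect_equal(pairwise_transition(c(6, 0, 4, 0), "C", "P", p, 2),
               (6 / 10) * (4 / 10) * 0.5)
  expect_error(pairwise_transition(c(5, 3, 2, 0), "C", "D", p, 2),
               "two-strategy")
})

test_that("the two fixation-probability forms agree to 1e-10", {
  p <- wm_params()
  pairs <- list(c("D", "P"), c("C", "D"), c("P", "M"), c("M", "C"))
  for (N in c(6, 10, 50, 100)) {
    for (s in c(0, 0.5, 2)) {
      pr <- pairs[[(N + s * 2) %% 4 + 1]]
      a <- fixation_probability(pr[1], pr[2], p, N, s, method = "exp_sum")
      b <- fixation_probability(pr[1], pr[2], p, N, s, method = "product")
      expect_equal(a, b, tolerance = 1e-10,
                   label = sprintf("%s->%s N=%d s=%g", pr[1], pr[2], N, s))
    }
  }
})

test_that("neutral fixation equals 1/N exactly", {
  p <- wm_params()
  for (N in c(6, 10, 40)) {
    for (pr in list(c("C", "D"), c("D", "P"), c("M", "C"))) {
      expect_equal(fixation_probability(pr[1], pr[2], p, N, 0), 1 / N)
    }
    # C vs P without defectors is neutral at any s
    expect_equal(fixation_probability("C", "P", p, N, 2), 1 / N,
                 tolerance = 1e-12)
  }
})

test_that("fixation matches a brute-force absorbing-chain solve at N = 6", {
  p <- wm_params()
  N <- 6; s <- 2
  for (pr in list(c("D", "P"), c("C", "M"))) {
    i <- match(pr[1], strategies()); j <- match(pr[2], strategies())
    # build the full (N+1)-state birth-death chain for the mutant count
    up <- dn <- numeric(N + 1)
    for (k in 1:(N - 1)) {
      cnt <- integer(4); cnt[i] <- N - k; cnt[j] <- k
      pay <- finite_expected_payoffs(cnt, p)
      up[k + 1] <- ((N - k) / N) * (k / N) * fermi(pay[[j]] - pay[[i]], s)
      dn[k + 1] <- (k / N) * ((N - k) / N) * fermi(pay[[i]] - pay[[j]], s)
    }
    # absorption probability at k = N starting from k = 1, by linear solve
    A <- matrix(0, N - 1, N - 1)
    b <- numeric(N - 1)
    for (k in 1:(N - 1)) {
      stay <- 1 - up[k + 1] - dn[k + 1]
      A[k, k] <- 1 - stay
      if (k > 1) A[k, k - 1] <- -dn[k + 1]
      if (k < N - 1) A[k, k + 1] <- -up[k + 1]
      if (k == N - 1) b[k] <- up[k + 1]
    }
    rho_oracle <- solve(A, b)[1]
    expect_equal(fixation_probability(pr[1], pr[2], p, N, s), rho_oracle,
                 tolerance = 1e-10)
  }
})

test_that("strong-imitation chain has the printed structure and stationary
           state of full defection", {
  m <- strong_imitation_matrix(100)
  expect_equal(unname(rowSums(m)), rep(1, 4))
  expect_equal(unname(m[1, ]), c(199 / 300, 1 / 3, 1 / 300, 0))
  expect_equal(unname(m[2, ]), c(0, 1, 0, 0))
  st <- stationary_distribution(m)
  expect_equal(as.numeric(st), c(0, 1, 0, 0))
  expect_equal(sum(st), 1, tolerance = 1e-12)
})

test_that("embedded chain: uniform at s = 0, rows stochastic, converges to
           the strong-imitation limit as s grows", {
  p <- wm_params()
  N <- 30
  ch0 <- embedded_markov_chain(p, N, 0)
  expect_equal(as.numeric(ch0$stationary), rep(0.25, 4), tolerance = 1e-9)
  expect_true(all(abs(ch0$fixation[row(ch0$fixation) !=
                                     col(ch0$fixation)] - 1 / N) < 1e-12))
  target <- strong_imitation_matrix(N)
  errs <- vapply(c(10, 50, 200), function(s) {
    ch <- embedded_markov_chain(p, N, s)
    expect_equal(unname(rowSums(ch$transition_matrix)), rep(1, 4),
                 tolerance = 1e-12)
    expect_true(all(ch$transition_matrix >= -1e-15))
    max(abs(ch$transition_matrix - target))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  ch <- embedded_markov_chain(p, N, 200)
  expect_equal(as.numeric(ch$stationary), c(0, 1, 0, 0), tolerance = 1e-6)
})
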