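#' Population counts in a finite well-mixed population
#'
#' @param X,Y,Z,W Non-negative integer counts of C, D, P, M.
#' @return Named integer vector of length 4 (population size is the sum).
#' @export
population_counts <- function(X, Y, Z, W) {
  cnt <- c(C = as.integer(X), D = as.integer(Y),
           P = as.integer(Z), M = as.integer(W))
  if (any(cnt < 0)) stop("counts must be non-negative")
  if (sum(cnt) < 2) stop("population size must be at least 2")
  cnt
}

#' Exact expected payoffs in a finite well-mixed population
#'
#' Expected payoff of each strategy when the `G - 1` co-players of a focal
#' individual are drawn without replacement from the other `N - 1`
#' population members (multivariate hypergeometric sampling). Implemented
#' as an exhaustive sum over co-player compositions weighted by
#' hypergeometric probabilities; for a strategy that is absent from the
#' population the payoff is undefined and reported as `NA`.
#'
#' @param counts A [population_counts()] vector.
#' @param params A [game_params()] object (requires `N >= G`).
#' @return Named numeric vector of payoffs `(C, D, P, M)`, `NA` for absent
#'   strategies.
#' @export
finite_expected_payoffs <- function(counts, params) {
  params <- as_params(params)
  counts <- population_counts(counts[[1]], counts[[2]], counts[[3]],
                              counts[[4]])
  N <- sum(counts)
  if (N < params$G) stop("population size must be at least the group size")
  tab <- co_player_compositions(params$G)
  ldenom <- lchoose(N - 1, params$G - 1)
  pay <- rep(NA_real_, 4)
  for (f in 1:4) {
    if (counts[f] == 0) next
    pool <- counts
    pool[f] <- pool[f] - 1L  # focal excluded from its own sampling pool
    lw <- rowSums(matrix(lchoose(rep(pool, each = nrow(tab$comps)),
                                 tab$comps), ncol = 4)) - ldenom
    ok <- is.finite(lw)
    pis <- vapply(which(ok), function(i)
      group_payoff(strategies()[f], tab$comps[i, ], params), numeric(1))
    pay[f] <- sum(exp(lw[ok]) * pis)
  }
  setNames(pay, strategies())
}

#' Fermi imitation probability
#'
#' Pairwise-comparison rule: a player imitates a role model whose payoff
#' exceeds its own by `delta_p` with probability
#' `1 / (1 + exp(-s * delta_p))`. Saturates cleanly to 0/1 for large
#' `|s * delta_p|`.
#'
#' @param delta_p Payoff difference `P_v - P_u` (vectorised).
#' @param s Imitation strength (`s >= 0`); `s = 0` gives probability 1/2.
#' @return Probability in `(0, 1)`.
#' @export
fermi <- function(delta_p, s) {
  stopifnot(s >= 0)
  plogis(s * delta_p)
}

two_strategy_payoffs <- function(i, j, k, N, params) {
  # payoffs (P_i, P_j) in a two-strategy state with k mutants of j
  cnt <- integer(4)
  cnt[i] <- N - k
  cnt[j] <- k
  pay <- finite_expected_payoffs(cnt, params)
  c(pay[i], pay[j])
}

#' Pairwise transition probability of the imitation chain
#'
#' In a two-strategy state with `N_i` players of strategy `i` (and
#' `N - N_i` of `j`), the probability that one update step decreases the
#' count of `i` by one: an `i` player is drawn as focal, a `j` player as
#' role model, and the imitation succeeds with the Fermi probability.
#'
#' @param counts A [population_counts()] vector with only strategies `i`
#'   and `j` present.
#' @param i,j Strategy labels.
#' @param params A [game_params()] object.
#' @param s Imitation strength.
#' @return Probability that `N_i` decreases by one.
#' @export
pairwise_transition <- function(counts, i, j, params, s) {
  ii <- match_strategy(i); jj <- match_strategy(j)
  counts <- population_counts(counts[[1]], counts[[2]], counts[[3]],
                              counts[[4]])
  if (any(counts[-c(ii, jj)] > 0))
    stop("pairwise_transition requires a two-strategy state")
  N <- sum(counts)
  N_i <- counts[[ii]]
  if (N_i == 0 || N_i == N) return(0)
  pay <- finite_expected_payoffs(counts, params)
  unname((N_i / N) * ((N - N_i) / N) * fermi(pay[[jj]] - pay[[ii]], s))
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Fixation probability of a single mutant
#'
#' Probability that a single mutant of strategy `mutant` takes over a
#' resident population of strategy `resident` of size `N` under the
#' pairwise-comparison imitation dynamics without mutation. Computed by
#' two routes that must agree: the birth-death product form over ratios of
#' the pairwise transition probabilities, and the simplified exponential
#' form `1 / (1 + sum_q exp(s * sum_{k<=q} (P_i - P_j)))`, both evaluated
#' with the exact finite-population payoffs at every intermediate state
#' and accumulated in log space.
#'
#' @param resident,mutant Strategy labels.
#' @param params A [game_params()] object.
#' @param N Population size (`N >= 2`).
#' @param s Imitation strength.
#' @param method `"both"` (default; cross-checks the two forms to 1e-10),
#'   `"exp_sum"`, or `"product"`.
#' @return Fixation probability in `(0, 1]`. Neutral pairs give `1/N`.
#' @export
fixation_probability <- function(resident, mutant, params, N, s,
                                 method = c("both", "exp_sum", "product")) {
  method <- match.arg(method)
  params <- as_params(params)
  stopifnot(N >= 2, N >= params$G)
  i <- match_strategy(resident); j <- match_strategy(mutant)
  if (i == j) stop("resident and mutant must differ")
  pay <- vapply(seq_len(N - 1), function(k)
    two_strategy_payoffs(i, j, k, N, params), numeric(2))
  d <- pay[1, ] - pay[2, ]  # P_i - P_j at k = 1..N-1 mutants

  rho_exp <- function() {
    # 1 / (1 + sum_q exp(s * cumsum(d)))
    exp(-log_sum_exp(c(0, s * cumsum(d))))
  }
  rho_prod <- function() {
    # product form: cumulative products of tau_{j->i}/tau_{i->j}; the
    # selection ratio only, since the sampling factors cancel
    lr <- vapply(seq_len(N - 1), function(k) {
      q_up <- fermi(-d[k], s)   # i imitates j
      q_dn <- fermi(d[k], s)    # j imitates i
      log(q_dn) - log(q_up)
    }, numeric(1))
    exp(-log_sum_exp(c(0, cumsum(lr))))
  }
  if (method == "exp_sum") return(rho_exp())
  if (method == "product") return(rho_prod())
  a <- rho_exp(); b <- rho_prod()
  if (abs(a - b) > 1e-10)
    warning(sprintf("fixation probability forms disagree by %.3g", a - b))
  a
}

#' Strong-imitation transition matrix of the embedded chain
#'
#' In the rare-mutation limit the population hops between the four
#' homogeneous states with probabilities `rho_ij / 3`. In the
#' strong-imitation limit (`s -> Inf`, for fines above the critical value)
#' advantageous invasions fix with probability 1, neutral ones with `1/N`,
#' and disadvantageous ones never, which gives a simple constant matrix
#' whose stationary distribution puts all mass on the all-defector state.
#'
#' @param N Population size.
#' @return 4x4 row-stochastic matrix over `(All_C, All_D, All_P, All_M)`.
#' @export
strong_imitation_matrix <- function(N) {
  stopifnot(N >= 2)
  m <- matrix(c(
    (2 * N - 1) / (3 * N), 1 / 3, 1 / (3 * N), 0,
    0, 1, 0, 0,
    1 / (3 * N), 0, (3 * N - 1) / (3 * N), 0,
    1 / 3, 1 / 3, 1 / 3, 0), nrow = 4, byrow = TRUE)
  dimnames(m) <- list(paste0("All_", strategies()),
                      paste0("All_", strategies()))
  m
}

#' Stationary distribution of a Markov transition matrix
#'
#' Normalised left eigenvector for eigenvalue 1. When the unit eigenvalue
#' is (numerically) multiple the chain is reducible and the returned
#' distribution is flagged.
#'
#' @param P Row-stochastic square matrix.
#' @return Numeric probability vector with attribute `"reducible"`.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  iu <- which(abs(e$values - 1) < 1e-9)
  v <- Re(e$vectors[, iu[1]])
  v <- v / sum(v)
  v[abs(v) < 1e-15] <- 0
  v <- pmax(v, 0)
  v <- v / sum(v)
  names(v) <- rownames(P)
  attr(v, "reducible") <- length(iu) > 1
  v
}

#' Rare-mutation embedded Markov chain over homogeneous states
#'
#' Builds the 4x4 chain on `(All_C, All_D, All_P, All_M)` whose
#' off-diagonal entries are `rho_ij / 3` (each homogeneous state is
#' entered by one of three possible mutants, each arising with equal
#' probability in the rare-mutation limit) and returns its stationary
#' distribution.
#'
#' @param params A [game_params()] object.
#' @param N Population size.
#' @param s Imitation strength; `Inf` selects the closed-form
#'   strong-imitation matrix.
#' @return A list with `transition_matrix`, `stationary` (with the
#'   reducibility flag as attribute) and `fixation` (matrix of `rho_ij`,
#'   `NA` on the diagonal; omitted for `s = Inf`).
#' @export
embedded_markov_chain <- function(params, N, s) {
  if (is.infinite(s)) {
    m <- strong_imitation_matrix(N)
    return(list(transition_matrix = m,
                stationary = stationary_distribution(m)))
  }
  params <- as_params(params)
  rho <- matrix(NA_real_, 4, 4,
                dimnames = list(strategies(), strategies()))
  for (i in 1:4) for (j in 1:4) if (i != j)
    rho[i, j] <- fixation_probability(strategies()[i], strategies()[j],
                                      params, N, s)
  m <- rho / 3
  diag(m) <- 0
  diag(m) <- 1 - rowSums(m)
  dimnames(m) <- list(paste0("All_", strategies()),
                      paste0("All_", strategies()))
  list(transition_matrix = m, stationary = stationary_distribution(m),
       fixation = rho)
}
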