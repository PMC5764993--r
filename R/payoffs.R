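#' Heaviside step function
#'
#' `heaviside(u)` is 1 for `u >= 0` and 0 otherwise. It encodes the
#' conditional-punishment trigger: with `N_P` unconditional punishers among
#' the co-players, a conditional punisher punishes iff
#' `heaviside(N_P - H) == 1`.
#'
#' @param u Integer (vectorised; may be negative).
#' @return Integer vector of 0s and 1s.
#' @examples
#' heaviside(c(-1, 0, 3))
#' @export
heaviside <- function(u) as.integer(u >= 0)

#' Group composition of co-players
#'
#' Counts of the other `G - 1` group members by strategy, in the order
#' C, D, P, M. Payoff formulas are written in terms of co-players; the
#' focal individual is added back inside the formulas where required (for
#' instance a focal unconditional punisher counts itself toward the
#' threshold, a focal conditional punisher does not).
#'
#' @param n_C,n_D,n_P,n_M Non-negative integer counts; must sum to `G - 1`.
#' @param params A [game_params()] object (used to validate the sum).
#' @return Named integer vector of length 4.
#' @export
group_composition <- function(n_C, n_D, n_P, n_M, params = NULL) {
  comp <- c(C = as.integer(n_C), D = as.integer(n_D),
            P = as.integer(n_P), M = as.integer(n_M))
  if (any(comp < 0)) stop("composition counts must be non-negative")
  if (!is.null(params)) {
    params <- as_params(params)
    if (sum(comp) != params$G - 1L)
      stop("composition counts must sum to G - 1 = ", params$G - 1L)
  }
  comp
}

check_composition <- function(comp, params) {
  comp <- as.integer(comp)
  if (length(comp) != 4 || any(comp < 0) || sum(comp) != params$G - 1L)
    stop("invalid group composition: need 4 non-negative counts summing to G - 1")
  comp
}

#' Single-group payoff of a focal strategy
#'
#' Payoff that a focal player of the given strategy earns from one group,
#' given the strategies of its `G - 1` co-players. All contributors put `c`
#' into the pot, which is multiplied by `r` and split among all `G`
#' members. A defector is fined `alpha` by every unconditional punisher and
#' (when the threshold is met, i.e. `N_P >= H`) by every conditional
#' punisher. The punishment cost `beta` per defector is shared equally
#' among the punishing individuals, the focal included: a focal P always
#' punishes and counts itself toward the threshold (so the conditional
#' co-punishers join when `N_P + 1 >= H`), whereas a focal M punishes only
#' when the unconditional punishers among its co-players already reach the
#' threshold (`N_P >= H`) and always pays the observation cost `gamma`.
#'
#' @param focal One of `"C"`, `"D"`, `"P"`, `"M"`.
#' @param comp A [group_composition()] (counts of co-players; length-4
#'   vector in C, D, P, M order).
#' @param params A [game_params()] object.
#' @return The focal payoff (payoff units).
#' @examples
#' p <- game_params(r = 3, c = 1, G = 5, alpha = 1, beta = 0.7,
#'                  gamma = 0.05, H = 1)
#' group_payoff("C", group_composition(4, 0, 0, 0), p)  # full cooperation
#' group_payoff("D", group_composition(0, 0, 4, 0), p)  # a defector, fined
#' @export
group_payoff <- function(focal, comp, params) {
  params <- as_params(params)
  comp <- check_composition(comp, params)
  n_C <- comp[[1]]; n_D <- comp[[2]]; n_P <- comp[[3]]; n_M <- comp[[4]]
  G <- params$G; r <- params$r; c <- params$c; H <- params$H
  pi_C <- r * c * (G - n_D) / G - c
  switch(match.arg(focal, strategies()),
    C = pi_C,
    D = r * c * (G - n_D - 1) / G -
        (n_P + heaviside(n_P - H) * n_M) * params$alpha,
    P = pi_C - n_D * params$beta /
        (n_P + heaviside(n_P + 1 - H) * n_M + 1),
    M = pi_C - heaviside(n_P - H) * n_D * params$beta /
        (n_P + n_M + 1) - params$gamma)
}

#' Payoffs of all four focal strategies
#'
#' Evaluates [group_payoff()] for each focal strategy. With a single
#' composition the same co-player counts are used for every focal; a named
#' list of compositions (one per strategy) evaluates each focal against its
#' own co-players.
#'
#' @param comp A single [group_composition()] or a named list with entries
#'   `C`, `D`, `P`, `M`.
#' @inheritParams group_payoff
#' @return Named numeric vector `c(C = , D = , P = , M = )`.
#' @export
payoff_vector <- function(comp, params) {
  params <- as_params(params)
  if (is.list(comp)) {
    if (!all(strategies() %in% names(comp)))
      stop("composition list must have entries C, D, P, M")
    vapply(strategies(), function(f) group_payoff(f, comp[[f]], params),
           numeric(1))
  } else {
    vapply(strategies(), function(f) group_payoff(f, comp, params),
           numeric(1))
  }
}

# All 4-part compositions of the G-1 co-players with log multinomial
# coefficients; cached per group size.
co_player_compositions <- local({
  cache <- new.env(parent = emptyenv())
  function(G) {
    key <- as.character(G)
    if (!is.null(cache[[key]])) return(cache[[key]])
    n <- G - 1L
    rows <- list()
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b))
      rows[[length(rows) + 1L]] <- c(a, b, cc, n - a - b - cc)
    comps <- do.call(rbind, rows)
    colnames(comps) <- strategies()
    lmult <- lgamma(n + 1) - rowSums(lgamma(comps + 1))
    out <- list(comps = comps, lmultinom = lmult)
    cache[[key]] <- out
    out
  }
})
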