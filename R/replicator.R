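#' Mixed population state on the strategy simplex
#'
#' Frequencies `(x, y, z, w)` of C, D, P, M in an infinite well-mixed
#' population. Frequencies must be non-negative and sum to 1 (tolerance
#' `1e-9`).
#'
#' @param x,y,z,w Frequencies of C, D, P, M.
#' @return Named numeric vector of length 4.
#' @export
mixed_state <- function(x, y, z, w = 1 - x - y - z) {
  s <- c(x = x, y = y, z = z, w = w)
  if (any(s < -1e-12) || abs(sum(s) - 1) > 1e-9)
    stop("invalid mixed state: frequencies must be non-negative and sum to 1")
  pmax(s, 0)
}

#' Expected payoffs in an infinite well-mixed population
#'
#' Exact expected payoff of each strategy when groups of `G` are assembled
#' by multinomial sampling from a population with frequencies
#' `(x, y, z, w)`: the sum over all compositions of the `G - 1` co-players
#' of the multinomial probability times the single-group payoff (35 terms
#' for `G = 5`).
#'
#' @param state A [mixed_state()] (or plain length-4 frequency vector).
#' @param params A [game_params()] object.
#' @return Named numeric vector of expected payoffs `(C, D, P, M)`.
#' @export
expected_payoffs <- function(state, params) {
  params <- as_params(params)
  state <- mixed_state(state[[1]], state[[2]], state[[3]], state[[4]])
  setNames(expected_payoffs_cpp(as.numeric(state), unclass(params)),
           strategies())
}

#' Population mean payoff
#'
#' @inheritParams expected_payoffs
#' @return `x P_C + y P_D + z P_P + w P_M` (payoff units).
#' @export
average_payoff <- function(state, params) {
  sum(state * expected_payoffs(state, params))
}

#' Replicator right-hand side
#'
#' Time derivatives of the strategy frequencies: each strategy grows at a
#' rate proportional to its payoff advantage over the population mean,
#' `dx_i/dt = x_i (P_i - Pbar)`. All four equations are integrated (the
#' fourth is implied by normalisation but carrying it explicitly is
#' numerically convenient); the derivatives sum to zero.
#'
#' @inheritParams expected_payoffs
#' @return Named numeric vector of derivatives `(x, y, z, w)`.
#' @export
replicator_rhs <- function(state, params) {
  pay <- expected_payoffs(state, params)
  pbar <- sum(state * pay)
  setNames(as.numeric(state) * (pay - pbar), c("x", "y", "z", "w"))
}

#' Integrate a replicator trajectory
#'
#' Solves the replicator equations from an initial state with
#' [deSolve::ode()] (adaptive `lsoda`), renormalising onto the simplex
#' whenever accumulated drift exceeds `1e-12`, and classifies the terminal
#' state with [classify_endpoint()].
#'
#' @param state0 Initial [mixed_state()].
#' @param params A [game_params()] object.
#' @param t_max Integration horizon (time units).
#' @param rtol,atol Relative/absolute integration tolerances.
#' @param n_out Number of output time points (log-spaced after t = 1).
#' @param eps Endpoint classification threshold (see [classify_endpoint()]).
#' @return A `"cp_trajectory"`: list with `times`, `states` (matrix with
#'   columns x, y, z, w) and `terminal_class` (`"DEFECTION"`,
#'   `"COOPERATIVE"` or `"UNRESOLVED"`).
#' @export
integrate_replicator <- function(state0, params, t_max = 1e4, rtol = 1e-8,
                                 atol = 1e-10, n_out = 200, eps = 1e-3) {
  params <- as_params(params)
  state0 <- mixed_state(state0[[1]], state0[[2]], state0[[3]], state0[[4]])
  times <- unique(c(0, exp(seq(log(1e-2), log(t_max), length.out = n_out))))
  deriv <- function(t, y, parms) {
    s <- pmax(y, 0)
    tot <- sum(s)
    if (abs(tot - 1) > 1e-12) s <- s / tot
    list(as.numeric(replicator_rhs(s, params)))
  }
  sol <- deSolve::ode(y = as.numeric(state0), times = times, func = deriv,
                      parms = NULL, method = "lsoda", rtol = rtol,
                      atol = atol)
  states <- pmax(sol[, -1, drop = FALSE], 0)
  states <- states / rowSums(states)
  colnames(states) <- c("x", "y", "z", "w")
  term <- classify_endpoint(states[nrow(states), ], params, eps = eps)
  structure(list(times = sol[, 1], states = states, terminal_class = term),
            class = "cp_trajectory")
}

#' @export
print.cp_trajectory <- function(x, ...) {
  n <- nrow(x$states)
  cat(sprintf("Replicator trajectory: %d points, t in [%g, %g]\n",
              n, x$times[1], x$times[length(x$times)]))
  cat("  final state:",
      paste(sprintf("%s=%.4g", colnames(x$states), x$states[n, ]),
            collapse = ", "), "\n")
  cat("  terminal class:", x$terminal_class, "\n")
  invisible(x)
}

#' Classify a trajectory endpoint
#'
#' The replicator dynamics of this game has two attractors: the all-defector
#' vertex and the defector-free segment on which cooperators and
#' unconditional punishers coexist neutrally. A state is `"DEFECTION"` when
#' the defector frequency exceeds `1 - eps`, `"COOPERATIVE"` when both the
#' defector and the conditional-punisher frequencies are below `eps` and
#' the state is stationary (`max |rhs| < stat_tol`), and `"UNRESOLVED"`
#' otherwise.
#'
#' @param state A [mixed_state()].
#' @param params A [game_params()] object.
#' @param eps Frequency threshold.
#' @param stat_tol Stationarity threshold on the right-hand side.
#' @return One of `"DEFECTION"`, `"COOPERATIVE"`, `"UNRESOLVED"`.
#' @export
classify_endpoint <- function(state, params, eps = 1e-3, stat_tol = 1e-8) {
  y <- state[[2]]; w <- state[[4]]
  if (y > 1 - eps) return("DEFECTION")
  if (y < eps && w < eps &&
      max(abs(replicator_rhs(state, params))) < stat_tol)
    return("COOPERATIVE")
  "UNRESOLVED"
}
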