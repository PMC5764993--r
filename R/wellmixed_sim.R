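#' Evolution/simulation settings
#'
#' @param s Imitation strength (`>= 0`).
#' @param mu Mutation (random exploration) rate in `[0, 1]`.
#' @param n_steps Number of elementary update steps.
#' @param seed RNG seed (integer); recorded in every output.
#' @return An object of class `"cp_evo"`.
#' @export
evo_params <- function(s = 2, mu = 1e-3, n_steps = 2e5, seed = 1L) {
  stopifnot(s >= 0, mu >= 0, mu <= 1, n_steps >= 1)
  structure(list(s = as.numeric(s), mu = as.numeric(mu),
                 n_steps = as.numeric(n_steps), seed = as.integer(seed)),
            class = "cp_evo")
}

#' Individual-based simulation of a finite well-mixed population
#'
#' Mutation-selection dynamics in discrete time: at each step a random
#' player `u` is chosen; with probability `mu` it mutates (by default to
#' one of the other three strategies, each with probability `mu/3`;
#' alternatively uniformly over all four), otherwise a random role model
#' `v != u` is chosen and `u` adopts `v`'s strategy with the Fermi
#' probability computed from the exact expected payoffs at the current
#' composition.
#'
#' @param params A [game_params()] object.
#' @param evo An [evo_params()] object.
#' @param initial_counts A [population_counts()] vector.
#' @param record_every Record the composition every this many steps.
#' @param mutation `"other_three"` (default, switch rate `mu/3` to each
#'   alternative) or `"all_four"` (uniform redraw, effective switch rate
#'   `3 mu / 4`).
#' @return A data frame with columns `step, X, Y, Z, W`; the seed and
#'   parameters are attached as attributes.
#' @export
simulate_wellmixed <- function(params, evo, initial_counts,
                               record_every = NULL,
                               mutation = c("other_three", "all_four")) {
  params <- as_params(params)
  mutation <- match.arg(mutation)
  counts <- population_counts(initial_counts[[1]], initial_counts[[2]],
                              initial_counts[[3]], initial_counts[[4]])
  if (sum(counts) < params$G)
    stop("population size must be at least the group size")
  if (is.null(record_every))
    record_every <- max(1L, floor(evo$n_steps / 2000))
  set.seed(evo$seed)
  m <- simulate_wellmixed_cpp(counts, unclass(params), evo$s, evo$mu,
                              evo$n_steps, as.integer(record_every),
                              mutation == "all_four")
  out <- as.data.frame(m)
  names(out) <- c("step", "X", "Y", "Z", "W")
  attr(out, "seed") <- evo$seed
  attr(out, "params") <- params
  attr(out, "evo") <- evo
  out
}
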