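#' Game parameters for the conditional-punishment public goods game
#'
#' Bundles and validates the static game definition. Groups of `G` players
#' play a public goods game: every non-defector contributes `c`, the pot is
#' multiplied by the synergy factor `r` and shared equally by all `G`
#' members. Each unconditional punisher (P) fines every defector in its
#' group by `alpha`; the associated cost `beta` per punished defector is
#' shared equally among all punishing individuals. A conditional punisher
#' (M) contributes like a cooperator, pays a permanent observation cost
#' `gamma`, and joins the punishment only when the number of unconditional
#' punishers in the group reaches the threshold `H`.
#'
#' @param G Group size (integer, at least 2).
#' @param r Synergy factor; the social dilemma requires `1 < r < G`.
#' @param c Contribution to the common pool (payoff units, positive).
#' @param alpha Fine imposed on each defector by each active punisher
#'   (payoff units, non-negative).
#' @param beta Punishment cost per punished defector, shared equally among
#'   the punishing individuals (payoff units, non-negative).
#' @param gamma Observation cost paid permanently by conditional punishers
#'   (payoff units, non-negative).
#' @param H Threshold number of unconditional punishers that triggers the
#'   conditional punishers; integer with `0 < H < G`.
#'
#' @return An object of class `"cp_params"`: a named list of the validated
#'   parameters.
#' @examples
#' game_params()                      # the baseline well-mixed parameters
#' game_params(r = 2, beta = 0.8)    # the lattice parameter set
#' @export
game_params <- function(G = 5L, r = 3, c = 1, alpha = 1, beta = 0.7,
                        gamma = 0.05, H = 1L) {
  stopifnot(length(G) == 1, length(r) == 1, length(c) == 1,
            length(alpha) == 1, length(beta) == 1, length(gamma) == 1,
            length(H) == 1)
  if (!is.finite(G) || G < 2 || G != round(G))
    stop("invalid G: group size must be an integer >= 2")
  if (!is.finite(r) || r <= 1 || r >= G)
    stop("invalid r: the synergy factor must satisfy 1 < r < G")
  if (!is.finite(c) || c <= 0)
    stop("invalid c: the contribution must satisfy c > 0")
  if (!is.finite(alpha) || alpha < 0)
    stop("invalid alpha: the fine must satisfy alpha >= 0")
  if (!is.finite(beta) || beta < 0)
    stop("invalid beta: the punishment cost must satisfy beta >= 0")
  if (!is.finite(gamma) || gamma < 0)
    stop("invalid gamma: the observation cost must satisfy gamma >= 0")
  if (!is.finite(H) || H != round(H) || H <= 0 || H >= G)
    stop("invalid H: the threshold must be an integer with 0 < H < G")
  structure(list(G = as.integer(G), r = as.numeric(r), c = as.numeric(c),
                 alpha = as.numeric(alpha), beta = as.numeric(beta),
                 gamma = as.numeric(gamma), H = as.integer(H)),
            class = "cp_params")
}

#' @export
print.cp_params <- function(x, ...) {
  cat("Conditional-punishment public goods game\n")
  cat(sprintf("  G = %d, r = %g, c = %g\n", x$G, x$r, x$c))
  cat(sprintf("  alpha = %g, beta = %g, gamma = %g, H = %d\n",
              x$alpha, x$beta, x$gamma, x$H))
  invisible(x)
}

as_params <- function(params) {
  if (inherits(params, "cp_params")) return(params)
  do.call(game_params, as.list(params))
}

#' Critical fine for the defector-punisher edge
#'
#' The fine level `(G - r) c / (G (G - 1))` above which the all-punisher
#' state `z = 1` on the defector-punisher edge becomes stable and a single
#' unstable interior equilibrium appears.
#'
#' @param params A [game_params()] object.
#' @return The critical fine (payoff units).
#' @export
alpha_crit <- function(params) {
  params <- as_params(params)
  (params$G - params$r) * params$c / (params$G * (params$G - 1))
}
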