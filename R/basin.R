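#' Sample initial conditions on a simplex
#'
#' Uniform sampling (flat Dirichlet) on the `k`-strategy simplex, or a
#' deterministic barycentric grid with roughly `n` points.
#'
#' @param n Number of samples (for the grid: a target; the realised count
#'   is the nearest achievable grid size).
#' @param k Number of strategies (simplex dimension + 1).
#' @param sampler `"uniform_simplex"` or `"grid"`.
#' @return An `n x k` matrix of frequency vectors, rows summing to 1.
#' @export
sample_simplex <- function(n, k = 4, sampler = c("uniform_simplex", "grid")) {
  sampler <- match.arg(sampler)
  if (sampler == "uniform_simplex") {
    e <- matrix(rexp(n * k), n, k)
    e / rowSums(e)
  } else {
    m <- 1L
    while (choose(m + k - 1, k - 1) < n) m <- m + 1L
    pts <- barycentric_grid(m, k)
    pts / m
  }
}

barycentric_grid <- function(m, k) {
  if (k == 1) return(matrix(m, 1, 1))
  rows <- lapply(0:m, function(i) {
    sub <- barycentric_grid(m - i, k - 1)
    cbind(i, sub)
  })
  unname(do.call(rbind, rows))
}

#' Basin of attraction of the cooperative equilibria
#'
#' Samples initial conditions on the simplex spanned by the given
#' strategies, integrates the replicator dynamics for each, and reports
#' the fraction converging to the cooperative (defector-free) attractor
#' versus the all-defector vertex. Trajectories still unresolved after the
#' horizon (doubled once internally) are counted and reported separately,
#' never dropped.
#'
#' @param params A [game_params()] object.
#' @param n_samples Number of initial conditions.
#' @param seed RNG seed (required for the random sampler).
#' @param sampler `"uniform_simplex"` (default) or `"grid"`.
#' @param strategies_used Character subset of `c("C","D","P","M")` spanning
#'   the sampled sub-simplex; strategies left out start (and stay) at
#'   frequency zero.
#' @param eps Endpoint threshold (see [classify_endpoint()]).
#' @param t_max Integration horizon.
#' @param rtol,atol Integrator tolerances.
#' @param stat_tol Stationarity threshold for the cooperative endpoint.
#' @return A list of class `"cp_basin"`: `cooperative_fraction`,
#'   `defection_fraction`, `unresolved` (count), `n_samples`, `seed`, and
#'   the per-sample `classification` factor.
#' @examples
#' \donttest{
#' p <- game_params(H = 1)
#' basin_fraction(p, n_samples = 200, seed = 1)
#' }
#' @export
basin_fraction <- function(params, n_samples = 10000, seed = NULL,
                           sampler = c("uniform_simplex", "grid"),
                           strategies_used = strategies(), eps = 1e-3,
                           t_max = 1e4, rtol = 1e-8, atol = 1e-10,
                           stat_tol = 1e-8) {
  params <- as_params(params)
  sampler <- match.arg(sampler)
  idx <- match_strategy(strategies_used)
  if (anyDuplicated(idx)) stop("duplicate strategies")
  if (!is.null(seed)) set.seed(seed)
  sub <- sample_simplex(n_samples, k = length(idx), sampler = sampler)
  states <- matrix(0, nrow(sub), 4)
  states[, idx] <- sub
  cls <- classify_states_cpp(states, unclass(params), eps, t_max, rtol,
                             atol, stat_tol)
  classification <- factor(c("UNRESOLVED", "DEFECTION", "COOPERATIVE")[cls + 1],
                           levels = c("COOPERATIVE", "DEFECTION", "UNRESOLVED"))
  n <- length(cls)
  structure(list(cooperative_fraction = mean(cls == 2),
                 defection_fraction = mean(cls == 1),
                 unresolved = sum(cls == 0),
                 n_samples = n,
                 seed = seed,
                 sampler = sampler,
                 strategies_used = strategies_used,
                 classification = classification),
            class = "cp_basin")
}

#' @export
print.cp_basin <- function(x, ...) {
  cat(sprintf(
    "Basin of attraction over %d initial conditions (%s on {%s}):\n",
    x$n_samples, x$sampler, paste(x$strategies_used, collapse = ",")))
  cat(sprintf("  cooperative: %.1f%%   defection: %.1f%%   unresolved: %d\n",
              100 * x$cooperative_fraction, 100 * x$defection_fraction,
              x$unresolved))
  invisible(x)
}

#' Basin fraction on a three-strategy face
#'
#' The faces of the simplex are invariant under the replicator dynamics,
#' so the basin computation restricted to a face (for instance the
#' C-D-P triangle, the game without conditional punishers) is exact.
#'
#' @param params A [game_params()] object.
#' @param face Character vector of exactly three strategies.
#' @param ... Passed to [basin_fraction()].
#' @inheritParams basin_fraction
#' @return See [basin_fraction()].
#' @export
face_basin_fraction <- function(params, face = c("C", "D", "P"),
                                n_samples = 10000, seed = NULL, ...) {
  if (length(face) != 3) stop("a face is spanned by exactly 3 strategies")
  basin_fraction(params, n_samples = n_samples, seed = seed,
                 strategies_used = face, ...)
}
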