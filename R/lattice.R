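#' Initialise a square-lattice population
#'
#' An `L x L` grid with periodic boundaries; every site is assigned a
#' strategy from `strategy_set` independently with equal probability. The
#' three-strategy control (the game without conditional punishers) uses
#' `strategy_set = c("C", "D", "P")`.
#'
#' @param L Side length (`L >= 4`).
#' @param strategy_set Strategies to draw from.
#' @param seed RNG seed.
#' @return Integer matrix of strategy codes (1 = C, 2 = D, 3 = P, 4 = M)
#'   of class `"cp_lattice"`.
#' @export
init_lattice <- function(L, strategy_set = strategies(), seed = NULL) {
  stopifnot(L >= 4)
  codes <- match_strategy(strategy_set)
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(codes[sample.int(length(codes), L * L, replace = TRUE)], L, L)
  class(g) <- c("cp_lattice", class(g))
  g
}

lattice_codes <- function(state) {
  g <- unclass(state)
  if (!is.matrix(g) || nrow(g) != ncol(g) ||
      !all(g %in% 1:4))
    stop("invalid lattice state")
  storage.mode(g) <- "integer"
  g
}

vn_neighbours <- function(i, j, L) {
  cbind(c((i - 2) %% L + 1, i %% L + 1, i, i),
        c(j, j, (j - 2) %% L + 1, j %% L + 1))
}

#' Total payoff of a lattice site
#'
#' Each player belongs to `G = 5` overlapping groups: the group centred on
#' itself and the four groups centred on its von Neumann neighbours. The
#' total payoff is the sum of the single-group payoffs over these five
#' groups, with the group composition taken over the focal's four
#' co-members in each group.
#'
#' @param state A lattice from [init_lattice()].
#' @param site Length-2 vector `(row, column)`, 1-based.
#' @param params A [game_params()] object (must have `G = 5`).
#' @return Total payoff (payoff units).
#' @export
site_total_payoff <- function(state, site, params) {
  params <- as_params(params)
  if (params$G != 5)
    stop("the lattice game uses von Neumann groups of size G = 5")
  g <- lattice_codes(state)
  L <- nrow(g)
  i <- site[1]; j <- site[2]
  stopifnot(i >= 1, i <= L, j >= 1, j <= L)
  focal <- strategies()[g[i, j]]
  centres <- rbind(c(i, j), vn_neighbours(i, j, L))
  tot <- 0
  for (k in seq_len(nrow(centres))) {
    members <- rbind(centres[k, , drop = FALSE],
                     vn_neighbours(centres[k, 1], centres[k, 2], L))
    self <- members[, 1] == i & members[, 2] == j
    co <- members[!self, , drop = FALSE]
    comp <- tabulate(g[cbind(co[, 1], co[, 2])], nbins = 4)
    tot <- tot + group_payoff(focal, comp, params)
  }
  tot
}

#' One elementary Monte Carlo step (reference implementation)
#'
#' Picks a random site `u`, a random von Neumann neighbour `v`; if their
#' strategies differ, `u` adopts `v`'s strategy with the Fermi probability
#' computed from the two current total payoffs. This is the readable
#' R counterpart of the compiled kernel used by [run_mcs()].
#'
#' @param state A lattice from [init_lattice()].
#' @param params A [game_params()] object.
#' @param s Imitation strength.
#' @return The (possibly updated) lattice.
#' @export
mc_elementary_step <- function(state, params, s) {
  g <- lattice_codes(state)
  L <- nrow(g)
  u <- c(sample.int(L, 1), sample.int(L, 1))
  nb <- vn_neighbours(u[1], u[2], L)
  v <- nb[sample.int(4, 1), ]
  if (g[u[1], u[2]] == g[v[1], v[2]]) return(state)
  pu <- site_total_payoff(state, u, params)
  pv <- site_total_payoff(state, v, params)
  if (runif(1) < fermi(pv - pu, s)) {
    state[u[1], u[2]] <- g[v[1], v[2]]
  }
  state
}

#' Run a lattice Monte Carlo simulation
#'
#' Asynchronous (random sequential with replacement) updating: one Monte
#' Carlo step (MCS) consists of `L^2` elementary steps, so every player
#' has one imitation opportunity on average per MCS. Payoffs of the two
#' players involved in an elementary step are recomputed from the current
#' configuration, never cached.
#'
#' @param state A lattice from [init_lattice()] (or `NULL` to initialise
#'   internally from `L` and `strategy_set`).
#' @param params A [game_params()] object with `G = 5`.
#' @param s Imitation strength.
#' @param n_mcs Number of Monte Carlo steps.
#' @param seed RNG seed (also reused for internal initialisation).
#' @param snapshot_at Integer MCS times at which to store grid snapshots.
#' @param L,strategy_set Used only when `state` is `NULL`.
#' @return A list of class `"cp_lattice_run"`: `frequencies` (data frame
#'   `mcs, f_C, f_D, f_P, f_M`), `snapshots` (named list of grids),
#'   `final_grid`, `seed`, `params`, `s`.
#' @export
run_mcs <- function(state = NULL, params, s = 2, n_mcs = 1000, seed = 1L,
                    snapshot_at = integer(0), L = 100,
                    strategy_set = strategies()) {
  params <- as_params(params)
  if (params$G != 5)
    stop("the lattice game uses von Neumann groups of size G = 5")
  stopifnot(n_mcs >= 1)
  set.seed(seed)
  if (is.null(state)) state <- init_lattice(L, strategy_set)
  g <- lattice_codes(state)
  res <- run_mcs_cpp(g, unclass(params), s, as.integer(n_mcs),
                     as.integer(snapshot_at))
  freq <- as.data.frame(res$freq)
  names(freq) <- paste0("f_", strategies())
  freq <- cbind(mcs = 0:n_mcs, freq)
  structure(list(frequencies = freq, snapshots = res$snapshots,
                 final_grid = res$final_grid, seed = seed, params = params,
                 s = s),
            class = "cp_lattice_run")
}

#' @export
print.cp_lattice_run <- function(x, ...) {
  n <- nrow(x$frequencies)
  cat(sprintf("Lattice run: L = %d, %d MCS, seed = %d\n",
              nrow(x$final_grid), n - 1, x$seed))
  cat("  final frequencies:",
      paste(sprintf("%s=%.3f", strategies(),
                    unlist(x$frequencies[n, -1])), collapse = ", "), "\n")
  invisible(x)
}

#' Equilibrium strategy frequencies from lattice runs
#'
#' Time-averages the strategy frequencies over the post-burn-in window of
#' each run and aggregates across runs (mean and run-to-run standard
#' deviation). A run whose post-burn-in linear frequency trend exceeds
#' `trend_tol` per MCS for any strategy is flagged as non-converged (and a
#' warning is raised) but still reported.
#'
#' @param runs A single [run_mcs()] result or a list of them.
#' @param burn_in_fraction Fraction of each run discarded as burn-in.
#' @param trend_tol Maximal absolute linear trend (frequency per MCS) for
#'   a run to count as converged.
#' @return A list with `mean` and `sd` (named over C, D, P, M),
#'   `per_run` (matrix of per-run window means), `converged` (logical per
#'   run), `n_runs`.
#' @export
equilibrium_frequencies <- function(runs, burn_in_fraction = 0.8,
                                    trend_tol = 1e-4) {
  if (inherits(runs, "cp_lattice_run")) runs <- list(runs)
  stopifnot(length(runs) >= 1, burn_in_fraction > 0, burn_in_fraction < 1)
  per_run <- matrix(NA_real_, length(runs), 4,
                    dimnames = list(NULL, strategies()))
  converged <- logical(length(runs))
  for (k in seq_along(runs)) {
    fr <- runs[[k]]$frequencies
    n <- nrow(fr)
    win <- fr[seq.int(ceiling(burn_in_fraction * n) + 1, n), ]
    per_run[k, ] <- colMeans(win[, -1])
    slopes <- vapply(2:5, function(col)
      unname(coef(lm(win[[col]] ~ win$mcs))[2]), numeric(1))
    converged[k] <- all(abs(slopes) <= trend_tol)
  }
  if (!all(converged))
    warning(sum(!converged), " run(s) failed the stationarity check")
  list(mean = colMeans(per_run),
       sd = apply(per_run, 2, stats::sd),
       per_run = per_run, converged = converged, n_runs = length(runs))
}
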