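#' Closed-form payoffs on the defector-punisher edge
#'
#' With only defectors and unconditional punishers present (punisher
#' fraction `z`, defector fraction `1 - z`), the expected payoffs have
#' closed binomial forms:
#' `P_P = (beta/z)[(1-z)^G - 1] + (rc/G)[(G-1)z + 1] + beta - c` and
#' `P_D = (rc/G - alpha)(G-1)z`. At `z = 0` the analytic limit
#' `P_P = rc/G - c + beta (1 - G)` is used.
#'
#' @param z Punisher fraction in `[0, 1]` (vectorised).
#' @param params A [game_params()] object.
#' @return A list with numeric vectors `P_P` and `P_D`.
#' @export
dp_payoffs <- function(z, params) {
  params <- as_params(params)
  G <- params$G; r <- params$r; c <- params$c
  beta <- params$beta; alpha <- params$alpha
  P_P <- ifelse(z > 0,
                beta / z * expm1(G * log1p(-pmin(z, 1))) +
                  r * c / G * ((G - 1) * z + 1) + beta - c,
                r * c / G - c + beta * (1 - G))
  P_D <- (r * c / G - alpha) * (G - 1) * z
  list(P_P = P_P, P_D = P_D)
}

#' Payoff difference on the defector-punisher edge
#'
#' `g(z) = P_P - P_D`; its roots in `(0, 1)` are the interior equilibria of
#' the two-strategy replicator dynamics `dz/dt = z (1 - z) g(z)`. The limit
#' `g(0+) = rc/G - c + beta (1 - G)` is negative for `1 < r < G`, so the
#' all-defector state is always stable on this edge, and
#' `g(1) = alpha (G - 1) + rc/G - c` is positive exactly when
#' `alpha > alpha_crit = (G - r) c / (G (G - 1))`.
#'
#' @inheritParams dp_payoffs
#' @return `g(z)` (payoff units, vectorised over `z`).
#' @export
g_function <- function(z, params) {
  p <- dp_payoffs(z, params)
  p$P_P - p$P_D
}

#' Interior equilibria on the defector-punisher edge
#'
#' Scans `g` on `n_scan` subintervals of `(0, 1]` for sign changes and
#' refines each bracketed root by bisection to `tol`. When
#' `alpha > alpha_crit` there is a single root `z*` (unstable, since `g`
#' is increasing there); when `alpha <= alpha_crit` there is none and the
#' all-defector state is the only stable edge equilibrium.
#'
#' @param params A [game_params()] object.
#' @param n_scan Number of scan subintervals.
#' @param tol Bisection tolerance on `z`.
#' @return A list with `exists` (logical), `z_star` (the root when unique,
#'   otherwise `NA`), `roots` (all roots found), `multiple` (flag set when
#'   more than one sign change is detected) and `alpha_crit`.
#' @export
find_interior_root <- function(params, n_scan = 1000, tol = 1e-10) {
  params <- as_params(params)
  zs <- seq(1e-9, 1, length.out = n_scan + 1)
  gs <- g_function(zs, params)
  sgn <- sign(gs)
  idx <- which(sgn[-length(sgn)] * sgn[-1] < 0)
  roots <- numeric(0)
  for (i in idx) {
    lo <- zs[i]; hi <- zs[i + 1]
    glo <- gs[i]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      gm <- g_function(mid, params)
      if (sign(gm) == sign(glo)) { lo <- mid; glo <- gm } else hi <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  roots <- c(roots, zs[gs == 0 & zs < 1])  # exact hits, excluding z = 1
  roots <- sort(unique(roots))
  list(exists = length(roots) > 0,
       z_star = if (length(roots) == 1) roots else NA_real_,
       roots = roots,
       multiple = length(roots) > 1,
       alpha_crit = alpha_crit(params))
}

#' Equilibrium structure of the defector-punisher edge
#'
#' Summarises the edge analysis: the two boundary equilibria with their
#' stability (read off the sign of `g` nearby) and the interior root when
#' present.
#'
#' @param params A [game_params()] object.
#' @return A list with `boundary_equilibria` (data frame of `z` and
#'   `stable`), `interior_root_z` (or `NA`), and `condition_alpha_crit`.
#' @export
dp_edge_report <- function(params) {
  params <- as_params(params)
  root <- find_interior_root(params)
  # z = 0 stable iff g(0+) < 0; z = 1 stable iff g(1) > 0
  g0 <- g_function(1e-9, params)
  g1 <- g_function(1, params)
  list(boundary_equilibria = data.frame(z = c(0, 1),
                                        stable = c(g0 < 0, g1 > 0)),
       interior_root_z = root$z_star,
       condition_alpha_crit = root$alpha_crit)
}
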