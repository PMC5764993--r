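test_that("expected payoffs match the exhaustive multinomial-sum oracle", {
  p <- wm_params()
  set.seed(4)
  for (k in 1:20) {
    st <- as.numeric(sample_simplex(1, 4))
    expect_equal(unname(expected_payoffs(st, p)),
                 unname(oracle_expected_payoffs(st, 5, 3, 1, 1.0, 0.7,
                                                0.05, 1)),
                 tolerance = 1e-10)
  }
  # homogeneous states: all-P and all-C both earn rc - c
  expect_equal(expected_payoffs(c(0, 0, 1, 0), p)[["P"]], 2.0)
  expect_equal(expected_payoffs(c(1, 0, 0, 0), p)[["C"]], 2.0)
})

test_that("average payoff is the frequency-weighted mean and convex", {
  p <- wm_params()
  expect_equal(average_payoff(c(1, 0, 0, 0), p), 2.0)
  set.seed(7)
  for (k in 1:10) {
    st <- as.numeric(sample_simplex(1, 4))
    pay <- expected_payoffs(st, p)
    pbar <- average_payoff(st, p)
    expect_gte(pbar, min(pay) - 1e-12)
    expect_lte(pbar, max(pay) + 1e-12)
  }
})

test_that("replicator rhs vanishes at vertices, sums to zero, keeps faces
           invariant", {
  p <- wm_params()
  for (v in 1:4) {
    st <- numeric(4); st[v] <- 1
    expect_equal(unname(replicator_rhs(st, p)), rep(0, 4))
  }
  set.seed(11)
  for (k in 1:10) {
    st <- as.numeric(sample_simplex(1, 4))
    expect_equal(sum(replicator_rhs(st, p)), 0, tolerance = 1e-12)
  }
  # y = 0 faces stay at y = 0 (boundary invariance)
  st <- c(0.3, 0, 0.5, 0.2)
  expect_equal(replicator_rhs(st, p)[["y"]], 0)
})

test_that("on the defector-free C-P edge selection is neutral", {
  p <- wm_params()
  for (x in c(0.2, 0.5, 0.8)) {
    rhs <- replicator_rhs(c(x, 0, 1 - x, 0), p)
    expect_equal(max(abs(rhs)), 0, tolerance = 1e-12)
  }
})

test_that("closed-form edge payoffs equal the multinomial expectation on a
           101-point grid", {
  p <- wm_params()
  zs <- seq(0, 1, length.out = 101)
  cf <- dp_payoffs(zs, p)
  for (i in seq_along(zs)) {
    z <- zs[i]
    pay <- expected_payoffs(c(0, 1 - z, z, 0), p)
    if (z > 0) expect_equal(cf$P_P[i], pay[["P"]], tolerance = 1e-10)
    if (z < 1) expect_equal(cf$P_D[i], pay[["D"]], tolerance = 1e-10)
  }
})

test_that("edge rhs reduces to z(1-z)(P_P - P_D) with the closed forms", {
  p <- wm_params()
  for (z in c(0.25, 0.5, 0.9)) {
    rhs <- replicator_rhs(c(0, 1 - z, z, 0), p)
    cf <- dp_payoffs(z, p)
    expect_equal(rhs[["z"]], z * (1 - z) * (cf$P_P - cf$P_D),
                 tolerance = 1e-10)
  }
})

test_that("g has the printed limit values and root structure", {
  p <- wm_params()
  expect_equal(g_function(1e-12, p), -3.2, tolerance = 1e-6)
  expect_equal(g_function(1, p), 3.6, tolerance = 1e-12)
  expect_equal(alpha_crit(p), 0.1)

  # above the critical fine: one unstable interior root, both ends stable
  root <- find_interior_root(p)
  expect_true(root$exists)
  expect_false(root$multiple)
  expect_gt(root$z_star, 0); expect_lt(root$z_star, 1)
  expect_equal(g_function(root$z_star, p), 0, tolerance = 1e-8)
  rep <- dp_edge_report(p)
  expect_equal(rep$boundary_equilibria$stable, c(TRUE, TRUE))

  # below the critical fine: no interior root, z = 1 unstable
  p_lo <- game_params(G = 5, r = 3, c = 1, alpha = 0.05, beta = 0.7,
                      gamma = 0.05, H = 1)
  root_lo <- find_interior_root(p_lo)
  expect_false(root_lo$exists)
  rep_lo <- dp_edge_report(p_lo)
  expect_equal(rep_lo$boundary_equilibria$stable, c(TRUE, FALSE))

  # exactly at the critical fine g(1) = 0 and no root in (0, 1)
  p_cr <- game_params(G = 5, r = 3, c = 1, alpha = 0.1, beta = 0.7,
                      gamma = 0.05, H = 1)
  expect_equal(g_function(1, p_cr), 0, tolerance = 1e-12)
  expect_false(any(find_interior_root(p_cr)$roots < 1 - 1e-6))
})

test_that("trajectories stay on the simplex and vertices are fixed", {
  p <- wm_params()
  tr <- integrate_replicator(c(0.1, 0.3, 0.5, 0.1), p, t_max = 500)
  expect_true(max(abs(rowSums(tr$states) - 1)) < 1e-6)
  expect_true(all(tr$states >= 0))
  expect_true(all(diff(tr$times) > 0))

  trD <- integrate_replicator(c(0, 1, 0, 0), p, t_max = 100)
  expect_equal(unname(trD$states[nrow(trD$states), ]), c(0, 1, 0, 0),
               tolerance = 1e-9)
  expect_identical(trD$terminal_class, "DEFECTION")

  # y = 0 faces are invariant along the whole trajectory
  tr0 <- integrate_replicator(c(0.3, 0, 0.4, 0.3), p, t_max = 500)
  expect_true(max(tr0$states[, "y"]) < 1e-9)
})

test_that("endpoint classification follows the attractor geometry", {
  p <- wm_params()
  expect_identical(classify_endpoint(c(0, 1, 0, 0), p), "DEFECTION")
  expect_identical(classify_endpoint(c(0.4, 0, 0.6, 0), p), "COOPERATIVE")
  expect_identical(classify_endpoint(c(0.25, 0.25, 0.25, 0.25), p),
                   "UNRESOLVED")
})

test_that("the compiled basin classifier agrees with the deSolve
           integrator", {
  p <- wm_params()
  set.seed(33)
  states <- sample_simplex(8, 4)
  slow <- vapply(seq_len(nrow(states)), function(i)
    integrate_replicator(states[i, ], p, t_max = 2000)$terminal_class,
    character(1))
  fast <- condpunish:::classify_states_cpp(states, unclass(p), 1e-3, 2000,
                                           1e-8, 1e-10, 1e-8)
  fast <- c("UNRESOLVED", "DEFECTION", "COOPERATIVE")[fast + 1]
  resolved <- slow != "UNRESOLVED" & fast != "UNRESOLVED"
  expect_gt(sum(resolved), 0)
  expect_identical(slow[resolved], fast[resolved])
})

test_that("below the critical fine the D-P edge always falls to defection", {
  p_lo <- game_params(G = 5, r = 3, c = 1, alpha = 0.05, beta = 0.7,
                      gamma = 0.05, H = 1)
  # sample on the open D-P edge; all trajectories must reach all-D
  zs <- c(0.1, 0.35, 0.6, 0.85, 0.99)
  states <- cbind(0, 1 - zs, zs, 0)
  cls <- condpunish:::classify_states_cpp(states, unclass(p_lo), 1e-3, 1e4,
                                          1e-8, 1e-10, 1e-8)
  expect_true(all(cls == 1))
})

test_that("basin sampling is reproducible and accounts for every sample", {
  p <- wm_params()
  b1 <- basin_fraction(p, n_samples = 60, seed = 5)
  b2 <- basin_fraction(p, n_samples = 60, seed = 5)
  expect_equal(b1$cooperative_fraction, b2$cooperative_fraction)
  expect_equal(b1$cooperative_fraction + b1$defection_fraction +
                 b1$unresolved / b1$n_samples, 1)
  expect_identical(length(b1$classification), 60L)
})

test_that("grid sampler covers the simplex deterministically", {
  g <- sample_simplex(50, 3, sampler = "grid")
  expect_true(all(abs(rowSums(g) - 1) < 1e-12))
  expect_gte(nrow(g), 50)
  expect_identical(g, sample_simplex(50, 3, sampler = "grid"))
})
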