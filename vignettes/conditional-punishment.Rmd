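---
title: "Conditional punishment in the public goods game: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional punishment in the public goods game: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condpunish)
```

## The model

`condpunish` implements a public goods game with four strategies. Groups of
`G` players form; every non-defector contributes `c` to a common pool,
which is multiplied by the synergy factor `r` (with `1 < r < G`, so that
contributing is collectively beneficial but individually costly) and split
equally among all `G` members. Besides pure cooperators (C) and pure
defectors (D) the population contains two kinds of punishers:

* **Unconditional punishers (P)** contribute, and fine every defector in
  their group by `alpha`. Each punished defector imposes a cost `beta` on
  the punishing community, shared equally among the individuals who
  actually punish.
* **Conditional punishers (M)** contribute and pay a permanent observation
  cost `gamma` for watching the other group members. They join the
  punishment only when the number of unconditional punishers in the group
  reaches a threshold `H` (an integer with `0 < H < G`); otherwise they
  behave as pure cooperators. The threshold captures a "sheep-flock"
  effect documented experimentally: people punish more readily when others
  already do.

Writing `N_C, N_D, N_P, N_M` for the counts among the `G - 1` co-players
of a focal individual and `δ(u)` for the closed Heaviside step
(`δ(u) = 1` iff `u >= 0`), the single-group payoffs are

$$
\begin{aligned}
\Pi_C &= \tfrac{r c (G - N_D)}{G} - c,\\
\Pi_D &= \tfrac{r c (G - N_D - 1)}{G} - \big[N_P + \delta(N_P - H) N_M\big]\,\alpha,\\
\Pi_P &= \Pi_C - \frac{N_D\,\beta}{N_P + \delta(N_P + 1 - H) N_M + 1},\\
\Pi_M &= \Pi_C - \delta(N_P - H)\,\frac{N_D\,\beta}{N_P + N_M + 1} - \gamma.
\end{aligned}
$$

Two conventions deserve emphasis because they are easy to get wrong. First,
compositions count **co-players only**; the focal individual is added back
inside the formulas. Second, the threshold is evaluated asymmetrically: a
focal P counts *itself* toward the trigger seen by the conditional
co-punishers (`δ(N_P + 1 - H)`), while a focal M tests only the
unconditional punishers around it (`δ(N_P - H)`). We also implement the
cost-share denominator of `Π_M` exactly as written — it counts all
conditional punishers in the group (`N_P + N_M + 1`) even though the
trigger uses only the unconditional ones — and deliberately do not
"harmonise" it with the `Π_P` denominator.

The default parameters (`G = 5`, `c = 1`, `r = 3`, `alpha = 1`,
`beta = 0.7`, `gamma = 0.05`, `H = 1`) are the well-mixed baseline used
throughout; the lattice studies use `r = 2`, `beta = 0.8`.

## Infinite well-mixed populations

With frequencies `(x, y, z, w)` on the simplex, each strategy's expected
payoff is the exact multinomial mixture of single-group payoffs over all
compositions of the `G - 1` co-players (35 terms for `G = 5`), and the
replicator equation `dx_i/dt = x_i (P_i - P̄)` drives the dynamics.
Although only three equations are independent, we integrate all four and
renormalise — symmetry makes the scheme simpler and numerically robust.

Every trajectory ends either at the all-defector vertex or on the
defector-free segment where cooperators and unconditional punishers mix
neutrally (conditional punishers die out there because of `gamma`). On the
defector–punisher edge the payoffs have closed binomial forms
(`dp_payoffs()`), and the edge equilibrium structure switches exactly at
the critical fine `alpha_crit = (G - r) c / (G (G - 1))`: above it a single
unstable interior equilibrium `z*` separates the basins of `z = 0` and
`z = 1`. `find_interior_root()` locates `z*` by scanning the exact payoff
difference `g(z)` on 1000 subintervals of `(0, 1]` and bisecting to
`1e-10`; we do not rely on the linearised approximation of `g`, which is
only good for arguing monotonicity.

```{r edge}
p <- game_params()       # G = 5, r = 3, alpha = 1, beta = 0.7, H = 1
alpha_crit(p)
find_interior_root(p)$z_star
```

### Basin-of-attraction estimation

`basin_fraction()` samples initial conditions, integrates each trajectory
with a compiled adaptive Cash–Karp Runge–Kutta 5(4) scheme
(`rtol = 1e-8`, `atol = 1e-10`), renormalises onto the simplex after every
accepted step, and classifies the endpoint:

* **defection** when `y > 1 - eps`,
* **cooperative** when `y < eps`, `w < eps` *and* the state is stationary
  (`max |rhs| < 1e-8`),
* **unresolved** otherwise, after a horizon of `t_max = 1e4` time units
  doubled once. Unresolved trajectories are counted and reported, never
  silently dropped or relabelled.

The classification threshold is `eps = 1e-3`. The stationarity test
matters: part of the defector-free segment (near the all-C corner) is
transversally *unstable*, and a state passing close to it has a tiny but
growing defector frequency — requiring `max |rhs| < 1e-8` prevents
misclassifying such states as cooperative. Trajectories near the
separatrix converge slowly, which is why the horizon is generous and
doubled once before giving up.

The sampling measure is uniform on the simplex (flat Dirichlet, drawn as
normalised exponentials) — "fraction of the strategy space" most naturally
means uniform measure. A deterministic barycentric grid is available as an
alternative because the original study does not state its sampling scheme;
the two agree to within Monte Carlo error. Faces of the simplex are
invariant under the replicator dynamics, so `face_basin_fraction()`
computes the three-strategy game (for example the game without conditional
punishers) exactly by sampling with the fourth frequency at zero.

At the baseline parameters the cooperative basin covers about 61% of the
simplex for `H = 1` and about 42% for `H = 3`, against about 49% for the
three-strategy face without conditional punishers (10^4 samples; Monte
Carlo standard error about 0.5 percentage points). This is the
double-edged sword: an easy punishment trigger enlarges the cooperative
basin relative to the game without conditional punishers, a hard trigger
shrinks it.

## Finite well-mixed populations

For a population of size `N`, expected payoffs replace the multinomial by
the multivariate hypergeometric: the `G - 1` co-players are drawn without
replacement from the other `N - 1` individuals
(`finite_expected_payoffs()`). We evaluate the sums by exhaustive
enumeration of co-player compositions with hypergeometric weights rather
than transcribing the printed nested-binomial forms, one of which carries
an apparent index typo; the composition sum is the unambiguous ground
truth and reproduces the closed form available for cooperators. A payoff
is undefined (reported `NA`) for a strategy that is absent — the focal is
excluded from its own sampling pool.

Imitation follows the pairwise-comparison (Fermi) rule
`q = 1 / (1 + exp(-s (P_v - P_u)))` with imitation strength `s >= 0`
(`fermi()` uses `plogis`, so it saturates cleanly). The fixation
probability of a single mutant (`fixation_probability()`) is computed by
two algebraically equivalent routes — the birth–death product over ratios
of transition probabilities, and the exponential-sum simplification — and
the implementation cross-checks them to `1e-10`. Both accumulate in log
space because `s` times a payoff sum can exceed the floating-point
exponent range. Neutral pairs give exactly `1/N` at any `s`.

In the rare-mutation limit the population hops between homogeneous states,
and `embedded_markov_chain()` builds the 4×4 chain with off-diagonal
entries `rho_ij / 3`. Its stationary distribution is the normalised left
unit eigenvector; a numerically multiple unit eigenvalue (a reducible
chain, as in the strong-imitation limit where the all-defector state is
absorbing) is flagged rather than hidden. In the strong-imitation limit
the matrix collapses to a closed form (`strong_imitation_matrix()`) whose
stationary vector is exactly `(0, 1, 0, 0)` — with rare mutations and
strong imitation the population ends in full defection, the classic
second-order free-rider outcome.

```{r chain}
stationary_distribution(strong_imitation_matrix(100))
```

`simulate_wellmixed()` runs the individual-based mutation–selection
process. The default mutation kernel switches a player to one of the
*other three* strategies with probability `mu/3` each, which is the
process whose rare-mutation limit the embedded chain describes; a uniform
redraw over all four (effective switch rate `3mu/4`) is available as an
option. The compiled kernel uses R's RNG, so `set.seed()` (or the seed
recorded in the output attributes) reproduces a run bit-for-bit.

## Structured populations

`run_mcs()` stages the game on an `L × L` lattice with periodic boundaries
and von Neumann neighbourhoods. Every player belongs to `G = 5`
overlapping groups — its own and its four neighbours' — and its total
payoff is the sum over those five groups. One Monte Carlo step (MCS) is
`L^2` elementary updates drawn randomly with replacement: pick a site, a
random neighbour, and imitate with the Fermi probability computed from the
two *current* total payoffs (payoffs are recomputed at every elementary
step, never cached, to avoid stale-payoff artefacts; the evaluation is
local, touching at most 25 sites, so each step is O(1) in `L`). Whether
the neighbour is drawn before or after checking for equal strategies is
observationally irrelevant; we skip the Fermi draw when the strategies
already agree.

`equilibrium_frequencies()` averages the final 20% of each run and
aggregates mean and run-to-run standard deviation over seeds, flagging any
run whose post-burn-in linear frequency trend exceeds `1e-4` per MCS. The
burn-in fraction, averaging window and trend tolerance are package
choices; the original study reports none.

### What the lattice runs show — and a caveat

At the lattice parameters (`r = 2`, `alpha = 1`, `beta = 0.8`, `s = 2`)
the dynamics is effectively bistable: after an initial defector surge,
either the surviving punisher clusters expand and the defectors go
extinct, or no viable cluster survives and defectors fix. With `H = 1`
conditional punishers amplify the punishment early on and the population
reliably reaches the defector-free C/P phase, with `M` extinct (it pays
`gamma` for nothing once defectors are gone). This qualitative picture —
and a flat-interface payoff calculation showing that a punisher front
strictly dominates a defector front at these parameters — means the model
as specified does **not** admit a stable defector–punisher coexistence:
ensemble averages of the punisher frequency reflect the fraction of runs
that reach the all-P outcome and depend on lattice size, rather than
settling at an interior coexistence value. Users comparing against
published coexistence frequencies for this parameter set should be aware
that those values are not reproducible from the payoff equations
implemented (and unit-tested) here, while the well-mixed results of the
same model are. The package reports what the equations produce, with
run-to-run spread, and flags non-stationary runs.

## Numerical choices and problem sizes

* Basin estimates in the tests and the reproduction script use 10^4
  initial conditions per parameter set — enough for ~0.5 pp standard
  error, and a few minutes of CPU per basin.
* Lattice ensembles use `L = 50`, `2×10^4` MCS and 10 seeds per
  parameter set. A size-robustness test checks that `L = 40` and `L = 60`
  give compatible cooperative outcomes.
* Finite-population cross-checks run at `N` up to 4000 (where the
  hypergeometric payoffs match the infinite-population payoffs to below
  `1e-2`) and Markov-chain sizes of `N = 20`–100.
* Root finding and the fixation-form cross-check are carried to `1e-10`;
  simplex drift is kept below `1e-6` along trajectories.

## What the synthetic dynamics does and does not show

All data in this package are generated by the simulators themselves; there
is no external input. The models capture the strategic feedback the theory
is about — threshold-triggered punishment, cost sharing, spatial
clustering — under mathematically clean conditions: infinite or
well-mixed populations, regular lattices, homogeneous parameters, a single
threshold `H` shared by all conditional punishers. Passing tests therefore
validate the implementation of the stated dynamics, not the behaviour of
real human groups: heterogeneous thresholds, noisy payoff perception,
network irregularity and anti-social punishment are all outside scope.
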