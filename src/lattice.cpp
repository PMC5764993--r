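#include "game.h"
using namespace Rcpp;

// Total payoff of one site: sum of single-group payoffs over the G = 5
// overlapping von Neumann groups the site belongs to (the group centred on
// the site plus the four groups centred on its neighbours).
static double site_payoff_c(const int* g, int L, int site, const int* nbr,
                            const GameParams& p) {
  const int focal = g[site];
  double tot = 0.0;
  int centres[5];
  centres[0] = site;
  for (int k = 0; k < 4; ++k) centres[k + 1] = nbr[4 * site + k];
  for (int c = 0; c < 5; ++c) {
    const int ctr = centres[c];
    int n[4] = {0, 0, 0, 0};
    if (ctr != site) ++n[g[ctr]];
    for (int k = 0; k < 4; ++k) {
      const int m = nbr[4 * ctr + k];
      if (m != site) ++n[g[m]];
    }
    tot += group_payoff_c(focal, n[0], n[1], n[2], n[3], p);
  }
  return tot;
}

static void build_neighbours(int L, std::vector<int>& nbr) {
  nbr.resize(4 * (size_t)L * L);
  for (int i = 0; i < L; ++i)
    for (int j = 0; j < L; ++j) {
      const int s = i * L + j;
      const int up = ((i - 1 + L) % L) * L + j;
      const int dn = ((i + 1) % L) * L + j;
      const int lf = i * L + (j - 1 + L) % L;
      const int rt = i * L + (j + 1) % L;
      nbr[4 * s + 0] = up;
      nbr[4 * s + 1] = dn;
      nbr[4 * s + 2] = lf;
      nbr[4 * s + 3] = rt;
    }
}

// [[Rcpp::export]]
double site_total_payoff_cpp(IntegerMatrix grid, int i, int j, List params) {
  GameParams p = params_from_list(params);
  const int L = grid.nrow();
  std::vector<int> g((size_t)L * L), nbr;
  for (int a = 0; a < L; ++a)
    for (int b = 0; b < L; ++b) g[a * L + b] = grid(a, b) - 1;
  build_neighbours(L, nbr);
  return site_payoff_c(g.data(), L, i * L + j, nbr.data(), p);
}

// Asynchronous Monte Carlo: one MCS = L^2 elementary steps (random
// sequential with replacement). Payoffs of the two players involved are
// recomputed from the current configuration at every elementary step.
// [[Rcpp::export]]
List run_mcs_cpp(IntegerMatrix grid, List params, double s, int n_mcs,
                 IntegerVector snapshot_at) {
  GameParams p = params_from_list(params);
  const int L = grid.nrow();
  const size_t L2 = (size_t)L * L;
  std::vector<int> g(L2), nbr;
  for (int a = 0; a < L; ++a)
    for (int b = 0; b < L; ++b) g[a * L + b] = grid(a, b) - 1;
  build_neighbours(L, nbr);

  std::vector<bool> want(n_mcs + 1, false);
  for (int k = 0; k < snapshot_at.size(); ++k)
    if (snapshot_at[k] >= 0 && snapshot_at[k] <= n_mcs)
      want[snapshot_at[k]] = true;
  List snaps;
  CharacterVector snap_names;

  NumericMatrix freq(n_mcs + 1, 4);
  long cnt[4] = {0, 0, 0, 0};
  for (size_t i = 0; i < L2; ++i) ++cnt[g[i]];

  auto record = [&](int mcs) {
    for (int f = 0; f < 4; ++f) freq(mcs, f) = (double)cnt[f] / (double)L2;
    if (want[mcs]) {
      IntegerMatrix snap(L, L);
      for (int a = 0; a < L; ++a)
        for (int b = 0; b < L; ++b) snap(a, b) = g[a * L + b] + 1;
      snaps.push_back(snap);
      snap_names.push_back(std::to_string(mcs));
    }
  };
  record(0);

  for (int mcs = 1; mcs <= n_mcs; ++mcs) {
    for (size_t e = 0; e < L2; ++e) {
      const int u = (int)(unif_rand() * L2);
      const int v = nbr[4 * u + (int)(unif_rand() * 4)];
      if (g[u] == g[v]) continue;
      const double pu = site_payoff_c(g.data(), L, u, nbr.data(), p);
      const double pv = site_payoff_c(g.data(), L, v, nbr.data(), p);
      const double q = 1.0 / (1.0 + std::exp(-s * (pv - pu)));
      if (unif_rand() < q) {
        --cnt[g[u]];
        g[u] = g[v];
        ++cnt[g[u]];
      }
    }
    record(mcs);
    if (mcs % 64 == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix final_grid(L, L);
  for (int a = 0; a < L; ++a)
    for (int b = 0; b < L; ++b) final_grid(a, b) = g[a * L + b] + 1;
  if (snaps.size() > 0) snaps.attr("names") = snap_names;
  return List::create(_["freq"] = freq, _["snapshots"] = snaps,
                      _["final_grid"] = final_grid);
}
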