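#include "game.h"
using namespace Rcpp;

static double lchoose_c(int n, int k) {
  if (k < 0 || k > n) return R_NegInf;
  return std::lgamma(n + 1.0) - std::lgamma(k + 1.0) -
         std::lgamma(n - k + 1.0);
}

// Exact expected payoff of one focal strategy in a finite population:
// co-player groups of size G-1 drawn without replacement (multivariate
// hypergeometric over the other N-1 individuals).
static double finite_payoff_c(int focal, const int cnt[4], int N,
                              const GameParams& p, const CompTable& tab) {
  int pool[4] = {cnt[0], cnt[1], cnt[2], cnt[3]};
  pool[focal] -= 1;  // the focal is excluded from its own sampling pool
  const double ldenom = lchoose_c(N - 1, p.G - 1);
  double pay = 0.0;
  for (size_t i = 0; i < tab.comps.size(); ++i) {
    const auto& cp = tab.comps[i];
    double lw = -ldenom;
    bool feasible = true;
    for (int s = 0; s < 4; ++s) {
      if (cp[s] > pool[s]) { feasible = false; break; }
      lw += lchoose_c(pool[s], cp[s]);
    }
    if (!feasible) continue;
    pay += std::exp(lw) * group_payoff_c(focal, cp[0], cp[1], cp[2], cp[3], p);
  }
  return pay;
}

// [[Rcpp::export]]
NumericVector finite_expected_payoffs_cpp(IntegerVector counts, List params) {
  GameParams p = params_from_list(params);
  CompTable tab(p.G);
  const int cnt[4] = {counts[0], counts[1], counts[2], counts[3]};
  const int N = cnt[0] + cnt[1] + cnt[2] + cnt[3];
  NumericVector out(4, NA_REAL);
  for (int f = 0; f < 4; ++f)
    if (cnt[f] > 0) out[f] = finite_payoff_c(f, cnt, N, p, tab);
  return out;
}

// Mutation-selection individual-based simulation (discrete time). Per step:
// pick u at random; with probability mu mutate u's strategy, otherwise pick
// a random role model v != u and imitate with Fermi probability. Uses the
// R RNG so runs are reproducible through set.seed().
// [[Rcpp::export]]
IntegerMatrix simulate_wellmixed_cpp(IntegerVector counts0, List params,
                                     double s, double mu, double n_steps,
                                     int record_every, bool mutate_all_four) {
  GameParams p = params_from_list(params);
  CompTable tab(p.G);
  int cnt[4] = {counts0[0], counts0[1], counts0[2], counts0[3]};
  const int N = cnt[0] + cnt[1] + cnt[2] + cnt[3];
  const long long steps = (long long)n_steps;
  const long long n_rec = steps / record_every + 1;
  IntegerMatrix rec(n_rec, 5);
  long long ri = 0;

  // payoff cache for the current composition (states persist many steps)
  double pay[4];
  int cached[4] = {-1, -1, -1, -1};
  auto payoffs = [&]() {
    if (cnt[0] != cached[0] || cnt[1] != cached[1] || cnt[2] != cached[2] ||
        cnt[3] != cached[3]) {
      for (int f = 0; f < 4; ++f)
        pay[f] = cnt[f] > 0 ? finite_payoff_c(f, cnt, N, p, tab) : 0.0;
      for (int f = 0; f < 4; ++f) cached[f] = cnt[f];
    }
  };
  auto strat_of_index = [&](int idx, int skip, int skip_strat) {
    // idx in 0..(pool-1) over individuals, optionally skipping one player
    for (int f = 0; f < 4; ++f) {
      int m = cnt[f] - (skip && f == skip_strat ? 1 : 0);
      if (idx < m) return f;
      idx -= m;
    }
    return 3;  // unreachable for valid idx
  };

  for (long long step = 0; step < steps; ++step) {
    if (step % record_every == 0) {
      rec(ri, 0) = (int)std::min<long long>(step, INT_MAX);
      for (int f = 0; f < 4; ++f) rec(ri, f + 1) = cnt[f];
      ++ri;
    }
    if (step % 65536 == 0) Rcpp::checkUserInterrupt();
    const int su = strat_of_index((int)(unif_rand() * N), 0, -1);
    if (unif_rand() < mu) {
      int snew;
      if (mutate_all_four) {
        snew = (int)(unif_rand() * 4);
      } else {
        snew = (int)(unif_rand() * 3);       // one of the other three
        if (snew >= su) ++snew;
      }
      --cnt[su]; ++cnt[snew];
    } else {
      const int sv = strat_of_index((int)(unif_rand() * (N - 1)), 1, su);
      if (sv != su) {
        payoffs();
        const double q = 1.0 / (1.0 + std::exp(-s * (pay[sv] - pay[su])));
        if (unif_rand() < q) { --cnt[su]; ++cnt[sv]; }
      }
    }
  }
  if (ri < n_rec) {
    rec(ri, 0) = (int)std::min<long long>(steps, INT_MAX);
    for (int f = 0; f < 4; ++f) rec(ri, f + 1) = cnt[f];
  }
  return rec;
}
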