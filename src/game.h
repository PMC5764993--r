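#pragma once
#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>

// Strategy codes shared with the R side: 0 = C, 1 = D, 2 = P, 3 = M.

struct GameParams {
  int G, H;
  double r, c, alpha, beta, gamma;
};

inline GameParams params_from_list(const Rcpp::List& p) {
  GameParams g;
  g.G = Rcpp::as<int>(p["G"]);
  g.H = Rcpp::as<int>(p["H"]);
  g.r = Rcpp::as<double>(p["r"]);
  g.c = Rcpp::as<double>(p["c"]);
  g.alpha = Rcpp::as<double>(p["alpha"]);
  g.beta = Rcpp::as<double>(p["beta"]);
  g.gamma = Rcpp::as<double>(p["gamma"]);
  return g;
}

inline int heaviside_i(int u) { return u >= 0 ? 1 : 0; }

// Payoff of a focal player from one group; counts are over the G-1
// co-players only (the focal is added back inside the formula where the
// convention requires it, e.g. a focal P counts itself toward the
// threshold while a focal M does not).
inline double group_payoff_c(int focal, int nC, int nD, int nP, int nM,
                             const GameParams& p) {
  (void)nC;
  const double pc = p.r * p.c * (p.G - nD) / p.G - p.c;
  switch (focal) {
  case 0:
    return pc;
  case 1:
    return p.r * p.c * (p.G - nD - 1) / p.G -
           (nP + heaviside_i(nP - p.H) * nM) * p.alpha;
  case 2:
    return pc - nD * p.beta / (nP + heaviside_i(nP + 1 - p.H) * nM + 1);
  default:
    return pc - heaviside_i(nP - p.H) * nD * p.beta / (nP + nM + 1) -
           p.gamma;
  }
}

// All 4-part compositions of G-1 co-players, with log multinomial
// coefficients (used for exact expected payoffs in mixed populations).
struct CompTable {
  std::vector<std::array<int, 4>> comps;
  std::vector<double> lmultinom;
  explicit CompTable(int G) {
    const int n = G - 1;
    const double lf_n = std::lgamma(n + 1.0);
    for (int a = 0; a <= n; ++a)
      for (int b = 0; b <= n - a; ++b)
        for (int c = 0; c <= n - a - b; ++c) {
          int d = n - a - b - c;
          comps.push_back({a, b, c, d});
          lmultinom.push_back(lf_n - std::lgamma(a + 1.0) -
                              std::lgamma(b + 1.0) - std::lgamma(c + 1.0) -
                              std::lgamma(d + 1.0));
        }
  }
};
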