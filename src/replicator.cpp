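#include "game.h"
using namespace Rcpp;

// Expected payoffs P_i for a mixed state on the simplex: exhaustive sum of
// multinomial co-player compositions times single-group payoffs.
static void expected_payoffs_c(const double s[4], const GameParams& p,
                               const CompTable& tab, double out[4]) {
  const int n = p.G - 1;
  // power tables avoid pow() in the inner loop
  std::vector<double> xp(n + 1, 1.0), yp(n + 1, 1.0), zp(n + 1, 1.0),
      wp(n + 1, 1.0);
  for (int k = 1; k <= n; ++k) {
    xp[k] = xp[k - 1] * s[0];
    yp[k] = yp[k - 1] * s[1];
    zp[k] = zp[k - 1] * s[2];
    wp[k] = wp[k - 1] * s[3];
  }
  out[0] = out[1] = out[2] = out[3] = 0.0;
  for (size_t i = 0; i < tab.comps.size(); ++i) {
    const auto& cp = tab.comps[i];
    const double w = std::exp(tab.lmultinom[i]) * xp[cp[0]] * yp[cp[1]] *
                     zp[cp[2]] * wp[cp[3]];
    if (w == 0.0) continue;
    for (int f = 0; f < 4; ++f)
      out[f] += w * group_payoff_c(f, cp[0], cp[1], cp[2], cp[3], p);
  }
}

static void rhs_c(const double s[4], const GameParams& p,
                  const CompTable& tab, double out[4]) {
  double pay[4];
  expected_payoffs_c(s, p, tab, pay);
  const double pbar =
      s[0] * pay[0] + s[1] * pay[1] + s[2] * pay[2] + s[3] * pay[3];
  for (int i = 0; i < 4; ++i) out[i] = s[i] * (pay[i] - pbar);
}

// [[Rcpp::export]]
NumericVector expected_payoffs_cpp(NumericVector state, List params) {
  GameParams p = params_from_list(params);
  CompTable tab(p.G);
  double s[4] = {state[0], state[1], state[2], state[3]};
  double out[4];
  expected_payoffs_c(s, p, tab, out);
  return NumericVector::create(out[0], out[1], out[2], out[3]);
}

// [[Rcpp::export]]
NumericVector replicator_rhs_cpp(NumericVector state, List params) {
  GameParams p = params_from_list(params);
  CompTable tab(p.G);
  double s[4] = {state[0], state[1], state[2], state[3]};
  double out[4];
  rhs_c(s, p, tab, out);
  return NumericVector::create(out[0], out[1], out[2], out[3]);
}

// Cash-Karp embedded Runge-Kutta 5(4) step; returns max |err/scale|.
static double ck_step(const double y[4], double h, const GameParams& p,
                      const CompTable& tab, const double k1[4],
                      double ynew[4], double rtol, double atol) {
  static const double a21 = 1.0 / 5,
      a31 = 3.0 / 40, a32 = 9.0 / 40,
      a41 = 3.0 / 10, a42 = -9.0 / 10, a43 = 6.0 / 5,
      a51 = -11.0 / 54, a52 = 5.0 / 2, a53 = -70.0 / 27, a54 = 35.0 / 27,
      a61 = 1631.0 / 55296, a62 = 175.0 / 512, a63 = 575.0 / 13824,
      a64 = 44275.0 / 110592, a65 = 253.0 / 4096,
      b1 = 37.0 / 378, b3 = 250.0 / 621, b4 = 125.0 / 594, b6 = 512.0 / 1771,
      d1 = b1 - 2825.0 / 27648, d3 = b3 - 18575.0 / 48384,
      d4 = b4 - 13525.0 / 55296, d5 = -277.0 / 14336, d6 = b6 - 1.0 / 4;
  double k2[4], k3[4], k4[4], k5[4], k6[4], t[4];
  for (int i = 0; i < 4; ++i) t[i] = y[i] + h * a21 * k1[i];
  rhs_c(t, p, tab, k2);
  for (int i = 0; i < 4; ++i) t[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
  rhs_c(t, p, tab, k3);
  for (int i = 0; i < 4; ++i)
    t[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
  rhs_c(t, p, tab, k4);
  for (int i = 0; i < 4; ++i)
    t[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
  rhs_c(t, p, tab, k5);
  for (int i = 0; i < 4; ++i)
    t[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                       a64 * k4[i] + a65 * k5[i]);
  rhs_c(t, p, tab, k6);
  double errmax = 0.0;
  for (int i = 0; i < 4; ++i) {
    ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b6 * k6[i]);
    const double err =
        h * (d1 * k1[i] + d3 * k3[i] + d4 * k4[i] + d5 * k5[i] + d6 * k6[i]);
    const double scale = atol + rtol * std::fabs(ynew[i]);
    errmax = std::max(errmax, std::fabs(err) / scale);
  }
  return errmax;
}

// Classify one initial condition: 0 = unresolved, 1 = defection (y -> 1),
// 2 = cooperative (defector-free segment of C and P).
static int classify_one(double y0[4], const GameParams& p,
                        const CompTable& tab, double eps, double tmax,
                        double rtol, double atol, double stat_tol) {
  double y[4] = {y0[0], y0[1], y0[2], y0[3]};
  double t = 0.0, h = 0.01;
  double k1[4], ynew[4];
  // horizon doubled once if the first pass does not resolve
  for (int pass = 0; pass < 2; ++pass) {
    const double tend = tmax * (pass + 1);
    while (t < tend) {
      rhs_c(y, p, tab, k1);
      // endpoint tests on the current state
      if (y[1] > 1.0 - eps) return 1;
      if (y[1] < eps && y[3] < eps) {
        double nrm = 0.0;
        for (int i = 0; i < 4; ++i) nrm = std::max(nrm, std::fabs(k1[i]));
        if (nrm < stat_tol) return 2;
      }
      if (h > tend - t) h = tend - t;
      double errmax = ck_step(y, h, p, tab, k1, ynew, rtol, atol);
      if (errmax <= 1.0) {
        t += h;
        double sum = 0.0;
        for (int i = 0; i < 4; ++i) {
          y[i] = ynew[i] < 0.0 ? 0.0 : ynew[i];
          sum += y[i];
        }
        if (std::fabs(sum - 1.0) > 1e-13)
          for (int i = 0; i < 4; ++i) y[i] /= sum;
        h *= std::min(5.0, 0.9 * std::pow(errmax, -0.2));
        if (h > 50.0) h = 50.0;
      } else {
        h *= std::max(0.1, 0.9 * std::pow(errmax, -0.25));
        if (h < 1e-12) return 0;  // step underflow: give up honestly
      }
    }
  }
  return 0;
}

// [[Rcpp::export]]
IntegerVector classify_states_cpp(NumericMatrix states, List params,
                                  double eps, double tmax, double rtol,
                                  double atol, double stat_tol) {
  GameParams p = params_from_list(params);
  CompTable tab(p.G);
  const int n = states.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double y0[4] = {states(i, 0), states(i, 1), states(i, 2), states(i, 3)};
    out[i] = classify_one(y0, p, tab, eps, tmax, rtol, atol, stat_tol);
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
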