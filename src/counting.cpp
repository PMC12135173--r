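#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Hot path of the counting model: per-region recombination-pattern
// distributions by phase-matrix multiplication.  Mirrors the R reference
// implementations (h_matrix / g_matrix / chain_pattern_distribution), which
// stay the documented API and the cross-check in the test suite.

// number of t-terms after which the neglected mass of the renewal sum is
// below tol (b_t <= 1, so the Poisson upper tail beyond 1 + T bounds it)
static int truncation_length(double lambda, int m, double tol) {
  int cap = (int) std::ceil(10.0 * (m + 1) + lambda + 10.0 * std::sqrt(lambda));
  int T = (int) R::qpois(1.0 - tol, lambda, 1, 0) - 1;
  if (T < 0) T = 0;
  while (R::ppois(1.0 + T, lambda, 0, 0) >= tol) {
    ++T;
    if (T > cap)
      stop("event-count sum did not converge within the hard cap");
  }
  return T;
}

// fills M0 = G/2 + H and M1 = G/2 for one interval (order mp1 = m + 1)
static void transition_pair(double lambda, const std::vector<double> &gam,
                            double tol, std::vector<double> &M0,
                            std::vector<double> &M1) {
  const int mp1 = (int) gam.size();
  const int m = mp1 - 1;
  std::fill(M0.begin(), M0.end(), 0.0);
  std::fill(M1.begin(), M1.end(), 0.0);
  if (lambda == 0.0) {            // no events: phase unchanged, no chiasma
    for (int i = 0; i < mp1; ++i) M0[i * mp1 + i] = 1.0;
    return;
  }
  const int T = truncation_length(lambda, m, tol);
  // renewal coefficients b_0..b_T
  std::vector<double> b(T + 1, 0.0);
  b[0] = 1.0;
  for (int t = 1; t <= T; ++t) {
    double acc = 0.0;
    for (int g = 0; g <= m && g <= t - 1; ++g)
      if (gam[g] > 0.0) acc += gam[g] * b[t - 1 - g];
    b[t] = acc;
  }
  // f(c) = sum_t b_t Pois(c + t; lambda), c = 1..cmax
  const int cmax = 2 * m + 1;
  std::vector<double> dp(cmax + T + 1);
  for (int x = 0; x <= cmax + T; ++x) dp[x] = R::dpois(x, lambda, 0);
  std::vector<double> f(cmax + 1, 0.0);
  for (int c = 1; c <= cmax; ++c) {
    double acc = 0.0;
    for (int t = 0; t <= T; ++t) acc += b[t] * dp[c + t];
    f[c] = acc;
  }
  // row i, column j (stored row-major: index i * mp1 + j)
  for (int i = 0; i < mp1; ++i) {
    for (int j = 0; j < mp1; ++j) {
      double g = 0.0;
      for (int s = j; s <= m; ++s) {
        if (gam[s] <= 0.0) continue;
        int c = i + 1 + s - j;
        if (c >= 1 && c <= cmax) g += gam[s] * f[c];
      }
      double h = (i >= j) ? dp[i - j] : 0.0;
      M1[i * mp1 + j] = 0.5 * g;
      M0[i * mp1 + j] = 0.5 * g + h;
    }
  }
}

//' @noRd
// [[Rcpp::export(name = ".chain_distributions_cpp")]]
List chain_distributions_cpp(List chains, NumericVector gamma,
                             NumericVector omega, double tol) {
  const int mp1 = gamma.size();
  if (omega.size() != mp1) stop("gamma and omega must have equal length");
  std::vector<double> gam(gamma.begin(), gamma.end());
  List out(chains.size());
  std::vector<double> M0((size_t) mp1 * mp1), M1((size_t) mp1 * mp1);
  for (int ci = 0; ci < chains.size(); ++ci) {
    NumericVector lam = chains[ci];
    const int n = lam.size();
    if (n > 24) stop("chain too long to enumerate (n > 24)");
    const size_t npat = (size_t) 1 << n;
    // states: npat rows (pattern prefixes) x mp1 phase columns
    std::vector<double> cur(npat * mp1, 0.0), nxt(npat * mp1, 0.0);
    for (int j = 0; j < mp1; ++j) cur[j] = omega[j];
    size_t rows = 1;
    for (int k = 0; k < n; ++k) {
      if (lam[k] < 0) stop("negative event rate");
      transition_pair(lam[k], gam, tol, M0, M1);
      for (size_t p = 0; p < rows; ++p) {
        const double *v = &cur[p * mp1];
        double *o0 = &nxt[p * mp1];
        double *o1 = &nxt[(p + rows) * mp1];
        for (int j = 0; j < mp1; ++j) {
          double a0 = 0.0, a1 = 0.0;
          for (int i = 0; i < mp1; ++i) {
            a0 += v[i] * M0[i * mp1 + j];
            a1 += v[i] * M1[i * mp1 + j];
          }
          o0[j] = a0;
          o1[j] = a1;
        }
      }
      rows <<= 1;
      std::swap(cur, nxt);
    }
    NumericVector dist(rows);
    for (size_t p = 0; p < rows; ++p) {
      double s = 0.0;
      for (int j = 0; j < mp1; ++j) s += cur[p * mp1 + j];
      dist[p] = s;
    }
    out[ci] = dist;
  }
  return out;
}
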