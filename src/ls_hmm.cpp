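// Scaled-linear dynamic-programming engines for the Li-Stephens
// haplotype-copying HMM over one window of typed variants.
//
// Layout: H is V x N (rows = typed variants in window order, columns =
// reference haplotypes = states), g is the observed query allele sequence
// over the window, rho[j] is the per-state recombination probability
// between variants j-1 and j (rho[0] unused; the start is uniform).
//
// Values are kept in the linear domain and multiplied by an integer power
// of a scaling factor whenever the column maximum leaves the configured
// band; the accumulated exponent is folded back when the log matrix is
// returned, so callers always see exact log values.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

// Rescale the working column so its maximum returns inside [lo, hi];
// accumulates the applied exponent (in units of slog) into kacc.
inline void rescale(std::vector<double>& v, double lo, double hi,
                    double slog, long& kacc) {
  double m = 0.0;
  for (double x : v) if (x > m) m = x;
  if (m <= 0.0) stop("degenerate window: DP column underflowed to zero");
  if (m >= lo && m <= hi) return;
  long k = (long)std::floor(std::log(m) / slog);
  double f = std::exp(-(double)k * slog);
  for (double& x : v) x *= f;
  kacc += k;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_ls_forward(IntegerMatrix H, IntegerVector g,
                             NumericVector rho, double eps,
                             double slog, double band_lo, double band_hi) {
  const int V = H.nrow(), N = H.ncol();
  NumericMatrix logmat(V, N);
  std::vector<double> f(N);
  long K = 0;
  const double e1 = 1.0 - eps;
  for (int a = 0; a < N; ++a)
    f[a] = (1.0 / N) * (H(0, a) == g[0] ? e1 : eps);
  rescale(f, band_lo, band_hi, slog, K);
  for (int a = 0; a < N; ++a) logmat(0, a) = std::log(f[a]) + K * slog;
  for (int j = 1; j < V; ++j) {
    const double pr = rho[j];
    const double pnr = 1.0 - (N - 1) * pr;
    double S = 0.0;
    for (int a = 0; a < N; ++a) S += f[a];
    for (int a = 0; a < N; ++a) {
      const double e = (H(j, a) == g[j]) ? e1 : eps;
      // sum over b of tau(b->a) F(b) = (pnr - pr) F(a) + pr S
      f[a] = e * ((pnr - pr) * f[a] + pr * S);
    }
    rescale(f, band_lo, band_hi, slog, K);
    for (int a = 0; a < N; ++a) logmat(j, a) = std::log(f[a]) + K * slog;
  }
  return logmat;
}

// [[Rcpp::export]]
NumericMatrix cpp_ls_backward(IntegerMatrix H, IntegerVector g,
                              NumericVector rho, double eps,
                              double slog, double band_lo, double band_hi) {
  const int V = H.nrow(), N = H.ncol();
  NumericMatrix logmat(V, N);
  std::vector<double> b(N), w(N);
  long K = 0;
  const double e1 = 1.0 - eps;
  for (int a = 0; a < N; ++a) b[a] = 1.0 / N;
  for (int a = 0; a < N; ++a) logmat(V - 1, a) = std::log(b[a]);
  for (int j = V - 2; j >= 0; --j) {
    const double pr = rho[j + 1];
    const double pnr = 1.0 - (N - 1) * pr;
    double S = 0.0;
    for (int a = 0; a < N; ++a) {
      const double e = (H(j + 1, a) == g[j + 1]) ? e1 : eps;
      w[a] = e * b[a];
      S += w[a];
    }
    for (int a = 0; a < N; ++a) b[a] = (pnr - pr) * w[a] + pr * S;
    rescale(b, band_lo, band_hi, slog, K);
    for (int a = 0; a < N; ++a) logmat(j, a) = std::log(b[a]) + K * slog;
  }
  return logmat;
}

// [[Rcpp::export]]
List cpp_ls_viterbi(IntegerMatrix H, IntegerVector g,
                    NumericVector rho, double eps,
                    double slog, double band_lo, double band_hi) {
  const int V = H.nrow(), N = H.ncol();
  NumericMatrix logmat(V, N);
  IntegerMatrix bp(V, N);
  std::vector<double> v(N);
  long K = 0;
  const double e1 = 1.0 - eps;
  for (int a = 0; a < N; ++a)
    v[a] = (1.0 / N) * (H(0, a) == g[0] ? e1 : eps);
  rescale(v, band_lo, band_hi, slog, K);
  for (int a = 0; a < N; ++a) logmat(0, a) = std::log(v[a]) + K * slog;
  for (int j = 1; j < V; ++j) {
    const double pr = rho[j];
    const double pnr = 1.0 - (N - 1) * pr;
    int best = 0;
    for (int a = 1; a < N; ++a) if (v[a] > v[best]) best = a;
    const double jump = pr * v[best];
    for (int a = 0; a < N; ++a) {
      const double e = (H(j, a) == g[j]) ? e1 : eps;
      const double stay = pnr * v[a];
      if (stay >= jump) {            // self-transition preferred on ties
        v[a] = e * stay;
        bp(j, a) = a + 1;
      } else {
        v[a] = e * jump;
        bp(j, a) = best + 1;
      }
    }
    // v was overwritten in place; the stay term for state a only reads
    // v[a] before writing it, and jump was frozen beforehand, so the
    // in-place update is safe.
    rescale(v, band_lo, band_hi, slog, K);
    for (int a = 0; a < N; ++a) logmat(j, a) = std::log(v[a]) + K * slog;
  }
  int last = 0;
  for (int a = 1; a < N; ++a) if (v[a] > v[last]) last = a;
  IntegerVector path(V);
  path[V - 1] = last + 1;
  for (int j = V - 1; j >= 1; --j) path[j - 1] = bp(j, path[j] - 1);
  return List::create(_["logmat"] = logmat, _["path"] = path,
                      _["logp"] = std::log(v[last]) + K * slog);
}
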