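#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Round half away from zero (matches round_half_away() on the R side).
static inline double round_half_away(double x) {
  return (x < 0) ? -std::floor(-x + 0.5) : std::floor(x + 0.5);
}

// JDistEn of one pair from precomputed per-channel column summaries.
//
// vals holds the unique upper-triangle joint distances (i < j). Each
// off-diagonal entry of the joint distance matrix appears twice (the matrix
// is symmetric), so histogram masses and skewness computed from the unique
// values equal those computed from both triangles; n_obv still counts both
// triangles, (P^2 - P), as the binning rule prescribes.
static double jdisten_from_values(std::vector<double> &vals, const double n_obv) {
  const size_t nv = vals.size();

  // population skewness g1 = m3 / m2^1.5, 0 for constant input
  double mu = 0.0;
  for (size_t t = 0; t < nv; ++t) mu += vals[t];
  mu /= (double)nv;
  double m2 = 0.0, m3 = 0.0;
  for (size_t t = 0; t < nv; ++t) {
    const double d = vals[t] - mu;
    m2 += d * d;
    m3 += d * d * d;
  }
  m2 /= (double)nv;
  m3 /= (double)nv;
  const double g1 = (m2 > 0.0) ? m3 / std::pow(m2, 1.5) : 0.0;

  const double sigma_g1 =
      std::sqrt(6.0 * (n_obv - 2.0) / ((n_obv + 1.0) * (n_obv + 3.0)));
  const double b_raw =
      1.0 + std::log2(n_obv) + std::log2(1.0 + std::fabs(g1) / sigma_g1);
  int bins = (int)round_half_away(b_raw);
  if (bins < 2) bins = 2;

  double lo = vals[0], hi = vals[0];
  for (size_t t = 1; t < nv; ++t) {
    if (vals[t] < lo) lo = vals[t];
    if (vals[t] > hi) hi = vals[t];
  }
  if (hi <= lo) return 0.0;  // all mass in one bin: zero entropy

  std::vector<double> counts(bins, 0.0);
  const double width = hi - lo;
  for (size_t t = 0; t < nv; ++t) {
    int k = (int)std::floor((vals[t] - lo) / width * bins);
    if (k > bins - 1) k = bins - 1;  // rightmost bin closed
    counts[k] += 1.0;
  }

  double h = 0.0;
  for (int k = 0; k < bins; ++k) {
    if (counts[k] > 0.0) {
      const double rho = counts[k] / (double)nv;
      h -= rho * std::log2(rho);
    }
  }
  return h / std::log2((double)bins);
}

// [[Rcpp::export]]
NumericMatrix cpp_coupling_matrix(NumericMatrix x, int m, int tau,
                                  bool chebyshev) {
  const int nc = x.nrow();        // channels
  const int ns = x.ncol();        // samples
  const int n = m * tau;          // trailing margin
  const int P = ns - n;           // state vectors per channel
  if (P < 3) stop("series too short for embedding");

  // Per-channel, per-column summaries. Range norm needs only the column
  // max/min; Chebyshev needs the full embedded columns.
  std::vector<std::vector<double>> cmax(nc), cmin(nc);
  std::vector<std::vector<double>> emb;  // [channel][k * P + i]
  if (chebyshev) emb.resize(nc);
  for (int c = 0; c < nc; ++c) {
    cmax[c].resize(P);
    cmin[c].resize(P);
    if (chebyshev) emb[c].resize((size_t)m * P);
    for (int i = 0; i < P; ++i) {
      double hi = x(c, i), lo = x(c, i);
      for (int k = 0; k < m; ++k) {
        const double v = x(c, i + k * tau);
        if (v > hi) hi = v;
        if (v < lo) lo = v;
        if (chebyshev) emb[c][(size_t)k * P + i] = v;
      }
      cmax[c][i] = hi;
      cmin[c][i] = lo;
    }
  }

  const double n_obv = (double)P * (double)P - (double)P;
  NumericMatrix w(nc, nc);
  std::vector<double> vals((size_t)P * (P - 1) / 2);

  for (int a = 0; a < nc; ++a) {
    for (int b = a + 1; b < nc; ++b) {
      size_t t = 0;
      if (!chebyshev) {
        const std::vector<double> &Ma = cmax[a], &ma = cmin[a];
        const std::vector<double> &Mb = cmax[b], &mb = cmin[b];
        for (int i = 0; i < P; ++i) {
          for (int j = i + 1; j < P; ++j) {
            const double d1 = std::max(Ma[i] - ma[j], Ma[j] - ma[i]);
            const double d2 = std::max(Mb[i] - mb[j], Mb[j] - mb[i]);
            vals[t++] = 1.0 - std::sqrt((1.0 - d1) * (1.0 - d2));
          }
        }
      } else {
        const std::vector<double> &ea = emb[a], &eb = emb[b];
        for (int i = 0; i < P; ++i) {
          for (int j = i + 1; j < P; ++j) {
            double d1 = 0.0, d2 = 0.0;
            for (int k = 0; k < m; ++k) {
              const double da = std::fabs(ea[(size_t)k * P + i] - ea[(size_t)k * P + j]);
              const double db = std::fabs(eb[(size_t)k * P + i] - eb[(size_t)k * P + j]);
              if (da > d1) d1 = da;
              if (db > d2) d2 = db;
            }
            vals[t++] = 1.0 - std::sqrt((1.0 - d1) * (1.0 - d2));
          }
        }
      }
      const double jde = jdisten_from_values(vals, n_obv);
      w(a, b) = jde;
      w(b, a) = jde;
    }
  }
  return w;
}
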