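#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Felsenstein pruning for one partition under HKY+Gamma on a fixed topology.
//
// edge      : postorder edge matrix (parent, child), 1-based ape node ids,
//             tips are ids 1..ntip and the root is the parent of the last edge
// edge_len  : branch lengths in expected substitutions/site (before `mult`)
// tip_pat   : ntip x npat integer matrix of base codes 0..3 (A,C,G,T);
//             code -1 means "missing" (all four states equally compatible)
// weights   : pattern multiplicities
// V, d, Vinv: eigen system of the normalised HKY rate matrix Q = V diag(d) Vinv
// pi        : stationary base frequencies (A,C,G,T)
// cat_rates : discrete-Gamma category rate multipliers (equal weights)
// mult      : partition rate multiplier applied to every branch
// [[Rcpp::export]]
double cpp_partition_loglik(const IntegerMatrix& edge,
                            const NumericVector& edge_len,
                            int ntip,
                            const IntegerMatrix& tip_pat,
                            const NumericVector& weights,
                            const NumericMatrix& V,
                            const NumericVector& d,
                            const NumericMatrix& Vinv,
                            const NumericVector& pi,
                            const NumericVector& cat_rates,
                            double mult) {
  const int nedge = edge.nrow();
  const int npat = tip_pat.ncol();
  const int ncat = cat_rates.size();
  const int nnode = ntip + nedge / 2 + 1;  // binary tree: internal = nedge/2 + 1
  const int root = edge(nedge - 1, 0);

  std::vector<double> sitelik(npat, 0.0);
  std::vector<double> part((size_t)nnode * 4 * npat);
  std::vector<char> seen(nnode, 0);
  double P[4][4];

  for (int c = 0; c < ncat; ++c) {
    std::fill(part.begin(), part.end(), 0.0);
    std::fill(seen.begin(), seen.end(), 0);

    for (int e = 0; e < nedge; ++e) {
      const int par = edge(e, 0) - 1;
      const int chd = edge(e, 1) - 1;
      const double t = edge_len[e] * mult * cat_rates[c];
      // P(t) = V diag(exp(d t)) Vinv
      double ed[4];
      for (int k = 0; k < 4; ++k) ed[k] = std::exp(d[k] * t);
      for (int a = 0; a < 4; ++a)
        for (int b = 0; b < 4; ++b) {
          double s = 0.0;
          for (int k = 0; k < 4; ++k) s += V(a, k) * ed[k] * Vinv(k, b);
          P[a][b] = s > 0.0 ? s : 0.0;
        }

      double* pp = &part[(size_t)par * 4 * npat];
      if (!seen[par]) {
        std::fill(pp, pp + 4 * npat, 1.0);
        seen[par] = 1;
      }
      if (chd < ntip) {
        for (int s = 0; s < npat; ++s) {
          const int b = tip_pat(chd, s);
          if (b < 0) continue;  // missing: sum_b P[a][b]*1 = 1, no-op
          for (int a = 0; a < 4; ++a) pp[a * npat + s] *= P[a][b];
        }
      } else {
        const double* cp = &part[(size_t)chd * 4 * npat];
        for (int s = 0; s < npat; ++s) {
          for (int a = 0; a < 4; ++a) {
            double v = 0.0;
            for (int b = 0; b < 4; ++b) v += P[a][b] * cp[b * npat + s];
            pp[a * npat + s] *= v;
          }
        }
      }
    }

    const double* rp = &part[(size_t)(root - 1) * 4 * npat];
    for (int s = 0; s < npat; ++s) {
      double v = 0.0;
      for (int a = 0; a < 4; ++a) v += pi[a] * rp[a * npat + s];
      sitelik[s] += v / ncat;
    }
  }

  double ll = 0.0;
  for (int s = 0; s < npat; ++s) {
    double v = sitelik[s];
    if (v < 1e-300) v = 1e-300;
    ll += weights[s] * std::log(v);
  }
  return ll;
}
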