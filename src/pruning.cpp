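#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Felsenstein pruning over compressed site patterns for one partition.
//
// edge: (nedge x 2) 1-based node ids in postorder (every child row precedes
//   the row where that node is a parent); node ids follow ape convention
//   (tips 1..ntip, internals ntip+1..).
// blen: expected substitutions per edge (rate x duration), before the
//   per-category rate multiplier.
// tipdat: (ntip x npat) integer codes 0..3 = A,C,G,T; 4 = missing/ambiguous.
// evec/ievec/eval: eigendecomposition of the scaled GTR rate matrix,
//   Q = evec %*% diag(eval) %*% ievec, so P(t) = evec diag(exp(eval t)) ievec.
// catrate/catw: discrete mixture of rate categories (weights sum to 1; a
//   zero rate encodes the invariant-sites class).
//
// Returns per-pattern log-likelihoods (length npat).

// [[Rcpp::export]]
NumericVector peel_loglik_cpp(IntegerMatrix edge, int ntip,
                              NumericVector blen, IntegerMatrix tipdat,
                              NumericMatrix evec, NumericMatrix ievec,
                              NumericVector eval, NumericVector freq,
                              NumericVector catrate, NumericVector catw) {
  const int nedge = edge.nrow();
  const int npat = tipdat.ncol();
  const int ncat = catrate.size();
  const int nnode = ntip + nedge + 1;  // upper bound on node ids (rooted)

  NumericMatrix sitell(ncat, npat);    // log lik per category per pattern
  std::vector<double> partial(static_cast<size_t>(nnode) * 4 * npat);
  std::vector<double> scaler(static_cast<size_t>(nnode) * npat);
  std::vector<char> seen(nnode, 0);
  double P[16];

  int root = edge(nedge - 1, 0) - 1;   // last postorder row's parent

  for (int c = 0; c < ncat; ++c) {
    std::fill(seen.begin(), seen.end(), 0);
    for (int e = 0; e < nedge; ++e) {
      int par = edge(e, 0) - 1;
      int chd = edge(e, 1) - 1;
      // transition matrix for this branch/category
      double t = blen[e] * catrate[c];
      double ex[4];
      for (int k = 0; k < 4; ++k) ex[k] = std::exp(eval[k] * t);
      for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j) {
          double s = 0.0;
          for (int k = 0; k < 4; ++k) s += evec(i, k) * ex[k] * ievec(k, j);
          P[4 * i + j] = s > 0.0 ? s : 0.0;  // clip eigen round-off
        }
      double *pp = &partial[static_cast<size_t>(par) * 4 * npat];
      double *ps = &scaler[static_cast<size_t>(par) * npat];
      if (!seen[par]) {
        std::fill(pp, pp + 4 * npat, 1.0);
        std::fill(ps, ps + npat, 0.0);
        seen[par] = 1;
      }
      if (chd < ntip) {
        for (int s = 0; s < npat; ++s) {
          int st = tipdat(chd, s);
          double down[4];
          if (st < 4)
            for (int i = 0; i < 4; ++i) down[i] = P[4 * i + st];
          else
            for (int i = 0; i < 4; ++i) down[i] = 1.0;
          for (int i = 0; i < 4; ++i) pp[4 * s + i] *= down[i];
        }
      } else {
        double *cp = &partial[static_cast<size_t>(chd) * 4 * npat];
        double *cs = &scaler[static_cast<size_t>(chd) * npat];
        for (int s = 0; s < npat; ++s) {
          double down[4];
          for (int i = 0; i < 4; ++i) {
            double v = 0.0;
            for (int j = 0; j < 4; ++j) v += P[4 * i + j] * cp[4 * s + j];
            down[i] = v;
          }
          double mx = 0.0;
          for (int i = 0; i < 4; ++i) {
            pp[4 * s + i] *= down[i];
            if (pp[4 * s + i] > mx) mx = pp[4 * s + i];
          }
          ps[s] += cs[s];
          if (mx < 1e-250 && mx > 0.0) {  // rescale against underflow
            for (int i = 0; i < 4; ++i) pp[4 * s + i] /= mx;
            ps[s] += std::log(mx);
          }
        }
      }
    }
    double *rp = &partial[static_cast<size_t>(root) * 4 * npat];
    double *rs = &scaler[static_cast<size_t>(root) * npat];
    for (int s = 0; s < npat; ++s) {
      double v = 0.0;
      for (int i = 0; i < 4; ++i) v += freq[i] * rp[4 * s + i];
      sitell(c, s) = (v > 0.0 ? std::log(v) : R_NegInf) + rs[s];
    }
  }

  // mix categories in linear space via log-sum-exp
  NumericVector out(npat);
  for (int s = 0; s < npat; ++s) {
    double mx = R_NegInf;
    for (int c = 0; c < ncat; ++c) {
      double lc = sitell(c, s) + std::log(catw[c]);
      if (lc > mx) mx = lc;
    }
    if (!std::isfinite(mx)) { out[s] = R_NegInf; continue; }
    double acc = 0.0;
    for (int c = 0; c < ncat; ++c)
      acc += std::exp(sitell(c, s) + std::log(catw[c]) - mx);
    out[s] = mx + std::log(acc);
  }
  return out;
}
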