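#include <Rcpp.h>
using namespace Rcpp;

// Abundance-weighted beta mean-nearest-taxon distance between all sample
// pairs. `relab` is samples x taxa (rows sum to 1 over the taxa present),
// `d` is the taxon-by-taxon patristic distance matrix in the same column
// order. For a pair (k, m):
//   0.5 * [ sum_i f_ik * min_{j in m} d(i, j) + sum_j f_jm * min_{i in k} d(j, i) ]
// with sums over taxa with nonzero abundance in the focal sample.
// [[Rcpp::export(name = ".bmntd_cpp")]]
NumericMatrix bmntd_cpp(NumericMatrix relab, NumericMatrix d) {
  const int ns = relab.nrow(), nt = relab.ncol();
  if (d.nrow() != nt || d.ncol() != nt)
    stop("distance matrix dimension does not match taxon count");

  // nonzero taxon indices per sample
  std::vector< std::vector<int> > present(ns);
  for (int s = 0; s < ns; ++s)
    for (int t = 0; t < nt; ++t)
      if (relab(s, t) > 0) present[s].push_back(t);

  NumericMatrix out(ns, ns);
  for (int k = 0; k < ns; ++k) {
    for (int m = k + 1; m < ns; ++m) {
      const std::vector<int> &pk = present[k], &pm = present[m];
      double acc = 0.0;
      for (size_t a = 0; a < pk.size(); ++a) {
        const int i = pk[a];
        double mn = R_PosInf;
        for (size_t b = 0; b < pm.size(); ++b) {
          const double v = d(i, pm[b]);
          if (v < mn) mn = v;
        }
        acc += relab(k, i) * mn;
      }
      for (size_t b = 0; b < pm.size(); ++b) {
        const int j = pm[b];
        double mn = R_PosInf;
        for (size_t a = 0; a < pk.size(); ++a) {
          const double v = d(j, pk[a]);
          if (v < mn) mn = v;
        }
        acc += relab(m, j) * mn;
      }
      out(k, m) = out(m, k) = 0.5 * acc;
    }
  }
  return out;
}

// Zero-sum Moran birth-death process on a single local community.
// Each step: one individual dies (chosen uniformly, i.e. proportional to
// taxon counts) and is replaced by the offspring of an independently,
// uniformly chosen parent from the pre-step community. Community size is
// conserved exactly. Uses R's RNG so results follow set.seed().
// [[Rcpp::export(name = ".moran_drift_cpp")]]
IntegerVector moran_drift_cpp(IntegerVector counts, double steps) {
  IntegerVector x = clone(counts);
  const int nt = x.size();
  long J = 0;
  for (int i = 0; i < nt; ++i) {
    if (x[i] < 0) stop("negative count");
    J += x[i];
  }
  if (J == 0) stop("empty community");

  RNGScope scope;
  for (double s = 0; s < steps; ++s) {
    // parent drawn from the pre-step community
    double u = unif_rand() * J;
    int birth = 0;
    for (double c = x[0]; u >= c && birth < nt - 1; c += x[++birth]) ;
    u = unif_rand() * J;
    int death = 0;
    for (double c = x[0]; u >= c && death < nt - 1; c += x[++death]) ;
    x[death] -= 1;
    x[birth] += 1;
  }
  return x;
}
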