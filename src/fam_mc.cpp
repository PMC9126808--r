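#include <Rcpp.h>
using namespace Rcpp;

// Monte-Carlo engine for the within-family conditional permutation null.
// Genotype rows are permuted uniformly among the siblings of each family,
// independently across families; burden and variance-component exceedance
// counts are accumulated from the SAME permutation stream. Inputs are
// family-centered: gc = genotype rows minus within-family column means,
// cc = per-sibling weighted burden minus its within-family mean, so the
// burden deviation B* - E[B*] is a plain sum. Uses R's RNG (set.seed
// governs determinism). Optional sequential early stopping: once both
// tests have at least `min_exceed` exceedances the p-values are resolved
// well above any extreme threshold and simulation stops.

// [[Rcpp::export]]
List fam_mc(List t_list, List gc_list, List cc_list, NumericVector w2,
            double b_obs_dev, double q_obs, double n_sims,
            double min_exceed, bool two_sided) {
  const int F = t_list.size();
  const int V = w2.size();
  std::vector<std::vector<double>> ts(F), ccs(F), gcs(F);
  std::vector<int> sz(F);
  int smax = 0;
  for (int f = 0; f < F; ++f) {
    NumericVector t = t_list[f];
    NumericVector cc = cc_list[f];
    NumericMatrix gc = gc_list[f];
    sz[f] = t.size();
    if (sz[f] > smax) smax = sz[f];
    ts[f].assign(t.begin(), t.end());
    ccs[f].assign(cc.begin(), cc.end());
    // store row-major: sibling i contiguous over variants
    gcs[f].resize((size_t)sz[f] * V);
    for (int i = 0; i < sz[f]; ++i)
      for (int v = 0; v < V; ++v)
        gcs[f][(size_t)i * V + v] = gc(i, v);
  }
  std::vector<int> perm(smax);
  std::vector<double> S(V);
  const double tolb = 1e-9 * (1.0 + std::fabs(b_obs_dev));
  const double tolq = 1e-9 * (1.0 + std::fabs(q_obs));
  double kb = 0.0, ks = 0.0, n_used = 0.0;
  for (double it = 0.0; it < n_sims; it += 1.0) {
    double B = 0.0;
    std::fill(S.begin(), S.end(), 0.0);
    for (int f = 0; f < F; ++f) {
      const int s = sz[f];
      const std::vector<double>& t = ts[f];
      const std::vector<double>& cc = ccs[f];
      const std::vector<double>& gc = gcs[f];
      if (s == 2) {                       // identity or swap, each w.p. 1/2
        const bool swap2 = unif_rand() < 0.5;
        const int i0 = swap2 ? 1 : 0, i1 = swap2 ? 0 : 1;
        B += t[0] * cc[i0] + t[1] * cc[i1];
        const double* r0 = &gc[(size_t)i0 * V];
        const double* r1 = &gc[(size_t)i1 * V];
        for (int v = 0; v < V; ++v) S[v] += t[0] * r0[v] + t[1] * r1[v];
        continue;
      }
      for (int i = 0; i < s; ++i) perm[i] = i;
      for (int i = s - 1; i > 0; --i) {   // Fisher-Yates
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(perm[i], perm[j]);
      }
      for (int i = 0; i < s; ++i) {
        const double ti = t[i];
        const int pi = perm[i];
        B += ti * cc[pi];
        const double* row = &gc[(size_t)pi * V];
        for (int v = 0; v < V; ++v) S[v] += ti * row[v];
      }
    }
    double Q = 0.0;
    for (int v = 0; v < V; ++v) Q += w2[v] * S[v] * S[v];
    const bool eb = two_sided ? (std::fabs(B) >= std::fabs(b_obs_dev) - tolb)
                              : (B >= b_obs_dev - tolb);
    if (eb) kb += 1.0;
    if (Q >= q_obs - tolq) ks += 1.0;
    n_used = it + 1.0;
    if (kb >= min_exceed && ks >= min_exceed) break;
  }
  return List::create(_["k_burden"] = kb, _["k_skat"] = ks,
                      _["n_used"] = n_used);
}
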