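// Meiosis engine for the forward-in-time population simulator.  Haplotypes
// are stored SNP-major (p rows, one column per haplotype) so that copying
// chromosome segments is cache friendly.  Crossovers follow a Poisson
// process along the genetic map (Haldane, no interference) and each SNP
// allele mutates independently at a fixed per-meiosis rate.  All randomness
// comes from R's RNG so that set.seed() gives bit-identical populations.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix drop_gametes_cpp(const IntegerMatrix& hap,
                               const IntegerVector& parent,
                               const NumericVector& pos,
                               const IntegerVector& chr_first,
                               const IntegerVector& chr_last,
                               const NumericVector& chr_len, double mu) {
  const int p = hap.nrow();
  const int n_gam = parent.size();
  const int n_chr = chr_len.size();
  IntegerMatrix out(p, n_gam);
  std::vector<double> bp;

  for (int g = 0; g < n_gam; ++g) {
    const int i = parent[g];  // 0-based individual index
    const int* h0 = &hap(0, 2 * i);
    const int* h1 = &hap(0, 2 * i + 1);
    int* og = &out(0, g);
    for (int c = 0; c < n_chr; ++c) {
      int cur = (unif_rand() < 0.5) ? 0 : 1;  // independent start per chromosome
      const int nco = (int)R::rpois(chr_len[c]);
      bp.clear();
      for (int k = 0; k < nco; ++k) bp.push_back(unif_rand() * chr_len[c]);
      std::sort(bp.begin(), bp.end());
      size_t nxt = 0;
      for (int j = chr_first[c]; j <= chr_last[c]; ++j) {
        while (nxt < bp.size() && bp[nxt] < pos[j]) {
          cur = 1 - cur;
          ++nxt;
        }
        og[j] = cur ? h1[j] : h0[j];
      }
    }
    const int nmut = (int)R::rpois(mu * (double)p);
    for (int k = 0; k < nmut; ++k) {
      int j = (int)(unif_rand() * p);
      if (j >= p) j = p - 1;
      og[j] = 1 - og[j];
    }
  }
  return out;
}
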