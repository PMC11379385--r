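// First-order Markov RNA sequence sampler (used for 3'UTR generation, which
// must carry dinucleotide structure such as CpG depletion). Randomness comes
// from R's RNG.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
std::string markov_rna_cpp(int len, NumericVector init, NumericMatrix trans) {
  if (len < 1) stop("len must be >= 1");
  if (init.size() != 4 || trans.nrow() != 4 || trans.ncol() != 4)
    stop("init must have 4 entries and trans must be 4x4");
  static const char bases[4] = {'A', 'C', 'G', 'U'};
  std::string out(len, 'A');
  auto draw = [](const double *p) {
    double u = unif_rand(), c = 0.0;
    for (int j = 0; j < 3; ++j) { c += p[j]; if (u < c) return j; }
    return 3;
  };
  std::vector<double> T(16);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) T[i * 4 + j] = trans(i, j);
  std::vector<double> p0(init.begin(), init.end());
  int s = draw(p0.data());
  out[0] = bases[s];
  for (int i = 1; i < len; ++i) {
    s = draw(&T[s * 4]);
    out[i] = bases[s];
  }
  return out;
}
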