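// Region-unpaired probabilities from a McCaskill-style inside/outside
// partition function over a base-pair-counting (Nussinov) energy model:
// every legal pair (A:U, G:C, G:U; minimum hairpin loop 3) contributes a
// fixed Boltzmann weight. For a query region [a,b] the exact probability
// that all its bases are unpaired is obtained by conditioning on the
// innermost base pair enclosing the region:
//
//   Pu(a,b) = Z(1,a-1) Z(b+1,n) / Z
//           + sum_{p<a<=b<q} p(p,q) Z(p+1,a-1) Z(b+1,q-1) / Z(p+1,q-1)
//
// where p(p,q) are pair probabilities computed by the analogous
// innermost-enclosing recursion (outside pass). 'N' is unpairable.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static const int MINLOOP = 3;          // minimal hairpin loop length
static const double PAIR_WEIGHT = 2.0; // Boltzmann weight per base pair

static inline bool legal_pair(char a, char b) {
  if (a == 'T') a = 'U';
  if (b == 'T') b = 'U';
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// [[Rcpp::export]]
NumericMatrix region_unpaired_probs_cpp(std::string seq,
                                        IntegerVector positions,
                                        int max_width) {
  const int n = (int)seq.size();
  if (n < 1) stop("empty sequence");
  if (max_width < 1) stop("max_width must be >= 1");

  // Z(i,j) over 1-based closed intervals; empty intervals (j < i) are 1.
  // Stored with 0-based offsets i-1, j-1 in (n+2)^2 for easy padding.
  auto idx = [n](int i, int j) { return i * (n + 2) + j; };
  std::vector<double> Z((n + 2) * (n + 2), 1.0), Zb((n + 2) * (n + 2), 0.0);

  auto zget = [&](int i, int j) { return (j < i) ? 1.0 : Z[idx(i, j)]; };

  for (int span = 1; span <= n; ++span) {
    for (int i = 1; i + span - 1 <= n; ++i) {
      const int j = i + span - 1;
      // Zb: i pairs j
      if (j - i > MINLOOP && legal_pair(seq[i - 1], seq[j - 1]))
        Zb[idx(i, j)] = PAIR_WEIGHT * zget(i + 1, j - 1);
      // Z: j unpaired, or j paired with some k in [i, j)
      double z = zget(i, j - 1);
      for (int k = i; k < j; ++k) {
        const double zb = Zb[idx(k, j)];
        if (zb > 0.0) z += zget(i, k - 1) * zb;
      }
      Z[idx(i, j)] = z;
    }
  }
  const double Ztot = zget(1, n);

  // collect pairable (i,j) sorted by decreasing span for the outside pass
  std::vector<int> pi, pj;
  for (int span = n; span >= MINLOOP + 2; --span)
    for (int i = 1; i + span - 1 <= n; ++i) {
      const int j = i + span - 1;
      if (Zb[idx(i, j)] > 0.0) { pi.push_back(i); pj.push_back(j); }
    }
  const int npair = (int)pi.size();

  // pair probabilities: innermost enclosing pair decomposition.
  // Enclosing pairs with negligible probability are skipped; the error is
  // bounded by npair * PRUNE, far below the reported precision.
  const double PRUNE = 1e-12;
  std::vector<double> pp((n + 2) * (n + 2), 0.0);
  std::vector<int> qi, qj;     // significant pairs (prob > PRUNE),
  std::vector<double> qp;      // in decreasing-span order
  for (int a = 0; a < npair; ++a) {
    const int i = pi[a], j = pj[a];
    double p = (Zb[idx(i, j)] / Ztot) * zget(1, i - 1) * zget(j + 1, n);
    // only significant enclosing pairs contribute measurably; spans of
    // processed pairs are >= the current span, so enclosure is possible
    for (size_t b = 0; b < qi.size(); ++b) {
      const int k = qi[b], l = qj[b];
      if (k < i && l > j) {
        p += qp[b] * Zb[idx(i, j)] * zget(k + 1, i - 1) *
             zget(j + 1, l - 1) / zget(k + 1, l - 1);
      }
    }
    pp[idx(i, j)] = p;
    if (p > PRUNE) { qi.push_back(i); qj.push_back(j); qp.push_back(p); }
  }
  const int nq = (int)qi.size();

  // query regions: window of width w ending at each position, clipped
  const int np = positions.size();
  NumericMatrix out(np, max_width);
  for (int q = 0; q < np; ++q) {
    for (int w = 1; w <= max_width; ++w) {
      int b = positions[q];
      int a = b - w + 1;
      if (a < 1) a = 1;
      if (b > n) b = n;
      if (a > n || b < 1 || a > b) { out(q, w - 1) = 1.0; continue; }
      double pu = zget(1, a - 1) * zget(b + 1, n) / Ztot;
      for (int c = 0; c < nq; ++c) {
        const int p = qi[c], r = qj[c];
        if (p < a && r > b) {
          pu += qp[c] * zget(p + 1, a - 1) * zget(b + 1, r - 1) /
                zget(p + 1, r - 1);
        }
      }
      out(q, w - 1) = pu;
    }
  }
  return out;
}
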