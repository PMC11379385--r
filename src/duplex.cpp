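// Hybridization duplex engine: gap-affine antiparallel alignment of a miRNA
// against a target RNA under a stacking-bonus energy model. Finds the
// minimum-energy duplex (local: both ends free), returning the base-pair map
// in duplex coordinates (miRNA positions increasing 5'->3', target positions
// decreasing, i.e. antiparallel), the energy, and the target site span.
// Also provides the seed-window classification core (canonical /
// non-canonical / other) shared by the single-duplex R wrappers and the
// batch scanner used by the negative-generation methods.
//
// Energy model (kcal/mol-like units, exposed via duplex_energy_params()):
//   pair:   G:C -2.2, A:U -1.1, G:U -0.6;  'N' and anything else unpairable
//   stack:  -1.0 bonus when two pairs are contiguous on both strands
//   loop:   affine, open +4.0, extend +1.0 per unpaired nucleotide
#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

static const double E_GC = -2.2, E_AU = -1.1, E_GU = -0.6;
static const double E_STACK = -1.0, GAP_OPEN = 4.0, GAP_EXT = 1.0;
static const double INF = std::numeric_limits<double>::infinity();

static inline char norm_base(char a) { return a == 'T' ? 'U' : a; }

static inline double pair_energy(char a, char b) {
  a = norm_base(a); b = norm_base(b);
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return E_GC;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return E_AU;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return E_GU;
  return INF;
}

static inline bool is_wc(char a, char b) {
  a = norm_base(a); b = norm_base(b);
  return (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'A' && b == 'U') || (a == 'U' && b == 'A');
}

static inline bool is_gu(char a, char b) {
  a = norm_base(a); b = norm_base(b);
  return (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// [[Rcpp::export]]
List duplex_energy_params_cpp() {
  return List::create(
    _["pair_gc"] = E_GC, _["pair_au"] = E_AU, _["pair_gu"] = E_GU,
    _["stack"] = E_STACK, _["gap_open"] = GAP_OPEN, _["gap_ext"] = GAP_EXT);
}

struct DuplexResult {
  std::vector<int> mi;   // miRNA positions, 1-based, increasing
  std::vector<int> tj;   // target positions, 1-based, decreasing
  double mfe;
  bool found;
};

struct DuplexWorkspace {
  std::vector<double> M, X, Y;
  std::string yr;
};

// Gotoh-style DP over x (miRNA) and the reverse of y (target).
// The workspace is reused across batch calls to avoid re-allocation.
static DuplexResult duplex_align(const std::string &x, const std::string &y,
                                 DuplexWorkspace &ws) {
  const int n = (int)x.size(), m = (int)y.size();
  DuplexResult res; res.mfe = 0.0; res.found = false;
  if (n == 0 || m == 0) return res;
  ws.yr.assign(y.rbegin(), y.rend());
  const std::string &yr = ws.yr;

  // state matrices, (n+1) x (m+1); M = ends in a pair, X = target-side gap,
  // Y = miRNA-side gap
  const size_t need = (size_t)(n + 1) * (m + 1);
  ws.M.assign(need, INF); ws.X.assign(need, INF); ws.Y.assign(need, INF);
  std::vector<double> &M = ws.M, &X = ws.X, &Y = ws.Y;
  auto id = [m](int i, int k) { return i * (m + 1) + k; };

  double best = 0.0; int bi = -1, bk = -1;
  for (int i = 1; i <= n; ++i) {
    for (int k = 1; k <= m; ++k) {
      const double pe = pair_energy(x[i - 1], yr[k - 1]);
      double mv = INF;
      if (pe < INF) {
        mv = pe;  // fresh duplex start
        const double mm = M[id(i - 1, k - 1)];
        if (mm + E_STACK + pe < mv) mv = mm + E_STACK + pe;
        const double xx = X[id(i - 1, k - 1)];
        if (xx + pe < mv) mv = xx + pe;
        const double yy = Y[id(i - 1, k - 1)];
        if (yy + pe < mv) mv = yy + pe;
      }
      M[id(i, k)] = mv;
      X[id(i, k)] = std::min(M[id(i, k - 1)] + GAP_OPEN,
                    std::min(X[id(i, k - 1)] + GAP_EXT,
                             Y[id(i, k - 1)] + GAP_OPEN));
      Y[id(i, k)] = std::min(M[id(i - 1, k)] + GAP_OPEN,
                    std::min(Y[id(i - 1, k)] + GAP_EXT,
                             X[id(i - 1, k)] + GAP_OPEN));
      if (mv < best) { best = mv; bi = i; bk = k; }
    }
  }
  if (bi < 0) return res;  // no legal pair anywhere

  // traceback from the best pair-ending cell (deterministic tie-breaking:
  // stop, then stacked pair, then target gap, then miRNA gap)
  int i = bi, k = bk, state = 0;  // 0=M, 1=X, 2=Y
  std::vector<int> mi, tk;
  while (true) {
    if (state == 0) {
      mi.push_back(i); tk.push_back(k);
      const double pe = pair_energy(x[i - 1], yr[k - 1]);
      const double v = M[id(i, k)];
      if (v == pe) break;  // duplex start
      if (v == M[id(i - 1, k - 1)] + E_STACK + pe) { state = 0; }
      else if (v == X[id(i - 1, k - 1)] + pe) { state = 1; }
      else { state = 2; }
      --i; --k;
    } else if (state == 1) {
      const double v = X[id(i, k)];
      if (v == M[id(i, k - 1)] + GAP_OPEN) state = 0;
      else if (v == X[id(i, k - 1)] + GAP_EXT) state = 1;
      else state = 2;
      --k;
    } else {
      const double v = Y[id(i, k)];
      if (v == M[id(i - 1, k)] + GAP_OPEN) state = 0;
      else if (v == Y[id(i - 1, k)] + GAP_EXT) state = 2;
      else state = 1;
      --i;
    }
  }
  const int np = (int)mi.size();
  res.mi.resize(np); res.tj.resize(np);
  for (int p = 0; p < np; ++p) {
    // reverse traversal order so miRNA positions increase; map yr index back
    res.mi[p] = mi[np - 1 - p];
    res.tj[p] = m - tk[np - 1 - p] + 1;  // decreasing as mi increases
  }
  res.mfe = best;
  res.found = true;
  return res;
}

// ---- seed-window classification core -------------------------------------

struct WindowStats {
  int wc, gu, unpaired, tbulge, defects;
  bool contiguous_full_wc;  // all 6 paired, all WC, consecutive target
};

// window [a,b] (1-based miRNA positions, inclusive)
static WindowStats window_stats(const std::string &x, const std::string &y,
                                const std::vector<int> &mi,
                                const std::vector<int> &tj,
                                int a, int b) {
  WindowStats w{0, 0, 0, 0, 0, false};
  const int W = b - a + 1;
  std::vector<int> partner(W, 0);
  for (size_t p = 0; p < mi.size(); ++p)
    if (mi[p] >= a && mi[p] <= b) partner[mi[p] - a] = tj[p];
  std::vector<int> pp, pt;  // paired window positions and their targets
  bool all_wc = true;
  for (int q = 0; q < W; ++q) {
    if (partner[q] > 0) {
      const char mb = x[a + q - 1], tb = y[partner[q] - 1];
      if (is_wc(mb, tb)) ++w.wc;
      else if (is_gu(mb, tb)) { ++w.gu; all_wc = false; }
      else all_wc = false;  // engine never emits these; defensive
      pp.push_back(a + q); pt.push_back(partner[q]);
    } else {
      ++w.unpaired;
    }
  }
  if (pp.empty()) { w.defects = W; return w; }
  // edge unpaired positions + per-gap defects (max of the two gap sizes)
  int defects = (pp.front() - a) + (b - pp.back());
  bool contig = true;
  for (size_t q = 0; q + 1 < pp.size(); ++q) {
    const int mgap = pp[q + 1] - pp[q] - 1;
    const int tgap = pt[q] - pt[q + 1] - 1;
    if (tgap > mgap) w.tbulge += tgap - mgap;
    defects += std::max(mgap, tgap);
    if (mgap != 0 || tgap != 0) contig = false;
  }
  w.defects = defects;
  w.contiguous_full_wc = ((int)pp.size() == W) && all_wc && contig;
  return w;
}

// seed code: 2 canonical, 1 non_canonical, 0 other
static int classify_seed_code(const std::string &x, const std::string &y,
                              const std::vector<int> &mi,
                              const std::vector<int> &tj) {
  const WindowStats w27 = window_stats(x, y, mi, tj, 2, 7);
  const WindowStats w38 = window_stats(x, y, mi, tj, 3, 8);
  if (w27.contiguous_full_wc || w38.contiguous_full_wc) return 2;
  if (w27.defects <= 1 || w38.defects <= 1) return 1;
  return 0;
}

// [[Rcpp::export]]
List seed_window_stats_cpp(std::string mirna, std::string target,
                           IntegerVector mirna_pos, IntegerVector target_pos) {
  std::vector<int> mi(mirna_pos.begin(), mirna_pos.end());
  std::vector<int> tj(target_pos.begin(), target_pos.end());
  const WindowStats w27 = window_stats(mirna, target, mi, tj, 2, 7);
  const WindowStats w38 = window_stats(mirna, target, mi, tj, 3, 8);
  auto pack = [](const WindowStats &w) {
    return List::create(_["wc"] = w.wc, _["gu"] = w.gu,
                        _["unpaired"] = w.unpaired, _["tbulge"] = w.tbulge,
                        _["defects"] = w.defects,
                        _["canonical_window"] = w.contiguous_full_wc);
  };
  return List::create(_["w2_7"] = pack(w27), _["w3_8"] = pack(w38),
                      _["seed_code"] = classify_seed_code(mirna, target, mi, tj));
}

// ---- exported duplex computation -----------------------------------------

static List duplex_to_list(const DuplexResult &r) {
  if (!r.found) return R_NilValue;
  return List::create(_["mirna_pos"] = IntegerVector(r.mi.begin(), r.mi.end()),
                      _["target_pos"] = IntegerVector(r.tj.begin(), r.tj.end()),
                      _["mfe"] = r.mfe);
}

// [[Rcpp::export]]
List duplex_align_cpp(std::string mirna, std::string target) {
  DuplexWorkspace ws;
  return duplex_to_list(duplex_align(mirna, target, ws));
}

// [[Rcpp::export]]
List duplex_align_batch_cpp(CharacterVector mirnas, CharacterVector targets) {
  const int n = mirnas.size();
  if (targets.size() != n) stop("mirnas and targets must have equal length");
  List out(n);
  DuplexWorkspace ws;
  std::string x, y;
  for (int i = 0; i < n; ++i) {
    x = CHAR(STRING_ELT(mirnas, i));
    y = CHAR(STRING_ELT(targets, i));
    out[i] = duplex_to_list(duplex_align(x, y, ws));
  }
  return out;
}

static std::string pairs_string(const DuplexResult &r) {
  std::string s;
  for (size_t p = 0; p < r.mi.size(); ++p) {
    if (p) s += ";";
    s += std::to_string(r.mi[p]) + ":" + std::to_string(r.tj[p]);
  }
  return s;
}

// Batch scan with full annotation: duplex, seed code, density count,
// 3'-tail length, site span (0-based half-open on the target).
// max_tail < 0 disables the tail filter for the `valid` flag.
// [[Rcpp::export]]
DataFrame duplex_scan_cpp(CharacterVector mirnas, CharacterVector targets,
                          int max_tail) {
  const int n = mirnas.size();
  if (targets.size() != n) stop("mirnas and targets must have equal length");
  LogicalVector found(n), valid(n);
  IntegerVector seed(n), npairs(n), tail(n), site_start(n), site_end(n);
  NumericVector mfe(n);
  CharacterVector pstr(n);
  DuplexWorkspace ws;
  std::string x, y;
  for (int i = 0; i < n; ++i) {
    x = CHAR(STRING_ELT(mirnas, i));
    y = CHAR(STRING_ELT(targets, i));
    const DuplexResult r = duplex_align(x, y, ws);
    if (!r.found) {
      found[i] = false; valid[i] = false; seed[i] = 0; npairs[i] = 0;
      tail[i] = (int)x.size(); site_start[i] = NA_INTEGER;
      site_end[i] = NA_INTEGER; mfe[i] = NA_REAL; pstr[i] = NA_STRING;
      continue;
    }
    found[i] = true;
    const int code = classify_seed_code(x, y, r.mi, r.tj);
    seed[i] = code;
    npairs[i] = (int)r.mi.size();
    int maxmi = 0, mint = (int)y.size() + 1, maxt = 0;
    for (size_t p = 0; p < r.mi.size(); ++p) {
      if (r.mi[p] > maxmi) maxmi = r.mi[p];
      if (r.tj[p] < mint) mint = r.tj[p];
      if (r.tj[p] > maxt) maxt = r.tj[p];
    }
    tail[i] = (int)x.size() - maxmi;
    site_start[i] = mint - 1;
    site_end[i] = maxt;
    mfe[i] = r.mfe;
    bool ok = (code == 1 || code == 2);
    if (ok && max_tail >= 0 && tail[i] > max_tail) ok = false;
    valid[i] = ok;
    pstr[i] = ok ? String(pairs_string(r)) : NA_STRING;
  }
  return DataFrame::create(
      _["found"] = found, _["valid"] = valid, _["seed_code"] = seed,
      _["n_pairs"] = npairs, _["tail"] = tail, _["mfe"] = mfe,
      _["site_start"] = site_start, _["site_end"] = site_end,
      _["pairs"] = pstr, _["stringsAsFactors"] = false);
}
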