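// Altschul-Erickson dinucleotide-preserving shuffle: a uniform random
// Eulerian path through the dinucleotide multigraph of the input sequence.
// Preserves exact 2-mer counts (hence 1-mer counts) and the first and last
// letters. Randomness comes from R's RNG so results are reproducible under
// set.seed().
#include <Rcpp.h>
#include <vector>
#include <map>
using namespace Rcpp;

static inline int runif_int(int n) {  // uniform on 0..n-1
  int v;
  do { v = (int)(unif_rand() * n); } while (v >= n);
  return v;
}

// [[Rcpp::export]]
std::string dinuc_shuffle_cpp(std::string s) {
  const int n = (int)s.size();
  if (n <= 2) return s;

  // map letters to vertex ids
  std::map<char, int> vid;
  std::vector<char> letters;
  for (char c : s) {
    if (vid.find(c) == vid.end()) { vid[c] = (int)letters.size(); letters.push_back(c); }
  }
  const int V = (int)letters.size();
  const int start = vid[s[0]], last = vid[s[n - 1]];

  // outgoing edge lists (targets)
  std::vector<std::vector<int> > out(V);
  for (int i = 0; i + 1 < n; ++i) out[vid[s[i]]].push_back(vid[s[i + 1]]);

  RNGScope scope;
  std::vector<int> last_edge(V, -1);
  for (int attempt = 0; ; ++attempt) {
    if (attempt > 10000) stop("dinucleotide shuffle failed to find an Eulerian ordering");
    // pick a random candidate last edge for every vertex except `last`
    for (int v = 0; v < V; ++v) {
      last_edge[v] = -1;
      if (v != last && !out[v].empty())
        last_edge[v] = out[v][runif_int((int)out[v].size())];
    }
    // the chosen last edges must connect every such vertex to `last`
    bool ok = true;
    for (int v = 0; v < V && ok; ++v) {
      if (v == last || out[v].empty()) continue;
      int cur = v, steps = 0;
      while (cur != last && steps <= V) {
        if (cur != last && last_edge[cur] < 0) break;
        cur = last_edge[cur];
        ++steps;
      }
      if (cur != last) ok = false;
    }
    if (ok) break;
  }

  // shuffle remaining edges per vertex; append the designated last edge
  std::vector<std::vector<int> > ordered(V);
  for (int v = 0; v < V; ++v) {
    std::vector<int> rest;
    bool removed = false;
    for (int t : out[v]) {
      if (!removed && v != last && t == last_edge[v]) { removed = true; continue; }
      rest.push_back(t);
    }
    for (int i = (int)rest.size() - 1; i > 0; --i)
      std::swap(rest[i], rest[runif_int(i + 1)]);
    if (v != last && last_edge[v] >= 0) rest.push_back(last_edge[v]);
    ordered[v] = rest;
  }

  // walk the Eulerian path
  std::string res; res.reserve(n);
  std::vector<size_t> next(V, 0);
  int cur = start;
  res.push_back(letters[cur]);
  for (int i = 0; i + 1 < n; ++i) {
    int t = ordered[cur][next[cur]++];
    res.push_back(letters[t]);
    cur = t;
  }
  return res;
}
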