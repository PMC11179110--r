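#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Degree-preserving double-edge swaps on an undirected simple graph.
// edges: m x 2 (1-based node indices). Attempts n_attempts swaps, rejecting
// any that would create a self-loop or a multi-edge. Uses R's RNG so results
// are reproducible under set.seed().
// [[Rcpp::export]]
List rewire_degseq_cpp(IntegerMatrix edges, int n_nodes, int n_attempts) {
  int m = edges.nrow();
  std::vector<int> a(m), b(m);
  std::unordered_set<long long> present;
  present.reserve(m * 2);
  long long N = n_nodes;
  auto key = [N](int u, int v) {
    return (long long)std::min(u, v) * N + std::max(u, v);
  };
  for (int i = 0; i < m; i++) {
    a[i] = edges(i, 0);
    b[i] = edges(i, 1);
    present.insert(key(a[i], b[i]));
  }
  int accepted = 0;
  for (int t = 0; t < n_attempts; t++) {
    int e1 = (int)(unif_rand() * m);
    int e2 = (int)(unif_rand() * m);
    if (e1 == e2) continue;
    int u1 = a[e1], v1 = b[e1];
    int u2 = a[e2], v2 = b[e2];
    if (unif_rand() < 0.5) std::swap(u2, v2);
    // proposed: (u1, v2) and (u2, v1)
    if (u1 == v2 || u2 == v1) continue;
    long long k1 = key(u1, v2), k2 = key(u2, v1);
    if (present.count(k1) || present.count(k2)) continue;
    present.erase(key(u1, v1));
    present.erase(key(u2, v2));
    present.insert(k1);
    present.insert(k2);
    a[e1] = u1; b[e1] = v2;
    a[e2] = u2; b[e2] = v1;
    accepted++;
  }
  IntegerMatrix out(m, 2);
  for (int i = 0; i < m; i++) {
    out(i, 0) = a[i];
    out(i, 1) = b[i];
  }
  return List::create(_["edges"] = out, _["accepted"] = accepted,
                      _["attempted"] = n_attempts);
}
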