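#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Maslov-Sneppen double-edge swaps on an undirected simple graph.
// `edges` is a K x 2 matrix of 0-based endpoints; `n` the node count.
// Performs `nswaps` attempted swaps, rejecting any that would create a
// self-loop or multi-edge; the degree sequence is invariant. Edge
// membership is kept in a flat byte matrix for O(1) lookups. Uses R's RNG,
// so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix ms_rewire_cpp(IntegerMatrix edges, int n, double nswaps) {
  const int K = edges.nrow();
  std::vector<int> u(K), v(K);
  std::vector<unsigned char> adj((size_t)n * n, 0);
  auto at = [n, &adj](int a, int b) -> unsigned char& {
    return adj[(size_t)a * n + b];
  };
  for (int e = 0; e < K; ++e) {
    u[e] = edges(e, 0);
    v[e] = edges(e, 1);
    at(u[e], v[e]) = at(v[e], u[e]) = 1;
  }
  const long long S = (long long)nswaps;
  for (long long s = 0; s < S; ++s) {
    int e1 = (int)(unif_rand() * K);
    int e2 = (int)(unif_rand() * K);
    if (e1 == e2) continue;
    int a = u[e1], b = v[e1], c = u[e2], d = v[e2];
    if (unif_rand() < 0.5) std::swap(c, d);
    if (a == c || a == d || b == c || b == d) continue;
    if (at(a, d) || at(c, b)) continue;
    at(a, b) = at(b, a) = 0;
    at(c, d) = at(d, c) = 0;
    at(a, d) = at(d, a) = 1;
    at(c, b) = at(b, c) = 1;
    u[e1] = a; v[e1] = d;
    u[e2] = c; v[e2] = b;
  }
  IntegerMatrix out(K, 2);
  for (int e = 0; e < K; ++e) {
    out(e, 0) = u[e];
    out(e, 1) = v[e];
  }
  return out;
}
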