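// Mechanistic growth simulators. All randomness comes from R's RNG (via
// unif_rand) so that set.seed() in R fully determines the output.

#include <Rcpp.h>
#include <set>
#include <vector>

using namespace Rcpp;

// uniform integer in [0, n)
static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static IntegerMatrix edges_to_matrix(const std::vector<std::set<int> > &adj, int n) {
  int m = 0;
  for (int i = 0; i < n; ++i)
    for (std::set<int>::const_iterator it = adj[i].begin(); it != adj[i].end(); ++it)
      if (*it > i) ++m;
  IntegerMatrix out(m, 2);
  int r = 0;
  for (int i = 0; i < n; ++i)
    for (std::set<int>::const_iterator it = adj[i].begin(); it != adj[i].end(); ++it)
      if (*it > i) { out(r, 0) = i + 1; out(r, 1) = *it + 1; ++r; }
  return out;
}

static void seed_adjacency(std::vector<std::set<int> > &adj, IntegerMatrix seed_edges) {
  for (int e = 0; e < seed_edges.nrow(); ++e) {
    int a = seed_edges(e, 0) - 1, b = seed_edges(e, 1) - 1;
    if (a == b) continue;
    adj[a].insert(b);
    adj[b].insert(a);
  }
}

// Duplication-mutation-complementation growth. Each step: pick an existing
// node u uniformly, add new node v with edges to every neighbour of u; for
// each neighbour w, with probability qmod remove one (chosen uniformly) of
// the two parallel-role edges u-w / v-w; finally add u-v with probability
// qcon. Grows from n0 seed nodes (1-based edge list) to n nodes.
// [[Rcpp::export]]
IntegerMatrix cpp_dmc(IntegerMatrix seed_edges, int n0, int n,
                      double qmod, double qcon) {
  std::vector<std::set<int> > adj(n);
  seed_adjacency(adj, seed_edges);
  for (int v = n0; v < n; ++v) {
    int u = runif_int(v);
    std::vector<int> nbrs(adj[u].begin(), adj[u].end()); // sorted copy
    for (size_t k = 0; k < nbrs.size(); ++k) {
      int w = nbrs[k];
      adj[v].insert(w);
      adj[w].insert(v);
      if (unif_rand() < qmod) {
        if (unif_rand() < 0.5) { adj[u].erase(w); adj[w].erase(u); }
        else                   { adj[v].erase(w); adj[w].erase(v); }
      }
    }
    if (unif_rand() < qcon) { adj[u].insert(v); adj[v].insert(u); }
  }
  return edges_to_matrix(adj, n);
}

// Duplication-mutation-random growth. Each step (node count cur at step
// start): duplicate a uniformly chosen node u into v, keeping each copied
// edge independently with probability 1-qdel; then for every node w existing
// at step start and not already linked to v, add v-w with probability
// qnew/cur. If remove_singletons and v ends isolated, v is discarded and the
// step does not count towards growth; max_steps caps total steps.
// [[Rcpp::export]]
IntegerMatrix cpp_dmr(IntegerMatrix seed_edges, int n0, int n,
                      double qdel, double qnew, bool remove_singletons,
                      double max_steps) {
  std::vector<std::set<int> > adj(n);
  seed_adjacency(adj, seed_edges);
  int cur = n0;
  double steps = 0;
  while (cur < n) {
    if (++steps > max_steps)
      stop("DMR did not reach %d nodes within %.0f steps (singleton removal kept discarding new nodes)",
           n, max_steps);
    int u = runif_int(cur);
    int v = cur;
    std::vector<int> nbrs(adj[u].begin(), adj[u].end());
    for (size_t k = 0; k < nbrs.size(); ++k) {
      int w = nbrs[k];
      if (unif_rand() >= qdel) { adj[v].insert(w); adj[w].insert(v); }
    }
    double p_new = qnew / cur;
    for (int w = 0; w < cur; ++w) {
      if (adj[v].count(w)) continue;
      if (unif_rand() < p_new) { adj[v].insert(w); adj[w].insert(v); }
    }
    if (remove_singletons && adj[v].empty()) {
      continue; // discard v; slot reused next step
    }
    ++cur;
  }
  return edges_to_matrix(adj, n);
}

// Triangle-closure variant of G(n, m): edges are added one at a time; a
// uniformly random unconnected pair is proposed and accepted with probability
// p0 (+ p1 if it closes at least one triangle, + pdelta per additional
// triangle closed), clamped to [0, 1]. Stops at exactly m edges; errors after
// max_reject rejected proposals.
// [[Rcpp::export]]
IntegerMatrix cpp_triangle_closure(int n, int m, double p0, double p1,
                                   double pdelta, double max_reject) {
  std::vector<std::vector<unsigned char> > A(n, std::vector<unsigned char>(n, 0));
  IntegerMatrix out(m, 2);
  int added = 0;
  double rejected = 0;
  while (added < m) {
    int i = runif_int(n), j = runif_int(n);
    if (i == j || A[i][j]) {
      if (++rejected > max_reject)
        stop("triangle-closure sampler exceeded %.0f rejected proposals before reaching m = %d edges",
             max_reject, m);
      continue;
    }
    int t = 0;
    for (int k = 0; k < n; ++k) if (A[i][k] && A[j][k]) ++t;
    double p = p0 + (t >= 1 ? p1 + (t - 1) * pdelta : 0.0);
    if (p < 0) p = 0;
    if (p > 1) p = 1;
    if (unif_rand() < p) {
      A[i][j] = A[j][i] = 1;
      out(added, 0) = (i < j ? i : j) + 1;
      out(added, 1) = (i < j ? j : i) + 1;
      ++added;
    } else if (++rejected > max_reject) {
      stop("triangle-closure sampler exceeded %.0f rejected proposals before reaching m = %d edges",
           max_reject, m);
    }
  }
  return out;
}
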