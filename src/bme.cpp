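#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Balanced minimum-evolution (BME) total tree length via Pauplin weights:
// L(T) = sum_{i<j} d_ij * prod_{v internal on path(i,j)} 1/(deg(v) - 1),
// which for fully binary (unrooted) trees equals sum d_ij * 2^(1 - e_ij)
// with e_ij the number of edges on the path. Exact for additive distances
// and, unlike unweighted OLS minimum evolution, a statistically consistent
// criterion for topology selection.

struct Adj {
  std::vector<std::vector<int>> nb;
  explicit Adj(int nv) : nb(nv) {}
  void add(int a, int b) { nb[a].push_back(b); nb[b].push_back(a); }
};

// sum over tip pairs from BFS out of each tip; tips are nodes 0..ntip-1 and
// map to rows of D in node order
static double bme_from_adj(const Adj &adj, int ntip,
                           const NumericMatrix &D) {
  const int nv = (int)adj.nb.size();
  std::vector<double> w(nv);
  std::vector<int> seen(nv, -1);
  std::vector<int> queue(nv);
  double total = 0.0;
  for (int s = 0; s < ntip; ++s) {
    int qh = 0, qt = 0;
    queue[qt++] = s;
    seen[s] = s;
    w[s] = 1.0;
    while (qh < qt) {
      const int u = queue[qh++];
      const double wu = (u < ntip) ? w[u]
        : w[u] / (double)(adj.nb[u].size() - 1);
      for (int v : adj.nb[u]) {
        if (seen[v] == s) continue;
        seen[v] = s;
        w[v] = wu;
        if (v < ntip) {
          if (v > s) total += D(s, v) * w[v];
        } else {
          queue[qt++] = v;
        }
      }
    }
  }
  return total;
}

static Adj adj_from_edges(const IntegerMatrix &edge, int nv) {
  Adj adj(nv);
  for (int e = 0; e < edge.nrow(); ++e)
    adj.add(edge(e, 0) - 1, edge(e, 1) - 1);
  return adj;
}

// [[Rcpp::export]]
double bme_total_cpp(IntegerMatrix edge, int nnodes, NumericMatrix D,
                     int ntip) {
  Adj adj = adj_from_edges(edge, nnodes);
  return bme_from_adj(adj, ntip, D);
}

// BME total for inserting a new taxon in the middle of each edge in turn.
// D is (ntip + 1) x (ntip + 1): rows/cols 0..ntip-1 are the current tips in
// node order, row/col ntip is the new taxon.
// [[Rcpp::export]]
NumericVector bme_insertion_scores_cpp(IntegerMatrix edge, int nnodes,
                                       NumericMatrix D, int ntip) {
  const int E = edge.nrow();
  NumericVector out(E);
  // renumber: tips 0..ntip-1 keep ids; new tip gets id ntip; old internal
  // node i (>= ntip) shifts to i + 1; two new nodes appended at the end
  const int newtip = ntip;
  const int nv = nnodes + 3; // +1 new tip, +1 shift pad, +1 split node
  for (int cand = 0; cand < E; ++cand) {
    Adj adj(nv);
    const int split = nnodes + 2;
    for (int e = 0; e < E; ++e) {
      int a = edge(e, 0) - 1, b = edge(e, 1) - 1;
      if (a >= ntip) a += 1;
      if (b >= ntip) b += 1;
      if (e == cand) {
        adj.add(a, split);
        adj.add(split, b);
      } else {
        adj.add(a, b);
      }
    }
    adj.add(split, newtip);
    out[cand] = bme_from_adj(adj, ntip + 1, D);
  }
  return out;
}
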