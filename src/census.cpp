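#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// Counts of connected induced 3- and 4-node subgraphs of a small graph given
// as sorted 0-based adjacency lists.  Copy (non-induced) counts come from
// degree / codegree / per-edge triangle formulas; induced counts follow by
// Moebius inversion over the spanning-subgraph containment matrix of the six
// connected 4-node classes.  Output order: p3, k3, p4, claw, c4, paw,
// diamond, k4.  Counts are accumulated as doubles: exact for any graph small
// enough to census (< 2^53).
static void count34(const std::vector<std::vector<int> > &adj, double *out) {
  const int nv = (int)adj.size();
  for (int i = 0; i < 8; ++i) out[i] = 0.0;
  if (nv < 3) return;

  std::vector<double> deg(nv), tri_v(nv, 0.0);
  double sumC2 = 0.0, sumC3 = 0.0;
  for (int v = 0; v < nv; ++v) {
    double d = (double)adj[v].size();
    deg[v] = d;
    sumC2 += d * (d - 1.0) / 2.0;
    sumC3 += d * (d - 1.0) * (d - 2.0) / 6.0;
  }

  // codegrees over all node pairs, via wedge enumeration
  std::unordered_map<long long, int> cod;
  cod.reserve((size_t)(sumC2 + 1));
  for (int w = 0; w < nv; ++w) {
    const std::vector<int> &nb = adj[w];
    for (size_t a = 0; a + 1 < nb.size(); ++a)
      for (size_t b = a + 1; b < nb.size(); ++b) {
        long long key = (long long)nb[a] * nv + nb[b]; // nb sorted: nb[a] < nb[b]
        ++cod[key];
      }
  }
  double codpairs = 0.0;
  for (std::unordered_map<long long, int>::const_iterator it = cod.begin();
       it != cod.end(); ++it) {
    double c = (double)it->second;
    codpairs += c * (c - 1.0) / 2.0;
  }

  // per-edge pass: triangles, P4 walks, diamonds, K4
  double t3 = 0.0, sumPP = 0.0, n_dia = 0.0, k4s = 0.0;
  std::vector<int> common;
  for (int u = 0; u < nv; ++u) {
    for (size_t iu = 0; iu < adj[u].size(); ++iu) {
      int v = adj[u][iu];
      if (v <= u) continue;
      common.clear();
      std::set_intersection(adj[u].begin(), adj[u].end(),
                            adj[v].begin(), adj[v].end(),
                            std::back_inserter(common));
      double c = (double)common.size();
      t3 += c;
      tri_v[u] += c;
      tri_v[v] += c;
      sumPP += (deg[u] - 1.0) * (deg[v] - 1.0);
      n_dia += c * (c - 1.0) / 2.0;
      for (size_t a = 0; a + 1 < common.size(); ++a)
        for (size_t b = a + 1; b < common.size(); ++b)
          if (std::binary_search(adj[common[a]].begin(), adj[common[a]].end(),
                                 common[b]))
            k4s += 1.0;
    }
  }

  double n_k3 = t3 / 3.0;
  double n_p3 = sumC2 - 3.0 * n_k3;
  double n_p4 = sumPP - t3;
  double n_claw = sumC3;
  double n_paw = 0.0;
  for (int v = 0; v < nv; ++v) n_paw += (tri_v[v] / 2.0) * (deg[v] - 2.0);
  double n_c4 = codpairs / 2.0;
  double n_k4 = k4s / 6.0;

  double i_k4 = n_k4;
  double i_dia = n_dia - 6.0 * i_k4;
  double i_c4 = n_c4 - i_dia - 3.0 * i_k4;
  double i_paw = n_paw - 4.0 * i_dia - 12.0 * i_k4;
  double i_claw = n_claw - i_paw - 2.0 * i_dia - 4.0 * i_k4;
  double i_p4 = n_p4 - 4.0 * i_c4 - 2.0 * i_paw - 6.0 * i_dia - 12.0 * i_k4;

  out[0] = n_p3; out[1] = n_k3;
  out[2] = i_p4; out[3] = i_claw; out[4] = i_c4;
  out[5] = i_paw; out[6] = i_dia; out[7] = i_k4;
}

static std::vector<std::vector<int> > as_adj(const List &adjlist) {
  int n = adjlist.size();
  std::vector<std::vector<int> > adj(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adjlist[i];
    adj[i].assign(nb.begin(), nb.end());
  }
  return adj;
}

// [[Rcpp::export]]
NumericVector count34_cpp(List adjlist) {
  std::vector<std::vector<int> > adj = as_adj(adjlist);
  NumericVector out(8);
  double buf[8];
  count34(adj, buf);
  for (int i = 0; i < 8; ++i) out[i] = buf[i];
  return out;
}

// Two-step ego census for the listed ego nodes (0-based ids).  Each row:
// ego size, ego edge count, then the eight subgraph counts of the induced
// two-step ego-network.
// [[Rcpp::export]]
NumericMatrix ego_census_cpp(List adjlist, IntegerVector egos) {
  std::vector<std::vector<int> > adj = as_adj(adjlist);
  const int n = (int)adj.size();
  const int ne = egos.size();
  NumericMatrix out(ne, 10);

  std::vector<int> stamp(n, -1), local(n, -1);
  std::vector<int> nodes;
  std::vector<std::vector<int> > sub;

  for (int e = 0; e < ne; ++e) {
    int v0 = egos[e];
    nodes.clear();
    nodes.push_back(v0);
    stamp[v0] = e;
    // depth-2 BFS
    size_t lvl1_end;
    for (size_t i = 0; i < adj[v0].size(); ++i) {
      int u = adj[v0][i];
      if (stamp[u] != e) { stamp[u] = e; nodes.push_back(u); }
    }
    lvl1_end = nodes.size();
    for (size_t i = 1; i < lvl1_end; ++i) {
      const std::vector<int> &nb = adj[nodes[i]];
      for (size_t j = 0; j < nb.size(); ++j) {
        int u = nb[j];
        if (stamp[u] != e) { stamp[u] = e; nodes.push_back(u); }
      }
    }
    std::sort(nodes.begin(), nodes.end());
    int nv = (int)nodes.size();
    for (int i = 0; i < nv; ++i) local[nodes[i]] = i;

    sub.assign(nv, std::vector<int>());
    double edges = 0.0;
    for (int i = 0; i < nv; ++i) {
      const std::vector<int> &nb = adj[nodes[i]];
      for (size_t j = 0; j < nb.size(); ++j)
        if (stamp[nb[j]] == e) sub[i].push_back(local[nb[j]]);
      edges += (double)sub[i].size();
      // source lists sorted by global id and local order preserves it
    }
    edges /= 2.0;

    double buf[8];
    count34(sub, buf);
    out(e, 0) = (double)nv;
    out(e, 1) = edges;
    for (int i = 0; i < 8; ++i) out(e, i + 2) = buf[i];
  }
  return out;
}
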