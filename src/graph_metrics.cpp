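// Unweighted graph metrics for binarized deposition networks.
// All graphs are simple, undirected, encoded as 0/1 adjacency matrices
// (zero diagonal). Betweenness follows Brandes' dependency accumulation;
// distances are BFS hop counts. Randomization is Maslov-Sneppen
// double-edge swapping driven by R's RNG so set.seed() governs results.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <stack>
using namespace Rcpp;

typedef std::vector<std::vector<int> > AdjList;

static AdjList to_adjlist(const IntegerMatrix &adj) {
  int n = adj.nrow();
  AdjList g(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && adj(i, j) != 0) g[i].push_back(j);
  return g;
}

// BFS from src; dist filled with -1 for unreachable
static void bfs(const AdjList &g, int src, std::vector<int> &dist) {
  std::fill(dist.begin(), dist.end(), -1);
  dist[src] = 0;
  std::queue<int> q;
  q.push(src);
  while (!q.empty()) {
    int v = q.front(); q.pop();
    for (size_t k = 0; k < g[v].size(); ++k) {
      int w = g[v][k];
      if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix bfs_distances_cpp(IntegerMatrix adj) {
  int n = adj.nrow();
  AdjList g = to_adjlist(adj);
  NumericMatrix d(n, n);
  std::vector<int> dist(n);
  for (int s = 0; s < n; ++s) {
    bfs(g, s, dist);
    for (int t = 0; t < n; ++t)
      d(s, t) = dist[t] < 0 ? R_PosInf : (double)dist[t];
  }
  return d;
}

// Brandes betweenness, unordered-pair convention (ordered sum halved)
static std::vector<double> brandes(const AdjList &g) {
  int n = (int)g.size();
  std::vector<double> bc(n, 0.0);
  std::vector<int> dist(n);
  std::vector<double> sigma(n), delta(n);
  std::vector<std::vector<int> > pred(n);
  for (int s = 0; s < n; ++s) {
    std::stack<int> S;
    for (int i = 0; i < n; ++i) { pred[i].clear(); sigma[i] = 0.0; dist[i] = -1; }
    sigma[s] = 1.0; dist[s] = 0;
    std::queue<int> q; q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      S.push(v);
      for (size_t k = 0; k < g[v].size(); ++k) {
        int w = g[v][k];
        if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
        if (dist[w] == dist[v] + 1) { sigma[w] += sigma[v]; pred[w].push_back(v); }
      }
    }
    std::fill(delta.begin(), delta.end(), 0.0);
    while (!S.empty()) {
      int w = S.top(); S.pop();
      for (size_t k = 0; k < pred[w].size(); ++k) {
        int v = pred[w][k];
        delta[v] += (sigma[v] / sigma[w]) * (1.0 + delta[w]);
      }
      if (w != s) bc[w] += delta[w];
    }
  }
  for (int i = 0; i < n; ++i) bc[i] /= 2.0;
  return bc;
}

// [[Rcpp::export]]
NumericVector betweenness_cpp(IntegerMatrix adj) {
  return wrap(brandes(to_adjlist(adj)));
}

static std::vector<double> clustering_nodal(const IntegerMatrix &adj, const AdjList &g) {
  int n = adj.nrow();
  std::vector<double> cc(n, 0.0);
  for (int v = 0; v < n; ++v) {
    int k = (int)g[v].size();
    if (k < 2) continue;
    int links = 0;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (adj(g[v][a], g[v][b]) != 0) ++links;
    cc[v] = 2.0 * links / ((double)k * (k - 1));
  }
  return cc;
}

// mean over ordered pairs of 1/d within the induced neighbor subgraph
static double local_eff_node(const IntegerMatrix &adj, const std::vector<int> &nb) {
  int k = (int)nb.size();
  if (k < 2) return 0.0;
  AdjList sub(k);
  for (int a = 0; a < k; ++a)
    for (int b = 0; b < k; ++b)
      if (a != b && adj(nb[a], nb[b]) != 0) sub[a].push_back(b);
  std::vector<int> dist(k);
  double s = 0.0;
  for (int a = 0; a < k; ++a) {
    bfs(sub, a, dist);
    for (int b = 0; b < k; ++b)
      if (b != a && dist[b] > 0) s += 1.0 / dist[b];
  }
  return s / ((double)k * (k - 1));
}

struct Metrics {
  std::vector<double> degree, cc, bc, nodal_eff, nodal_loc_eff;
  double avg_degree, cp, lp, inf_frac, eglob, eloc, avg_bc;
  bool lp_defined;
};

static Metrics compute_all(const IntegerMatrix &adj, bool want_bc, bool want_loc) {
  int n = adj.nrow();
  AdjList g = to_adjlist(adj);
  Metrics m;
  m.degree.resize(n);
  for (int i = 0; i < n; ++i) m.degree[i] = (double)g[i].size();
  m.cc = clustering_nodal(adj, g);
  m.nodal_eff.assign(n, 0.0);
  std::vector<int> dist(n);
  double sum_d = 0.0; long n_conn = 0, n_disc = 0;
  double sum_inv = 0.0;
  for (int s = 0; s < n; ++s) {
    bfs(g, s, dist);
    double inv = 0.0;
    for (int t = 0; t < n; ++t) {
      if (t == s) continue;
      if (dist[t] > 0) { sum_d += dist[t]; ++n_conn; inv += 1.0 / dist[t]; }
      else ++n_disc;
    }
    m.nodal_eff[s] = n > 1 ? inv / (n - 1) : 0.0;
    sum_inv += inv;
  }
  m.lp_defined = n_conn > 0;
  m.lp = m.lp_defined ? sum_d / n_conn : NA_REAL;
  m.inf_frac = (n_conn + n_disc) > 0 ? (double)n_disc / (n_conn + n_disc) : 0.0;
  m.eglob = n > 1 ? sum_inv / ((double)n * (n - 1)) : 0.0;
  double cpsum = 0.0, dsum = 0.0;
  for (int i = 0; i < n; ++i) { cpsum += m.cc[i]; dsum += m.degree[i]; }
  m.cp = n > 0 ? cpsum / n : 0.0;
  m.avg_degree = n > 0 ? dsum / n : 0.0;
  if (want_loc) {
    m.nodal_loc_eff.assign(n, 0.0);
    double le = 0.0;
    for (int v = 0; v < n; ++v) {
      m.nodal_loc_eff[v] = local_eff_node(adj, g[v]);
      le += m.nodal_loc_eff[v];
    }
    m.eloc = n > 0 ? le / n : 0.0;
  } else m.eloc = NA_REAL;
  if (want_bc) {
    m.bc = brandes(g);
    double bsum = 0.0;
    for (int i = 0; i < n; ++i) bsum += m.bc[i];
    m.avg_bc = n > 0 ? bsum / n : 0.0;
  } else m.avg_bc = NA_REAL;
  return m;
}

// [[Rcpp::export]]
List graph_metrics_cpp(IntegerMatrix adj) {
  Metrics m = compute_all(adj, true, true);
  return List::create(
    _["degree"] = m.degree, _["nodal_cc"] = m.cc, _["betweenness"] = m.bc,
    _["nodal_efficiency"] = m.nodal_eff, _["nodal_local_efficiency"] = m.nodal_loc_eff,
    _["average_degree"] = m.avg_degree, _["cp"] = m.cp,
    _["lp"] = m.lp_defined ? m.lp : NA_REAL, _["inf_frac"] = m.inf_frac,
    _["eglob"] = m.eglob, _["eloc"] = m.eloc, _["avg_bc"] = m.avg_bc);
}

// Maslov-Sneppen double edge swaps on an edge list; preserves degrees,
// keeps the graph simple. Returns number of successful swaps via attribute.
static int rewire_edges(std::vector<std::pair<int,int> > &edges,
                        std::vector<std::vector<bool> > &has, int n_swaps) {
  int m = (int)edges.size();
  if (m < 2) return 0;
  int done = 0;
  long max_tries = 40L * n_swaps + 100;
  for (long t = 0; t < max_tries && done < n_swaps; ++t) {
    int e1 = (int)(unif_rand() * m), e2 = (int)(unif_rand() * m);
    if (e1 == e2) continue;
    int a = edges[e1].first, b = edges[e1].second;
    int c = edges[e2].first, d = edges[e2].second;
    if (unif_rand() < 0.5) std::swap(c, d);
    // propose (a,d) and (c,b)
    if (a == d || c == b) continue;
    if (a == c || b == d) continue;
    if (has[a][d] || has[c][b]) continue;
    has[a][b] = has[b][a] = false;
    has[c][d] = has[d][c] = false;
    has[a][d] = has[d][a] = true;
    has[c][b] = has[b][c] = true;
    edges[e1] = std::make_pair(a, d);
    edges[e2] = std::make_pair(c, b);
    ++done;
  }
  return done;
}

// [[Rcpp::export]]
IntegerMatrix rewire_cpp(IntegerMatrix adj, int n_swaps) {
  int n = adj.nrow();
  std::vector<std::pair<int,int> > edges;
  std::vector<std::vector<bool> > has(n, std::vector<bool>(n, false));
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (adj(i, j) != 0) { edges.push_back(std::make_pair(i, j)); has[i][j] = has[j][i] = true; }
  int done = rewire_edges(edges, has, n_swaps);
  IntegerMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      out(i, j) = has[i][j] ? 1 : 0;
  out.attr("swaps_done") = done;
  return out;
}

// Metrics across a nested sparsity ensemble. Edges are passed 0-based,
// sorted by decreasing weight; counts[k] gives the edge count retained at
// threshold k (non-decreasing). Small-world normalization uses n_random
// degree-preserving rewires with n_swaps = ceil(swap_factor * edge count).
// [[Rcpp::export]]
List ensemble_metrics_cpp(int n_nodes, IntegerVector edge_i, IntegerVector edge_j,
                          IntegerVector counts, bool nodal, bool small_world,
                          int n_random, double swap_factor) {
  int K = counts.size();
  NumericMatrix glob(K, 12);
  colnames(glob) = CharacterVector::create(
    "average_degree", "cp", "lp", "inf_frac", "eglob", "eloc", "avg_bc",
    "sigma", "lambda", "gamma", "lp_rand", "cp_rand");
  NumericMatrix nd_deg(K, n_nodes), nd_cc(K, n_nodes), nd_bc(K, n_nodes),
                nd_eff(K, n_nodes), nd_leff(K, n_nodes);
  IntegerMatrix adj(n_nodes, n_nodes);
  int placed = 0;
  for (int k = 0; k < K; ++k) {
    int target = counts[k];
    while (placed < target && placed < edge_i.size()) {
      adj(edge_i[placed], edge_j[placed]) = 1;
      adj(edge_j[placed], edge_i[placed]) = 1;
      ++placed;
    }
    Metrics m = compute_all(adj, true, true);
    glob(k, 0) = m.avg_degree; glob(k, 1) = m.cp;
    glob(k, 2) = m.lp_defined ? m.lp : NA_REAL;
    glob(k, 3) = m.inf_frac; glob(k, 4) = m.eglob; glob(k, 5) = m.eloc;
    glob(k, 6) = m.avg_bc;
    if (small_world && placed >= 2) {
      double lp_sum = 0.0, cp_sum = 0.0; int lp_n = 0, cp_n = 0;
      for (int r = 0; r < n_random; ++r) {
        std::vector<std::pair<int,int> > edges;
        std::vector<std::vector<bool> > has(n_nodes, std::vector<bool>(n_nodes, false));
        for (int p = 0; p < placed; ++p) {
          edges.push_back(std::make_pair((int)edge_i[p], (int)edge_j[p]));
          has[edge_i[p]][edge_j[p]] = has[edge_j[p]][edge_i[p]] = true;
        }
        int nsw = (int)std::ceil(swap_factor * placed);
        rewire_edges(edges, has, nsw);
        IntegerMatrix radj(n_nodes, n_nodes);
        for (int i = 0; i < n_nodes; ++i)
          for (int j = 0; j < n_nodes; ++j)
            radj(i, j) = has[i][j] ? 1 : 0;
        Metrics rm = compute_all(radj, false, false);
        if (rm.lp_defined) { lp_sum += rm.lp; ++lp_n; }
        cp_sum += rm.cp; ++cp_n;
      }
      double lp_rand = lp_n > 0 ? lp_sum / lp_n : NA_REAL;
      double cp_rand = cp_n > 0 ? cp_sum / cp_n : NA_REAL;
      glob(k, 10) = lp_rand; glob(k, 11) = cp_rand;
      double lambda = (m.lp_defined && lp_n > 0 && lp_rand > 0) ? m.lp / lp_rand : NA_REAL;
      double gamma = (cp_n > 0 && cp_rand > 0) ? m.cp / cp_rand : NA_REAL;
      glob(k, 8) = lambda; glob(k, 9) = gamma;
      glob(k, 7) = (R_finite(lambda) && R_finite(gamma) && lambda > 0) ? gamma / lambda : NA_REAL;
    } else {
      glob(k, 7) = NA_REAL; glob(k, 8) = NA_REAL; glob(k, 9) = NA_REAL;
      glob(k, 10) = NA_REAL; glob(k, 11) = NA_REAL;
    }
    if (nodal) {
      for (int i = 0; i < n_nodes; ++i) {
        nd_deg(k, i) = m.degree[i]; nd_cc(k, i) = m.cc[i]; nd_bc(k, i) = m.bc[i];
        nd_eff(k, i) = m.nodal_eff[i]; nd_leff(k, i) = m.nodal_loc_eff[i];
      }
    }
  }
  List out = List::create(_["global"] = glob);
  if (nodal)
    out["nodal"] = List::create(
      _["degree"] = nd_deg, _["nodal_cc"] = nd_cc, _["betweenness"] = nd_bc,
      _["nodal_efficiency"] = nd_eff, _["nodal_local_efficiency"] = nd_leff);
  return out;
}

// Fast path for cohort-scale recovery studies: nodal betweenness AUC only.
// [[Rcpp::export]]
NumericMatrix ensemble_bc_cpp(int n_nodes, IntegerVector edge_i, IntegerVector edge_j,
                              IntegerVector counts) {
  int K = counts.size();
  NumericMatrix bc(K, n_nodes);
  IntegerMatrix adj(n_nodes, n_nodes);
  int placed = 0;
  for (int k = 0; k < K; ++k) {
    while (placed < counts[k] && placed < edge_i.size()) {
      adj(edge_i[placed], edge_j[placed]) = 1;
      adj(edge_j[placed], edge_i[placed]) = 1;
      ++placed;
    }
    std::vector<double> b = brandes(to_adjlist(adj));
    for (int i = 0; i < n_nodes; ++i) bc(k, i) = b[i];
  }
  return bc;
}
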