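#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Damped asynchronous max-sum (log-space max-product) belief propagation
// on a pairwise model.  Messages are updated in a fixed order (edges
// sorted by their endpoints' node indices, both directions per edge), each
// update seeing the latest messages, and normalised by their maximum so
// long runs stay finite.  Terminates early when the largest message change
// in a sweep drops below tol.
//
// edge_pot[e] is a |dom_i| x |dom_j| matrix for undirected edge
// (edge_i[e], edge_j[e]); node indices are 0-based.

// [[Rcpp::export]]
List bp_max_sum(int n, IntegerVector edge_i, IntegerVector edge_j,
                List node_pot, List edge_pot,
                int max_iters, double damping, double tol) {
  int m = edge_i.size();
  std::vector<std::vector<double>> np(n);
  for (int v = 0; v < n; ++v) {
    NumericVector x = node_pot[v];
    np[v] = std::vector<double>(x.begin(), x.end());
  }
  std::vector<NumericMatrix> ep(m);
  for (int e = 0; e < m; ++e) ep[e] = as<NumericMatrix>(edge_pot[e]);

  // directed message d in [0, 2m): d < m is i->j of edge d, d >= m is j->i
  // of edge d - m.  msg[d] lives on the destination's domain.
  std::vector<std::vector<double>> msg(2 * m);
  std::vector<int> src(2 * m), dst(2 * m), rev(2 * m);
  for (int e = 0; e < m; ++e) {
    src[e] = edge_i[e]; dst[e] = edge_j[e];
    src[e + m] = edge_j[e]; dst[e + m] = edge_i[e];
    rev[e] = e + m; rev[e + m] = e;
    msg[e].assign(np[dst[e]].size(), 0.0);
    msg[e + m].assign(np[dst[e + m]].size(), 0.0);
  }
  // incoming directed messages per node
  std::vector<std::vector<int>> incoming(n);
  for (int d = 0; d < 2 * m; ++d) incoming[dst[d]].push_back(d);
  // fixed processing order: by source node, then destination node
  std::vector<int> order(2 * m);
  for (int d = 0; d < 2 * m; ++d) order[d] = d;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (src[a] != src[b]) return src[a] < src[b];
    return dst[a] < dst[b];
  });

  int iters = 0;
  bool converged = false;
  double delta = R_PosInf;
  std::vector<double> b, raw;
  for (iters = 1; iters <= max_iters; ++iters) {
    delta = 0.0;
    for (int d : order) {
      int s = src[d], t = dst[d];
      int e = d < m ? d : d - m;
      size_t ds = np[s].size(), dt = np[t].size();
      // source belief excluding the reverse message
      b.assign(np[s].begin(), np[s].end());
      for (int din : incoming[s]) {
        if (din == rev[d]) continue;
        for (size_t k = 0; k < ds; ++k) b[k] += msg[din][k];
      }
      raw.assign(dt, R_NegInf);
      const NumericMatrix &M = ep[e];
      if (d < m) {            // source is the row side
        for (size_t yj = 0; yj < dt; ++yj)
          for (size_t yi = 0; yi < ds; ++yi) {
            double val = b[yi] + M(yi, yj);
            if (val > raw[yj]) raw[yj] = val;
          }
      } else {                // source is the column side
        for (size_t yi = 0; yi < dt; ++yi)
          for (size_t yj = 0; yj < ds; ++yj) {
            double val = b[yj] + M(yi, yj);
            if (val > raw[yi]) raw[yi] = val;
          }
      }
      double mx = raw[0];
      for (size_t k = 1; k < dt; ++k) if (raw[k] > mx) mx = raw[k];
      for (size_t k = 0; k < dt; ++k) {
        double nv = damping * msg[d][k] + (1.0 - damping) * (raw[k] - mx);
        double ch = std::fabs(nv - msg[d][k]);
        if (ch > delta) delta = ch;
        msg[d][k] = nv;
      }
    }
    if (delta < tol) { converged = true; break; }
  }
  if (iters > max_iters) iters = max_iters;

  List beliefs(n);
  for (int v = 0; v < n; ++v) {
    std::vector<double> bv(np[v]);
    for (int din : incoming[v])
      for (size_t k = 0; k < bv.size(); ++k) bv[k] += msg[din][k];
    beliefs[v] = NumericVector(bv.begin(), bv.end());
  }
  return List::create(_["beliefs"] = beliefs,
                      _["iterations"] = iters,
                      _["converged"] = converged,
                      _["delta"] = delta);
}
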