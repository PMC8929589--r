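#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Multi-source Dijkstra on a water/land grid.
//
// Cells are addressed column-major like an R matrix: k = (c)*n_rows + r with
// 0-based r (row = northing index) and c (column = easting index). Moves:
//   orthogonal  cost = cell
//   diagonal    cost = cell * sqrt(2)   (corner cutting across a land corner
//                                        is allowed, matching straight-line
//                                        distance-accumulation tools)
//   knight      cost = cell * sqrt(5)   (connectivity = 16 only; both cells
//                                        adjacent to the move's chord must be
//                                        water so the path cannot jump land)
//
// Distances are truncated at d_max: cells whose shortest path exceeds d_max
// are reported unreachable (Inf), as are land cells.

// [[Rcpp::export]]
NumericVector grid_dijkstra_cpp(LogicalMatrix water, IntegerVector sources,
                                double cell, double d_max, int connectivity) {
  const int nr = water.nrow(), nc = water.ncol();
  const int n = nr * nc;
  std::vector<double> dist(n, R_PosInf);
  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;

  for (int i = 0; i < sources.size(); ++i) {
    int k = sources[i];
    if (k < 0 || k >= n) stop("source index out of range");
    if (!water[k]) stop("source cell is not water");
    if (dist[k] > 0.0) { dist[k] = 0.0; pq.push(Node(0.0, k)); }
  }

  const double c1 = cell, c2 = cell * std::sqrt(2.0), c5 = cell * std::sqrt(5.0);
  // (dr, dc, cost) for the 8-neighbourhood
  const int dr8[8] = { 1, -1, 0, 0, 1, 1, -1, -1 };
  const int dc8[8] = { 0, 0, 1, -1, 1, -1, 1, -1 };
  // knight moves with the two water cells each must clear
  const int drk[8]  = { 1, 1, -1, -1, 2, 2, -2, -2 };
  const int dck[8]  = { 2, -2, 2, -2, 1, -1, 1, -1 };
  const int dri1[8] = { 0, 0, 0, 0, 1, 1, -1, -1 };
  const int dci1[8] = { 1, -1, 1, -1, 0, 0, 0, 0 };
  const int dri2[8] = { 1, 1, -1, -1, 1, 1, -1, -1 };
  const int dci2[8] = { 1, -1, 1, -1, 1, -1, 1, -1 };

  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    double d = top.first; int k = top.second;
    if (d > dist[k]) continue;
    int r = k % nr, c = k / nr;

    for (int m = 0; m < 8; ++m) {
      int r2 = r + dr8[m], c2i = c + dc8[m];
      if (r2 < 0 || r2 >= nr || c2i < 0 || c2i >= nc) continue;
      int k2 = c2i * nr + r2;
      if (!water[k2]) continue;
      double nd = d + (m < 4 ? c1 : c2);
      if (nd <= d_max && nd < dist[k2]) { dist[k2] = nd; pq.push(Node(nd, k2)); }
    }
    if (connectivity == 16) {
      for (int m = 0; m < 8; ++m) {
        int r2 = r + drk[m], c2i = c + dck[m];
        if (r2 < 0 || r2 >= nr || c2i < 0 || c2i >= nc) continue;
        int k2 = c2i * nr + r2;
        if (!water[k2]) continue;
        int ra = r + dri1[m], ca = c + dci1[m];
        int rb = r + dri2[m], cb = c + dci2[m];
        if (!water[ca * nr + ra] || !water[cb * nr + rb]) continue;
        double nd = d + c5;
        if (nd <= d_max && nd < dist[k2]) { dist[k2] = nd; pq.push(Node(nd, k2)); }
      }
    }
  }

  NumericVector out(n);
  for (int k = 0; k < n; ++k) out[k] = water[k] ? dist[k] : R_PosInf;
  out.attr("dim") = IntegerVector::create(nr, nc);
  return out;
}
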