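#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Iterated conditional modes for the binary Ising clique energy:
// pairwise 4-neighbour potential -beta (labels equal) / +beta (labels differ).
// Raster-order (row-major) sweeps; a pixel flips only when the flip strictly
// lowers its local energy, so the total energy is non-increasing.  Stops at
// the first sweep with no flips or after max_sweeps.
// [[Rcpp::export]]
IntegerMatrix icm_denoise_cpp(IntegerMatrix mask, double beta, int max_sweeps) {
  int U = mask.nrow(), V = mask.ncol();
  IntegerMatrix lab = clone(mask);
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    int flips = 0;
    for (int r = 0; r < U; ++r) {
      for (int c = 0; c < V; ++c) {
        int n1 = 0, n = 0;
        if (r > 0)     { ++n; n1 += lab(r - 1, c); }
        if (r < U - 1) { ++n; n1 += lab(r + 1, c); }
        if (c > 0)     { ++n; n1 += lab(r, c - 1); }
        if (c < V - 1) { ++n; n1 += lab(r, c + 1); }
        int n0 = n - n1;
        // local energy for label 1: beta*(n0 - n1); for label 0: beta*(n1 - n0)
        int cur = lab(r, c);
        int best = cur;
        if (n1 > n0) best = 1; else if (n0 > n1) best = 0; // tie keeps current
        if (best != cur) { lab(r, c) = best; ++flips; }
      }
    }
    if (flips == 0) break;
  }
  return lab;
}

// 8-connected component labelling by breadth-first search.  Labels are
// assigned in row-major scan order of the first-encountered pixel, so the
// numbering is deterministic and label 1 starts at the top-left-most pixel.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix mask) {
  int U = mask.nrow(), V = mask.ncol();
  IntegerMatrix lab(U, V);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < U; ++r) {
    for (int c = 0; c < V; ++c) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int rr = p.first + dr, cc = p.second + dc;
            if (rr < 0 || rr >= U || cc < 0 || cc >= V) continue;
            if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              q.push(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  return lab;
}

// For each point of `from`, the distance to the nearest point of `to`
// (both n x d coordinate matrices, d = 2 or 3).  Brute force O(n1*n2);
// border-voxel sets of desk-scale volumes stay well within budget.
// [[Rcpp::export]]
NumericVector min_distances_cpp(NumericMatrix from, NumericMatrix to) {
  int n1 = from.nrow(), n2 = to.nrow(), d = from.ncol();
  NumericVector out(n1);
  for (int i = 0; i < n1; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < n2; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = from(i, k) - to(j, k);
        s += diff * diff;
      }
      if (s < best) best = s;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
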