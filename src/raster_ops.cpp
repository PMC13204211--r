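// Low-level raster operations shared by the segmentation and Sholl stages.
// All matrices are row-major R matrices indexed (row, col), 0-based here.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DR4[4] = {-1, 0, 0, 1};
static const int DC4[4] = {-1, 1, 0, 0};

// Connected-component labelling by breadth-first search.
// mask: 0/1 integer matrix. connectivity: 4 or 8. Labels 1..k, background 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int* dr = (connectivity == 4) ? DR4 : DR8;
  const int* dc = (connectivity == 4) ? DC4 : DC8;
  int nn = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nn; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) != 0 && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Count of foreground 8-neighbours for every foreground pixel (else -1).
// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_count8(const IntegerMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0) { out(r, c) = -1; continue; }
      int n = 0;
      for (int k = 0; k < 8; ++k) {
        int r2 = r + DR8[k], c2 = c + DC8[k];
        if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc && mask(r2, c2) != 0) ++n;
      }
      out(r, c) = n;
    }
  return out;
}

// Zhang-Suen thinning to a 1-px-wide, topology-preserving skeleton.
// [[Rcpp::export]]
IntegerMatrix cpp_thin_zhang_suen(const IntegerMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix img = clone(mask);
  // neighbour order P2..P9: N, NE, E, SE, S, SW, W, NW
  const int pr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int pc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  std::vector<int> kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (img(r, c) == 0) continue;
          int p[8];
          for (int k = 0; k < 8; ++k) {
            int r2 = r + pr[k], c2 = c + pc[k];
            p[k] = (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc) ? (img(r2, c2) != 0) : 0;
          }
          int b = 0, a = 0;
          for (int k = 0; k < 8; ++k) {
            b += p[k];
            if (p[k] == 0 && p[(k + 1) % 8] == 1) ++a;
          }
          if (b < 2 || b > 6 || a != 1) continue;
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;  // P2*P4*P6
            if (p[2] * p[4] * p[6] != 0) continue;  // P4*P6*P8
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;  // P2*P4*P8
            if (p[0] * p[4] * p[6] != 0) continue;  // P2*P6*P8
          }
          kill.push_back(r + c * nr);
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t i = 0; i < kill.size(); ++i)
          img[kill[i]] = 0;
      }
    }
  }
  return img;
}

// Felzenszwalb-Huttenlocher 1D squared distance transform.
static void dt1d(std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact Euclidean distance from every pixel to the nearest zero pixel of
// `mask`. If mask has no zero pixel, all distances are +Inf.
// [[Rcpp::export]]
NumericMatrix cpp_edt(const IntegerMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix d(nr, nc);
  // large finite sentinel: keeps the parabola arithmetic NaN-free when a
  // whole row/column lacks background
  const double INF = 1e12;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      d(r, c) = (mask(r, c) == 0) ? 0.0 : INF;
  std::vector<double> f(std::max(nr, nc)), out(std::max(nr, nc));
  // columns
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = d(r, c);
    dt1d(f, out, nr);
    for (int r = 0; r < nr; ++r) d(r, c) = out[r];
  }
  // rows
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = d(r, c);
    dt1d(f, out, nc);
    for (int c = 0; c < nc; ++c) d(r, c) = std::sqrt(out[c]);
  }
  return d;
}

// Sliding-window maximum filter (square window of half-width `radius`).
// [[Rcpp::export]]
NumericMatrix cpp_max_filter(const NumericMatrix& x, int radius) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double m = -std::numeric_limits<double>::infinity();
      for (int k = std::max(0, r - radius); k <= std::min(nr - 1, r + radius); ++k)
        if (x(k, c) > m) m = x(k, c);
      tmp(r, c) = m;
    }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double m = -std::numeric_limits<double>::infinity();
      for (int k = std::max(0, c - radius); k <= std::min(nc - 1, c + radius); ++k)
        if (tmp(r, k) > m) m = tmp(r, k);
      out(r, c) = m;
    }
  return out;
}

// Marker-driven watershed on a height map (flooded from high to low),
// restricted to `mask`. Markers carry labels 1..k; unlabeled mask pixels
// get the label of the first marker basin to reach them.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed_flood(const IntegerMatrix& mask,
                                  const IntegerMatrix& markers,
                                  const NumericMatrix& height) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  typedef std::pair<double, int> Node;  // (height, linear index)
  std::priority_queue<Node> pq;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (markers(r, c) > 0 && mask(r, c) != 0) {
        lab(r, c) = markers(r, c);
        pq.push(Node(height(r, c), r + c * nr));
      }
  while (!pq.empty()) {
    int idx = pq.top().second;
    pq.pop();
    int r = idx % nr, c = idx / nr;
    int l = lab(r, c);
    for (int k = 0; k < 8; ++k) {
      int r2 = r + DR8[k], c2 = c + DC8[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (mask(r2, c2) != 0 && lab(r2, c2) == 0) {
        lab(r2, c2) = l;
        pq.push(Node(height(r2, c2), r2 + c2 * nr));
      }
    }
  }
  return lab;
}
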