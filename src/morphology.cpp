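// Low-level image-morphology kernels: exact euclidean / chebyshev distance
// transforms, connected-component labeling and geodesic (within-mask) BFS.
// All matrices are row x col, column-major as R stores them.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Felzenszwalb & Huttenlocher 1-D squared distance transform. Cells with
// f = Inf carry no parabola; an all-Inf row stays Inf.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
  int n = (int)f.size();
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = 0.0;
    while (k >= 0) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else { break; }
    }
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -INF;
      z[1] = INF;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
      z[k + 1] = INF;
    }
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Exact squared euclidean distance (in pixels) from every cell to the nearest
// TRUE cell of `sites`. Cells with no site anywhere get Inf.
// [[Rcpp::export(name = ".cg_edt_sq")]]
NumericMatrix cg_edt_sq(LogicalMatrix sites) {
  int nr = sites.nrow(), nc = sites.ncol();
  NumericMatrix out(nr, nc);
  int m = std::max(nr, nc);
  std::vector<double> f(m), d(m), z(m + 1);
  std::vector<int> v(m);
  // pass 1: along columns (each column independently)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = sites(i, j) ? 0.0 : INF;
    f.resize(nr);
    dt1d(f, d, v, z);
    for (int i = 0; i < nr; ++i) out(i, j) = d[i];
    f.resize(m);
  }
  // pass 2: along rows
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = out(i, j);
    f.resize(nc);
    dt1d(f, d, v, z);
    for (int j = 0; j < nc; ++j) out(i, j) = d[j];
    f.resize(m);
  }
  return out;
}

// Chebyshev (chessboard) distance to the nearest TRUE cell, exact via
// two-pass chamfer (all 8 neighbour steps cost 1). NA-free; Inf if no site.
// [[Rcpp::export(name = ".cg_chebyshev_dist")]]
NumericMatrix cg_chebyshev_dist(LogicalMatrix sites) {
  int nr = sites.nrow(), nc = sites.ncol();
  NumericMatrix d(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      d(i, j) = sites(i, j) ? 0.0 : INF;
  // forward pass
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double best = d(i, j);
      if (i > 0 && d(i - 1, j) + 1 < best) best = d(i - 1, j) + 1;
      if (j > 0 && d(i, j - 1) + 1 < best) best = d(i, j - 1) + 1;
      if (i > 0 && j > 0 && d(i - 1, j - 1) + 1 < best) best = d(i - 1, j - 1) + 1;
      if (i < nr - 1 && j > 0 && d(i + 1, j - 1) + 1 < best) best = d(i + 1, j - 1) + 1;
      d(i, j) = best;
    }
  }
  // backward pass
  for (int j = nc - 1; j >= 0; --j) {
    for (int i = nr - 1; i >= 0; --i) {
      double best = d(i, j);
      if (i < nr - 1 && d(i + 1, j) + 1 < best) best = d(i + 1, j) + 1;
      if (j < nc - 1 && d(i, j + 1) + 1 < best) best = d(i, j + 1) + 1;
      if (i < nr - 1 && j < nc - 1 && d(i + 1, j + 1) + 1 < best) best = d(i + 1, j + 1) + 1;
      if (i > 0 && j < nc - 1 && d(i - 1, j + 1) + 1 < best) best = d(i - 1, j + 1) + 1;
      d(i, j) = best;
    }
  }
  return d;
}

// Connected-component labels (1..k) of TRUE cells under 4- or 8-connectivity;
// 0 elsewhere. BFS flood fill, deterministic label order (column-major scan).
// [[Rcpp::export(name = ".cg_label")]]
IntegerMatrix cg_label(LogicalMatrix mask, int conn) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::queue<int> q;
  const int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nnb = (conn == 8) ? 8 : 4;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(j * nr + i);
      while (!q.empty()) {
        int idx = q.front(); q.pop();
        int ci = idx % nr, cj = idx / nr;
        for (int t = 0; t < nnb; ++t) {
          int ni = ci + di8[t], nj = cj + dj8[t];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            q.push(nj * nr + ni);
          }
        }
      }
    }
  }
  return lab;
}

// Geodesic step distance from `sources` staying inside `allowed`; each move to
// one of the 4 or 8 neighbours costs 1. Unreachable / disallowed cells get -1.
// [[Rcpp::export(name = ".cg_geodesic")]]
IntegerMatrix cg_geodesic(LogicalMatrix allowed, LogicalMatrix sources, int conn) {
  int nr = allowed.nrow(), nc = allowed.ncol();
  IntegerMatrix d(nr, nc);
  std::fill(d.begin(), d.end(), -1);
  std::queue<int> q;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (sources(i, j) && allowed(i, j)) {
        d(i, j) = 0;
        q.push(j * nr + i);
      }
  const int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nnb = (conn == 8) ? 8 : 4;
  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int ci = idx % nr, cj = idx / nr;
    for (int t = 0; t < nnb; ++t) {
      int ni = ci + di8[t], nj = cj + dj8[t];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      if (allowed(ni, nj) && d(ni, nj) == -1) {
        d(ni, nj) = d(ci, cj) + 1;
        q.push(nj * nr + ni);
      }
    }
  }
  return d;
}
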