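#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher,
// two-pass lower-envelope of parabolas). Distances are in pixel units and,
// for a boolean source mask, are exact integers stored as doubles, so
// thresholding against a squared radius is free of rounding ambiguity.

static const double DT_INF = std::numeric_limits<double>::infinity();

// 1-D squared distance transform of sampled function f (length n).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; q++) {
    if (f[q] == DT_INF) continue;
    if (f[v[k]] == DT_INF) { v[k] = q; continue; }
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (k > 0 && s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)q - v[k];
    d[q] = (f[v[k]] == DT_INF) ? DT_INF : dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_sq")]]
NumericMatrix edt_sq(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  NumericMatrix out(H, W);
  // column pass: distance along rows within each column
  for (int j = 0; j < W; j++) {
    std::vector<double> f(H), d(H);
    for (int i = 0; i < H; i++) f[i] = mask(i, j) ? 0.0 : DT_INF;
    dt1d(f, d, H);
    for (int i = 0; i < H; i++) out(i, j) = d[i];
  }
  // row pass
  for (int i = 0; i < H; i++) {
    std::vector<double> f(W), d(W);
    for (int j = 0; j < W; j++) f[j] = out(i, j);
    dt1d(f, d, W);
    for (int j = 0; j < W; j++) out(i, j) = d[j];
  }
  return out;
}

// 8-connected component labeling by iterative flood fill.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int j0 = 0; j0 < W; j0++) {
    for (int i0 = 0; i0 < H; i0++) {
      if (!mask(i0, j0) || lab(i0, j0) != 0) continue;
      next++;
      stack.push_back(i0 + j0 * H);
      lab(i0, j0) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int i = idx % H, j = idx / H;
        for (int dj = -1; dj <= 1; dj++) {
          for (int di = -1; di <= 1; di++) {
            int ii = i + di, jj = j + dj;
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              stack.push_back(ii + jj * H);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Union of disks of radius r_px stamped at (row, col) centers given in
// 0-based pixel coordinates (may be fractional). A pixel is covered when
// its center lies within r_px of some source point. Independent of the
// distance-transform path, hence usable as its oracle.
// [[Rcpp::export(name = ".disk_union")]]
LogicalMatrix disk_union(NumericVector row0, NumericVector col0,
                         int H, int W, double r_px) {
  LogicalMatrix out(H, W);
  std::fill(out.begin(), out.end(), false);
  double r2 = r_px * r_px;
  int n = row0.size();
  for (int p = 0; p < n; p++) {
    double cr = row0[p], cc = col0[p];
    int ilo = (int)std::ceil(cr - r_px), ihi = (int)std::floor(cr + r_px);
    if (ilo < 0) ilo = 0;
    if (ihi > H - 1) ihi = H - 1;
    for (int i = ilo; i <= ihi; i++) {
      double dy = (double)i - cr;
      double rem = r2 - dy * dy;
      if (rem < 0) continue;
      double dx = std::sqrt(rem);
      int jlo = (int)std::ceil(cc - dx), jhi = (int)std::floor(cc + dx);
      if (jlo < 0) jlo = 0;
      if (jhi > W - 1) jhi = W - 1;
      for (int j = jlo; j <= jhi; j++) {
        double ddx = (double)j - cc;
        if (dy * dy + ddx * ddx <= r2) out(i, j) = true;
      }
    }
  }
  return out;
}
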