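#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Separable 2-D filtering with edge replication. `kv` runs along rows
// (vertical), `kh` along columns. Correlation convention; all kernels used
// by the package are symmetric or antisymmetric so the distinction only
// flips the sign of derivative responses, which are rectified downstream.
// [[Rcpp::export]]
NumericMatrix sep_filter2_cpp(const NumericMatrix& x,
                              const NumericVector& kv,
                              const NumericVector& kh) {
  const int H = x.nrow(), W = x.ncol();
  const int rv = (kv.size() - 1) / 2, rh = (kh.size() - 1) / 2;
  NumericMatrix tmp(H, W), out(H, W);
  const double* xp = x.begin();
  double* tp = tmp.begin();
  // vertical pass: columns are contiguous in memory
  for (int j = 0; j < W; ++j) {
    const double* col = xp + (size_t)j * H;
    double* dst = tp + (size_t)j * H;
    int top = rv < H ? rv : H;
    int bottom = H - rv > top ? H - rv : top;
    for (int i = 0; i < top; ++i) {            // clamped top border
      double s = 0.0;
      for (int t = -rv; t <= rv; ++t) {
        int ii = i + t;
        if (ii < 0) ii = 0; else if (ii >= H) ii = H - 1;
        s += kv[t + rv] * col[ii];
      }
      dst[i] = s;
    }
    for (int i = top; i < bottom; ++i) {       // interior, no clamping
      double s = 0.0;
      const double* p = col + i - rv;
      for (int t = 0; t <= 2 * rv; ++t) s += kv[t] * p[t];
      dst[i] = s;
    }
    for (int i = bottom; i < H; ++i) {         // clamped bottom border
      double s = 0.0;
      for (int t = -rv; t <= rv; ++t) {
        int ii = i + t;
        if (ii < 0) ii = 0; else if (ii >= H) ii = H - 1;
        s += kv[t + rv] * col[ii];
      }
      dst[i] = s;
    }
  }
  // horizontal pass: accumulate whole columns (contiguous axpy)
  double* op = out.begin();
  for (int j = 0; j < W; ++j) {
    double* dst = op + (size_t)j * H;
    for (int t = -rh; t <= rh; ++t) {
      int jj = j + t;
      if (jj < 0) jj = 0; else if (jj >= W) jj = W - 1;
      const double w = kh[t + rh];
      const double* src = tp + (size_t)jj * H;
      for (int i = 0; i < H; ++i) dst[i] += w * src[i];
    }
  }
  return out;
}

static int uf_find(std::vector<int>& parent, int a) {
  while (parent[a] != a) {
    parent[a] = parent[parent[a]];
    a = parent[a];
  }
  return a;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra < rb) parent[rb] = ra; else parent[ra] = rb;
}

// Two-pass connected-component labelling of a binary mask.
// connectivity: 4 or 8. Labels are consecutive integers from 1 in
// raster-scan order of first appearance; background is 0.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent;
  parent.reserve(256);
  int next = 0;
  const bool diag = (connectivity == 8);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) { lab(i, j) = -1; continue; }
      int best = -1;
      // previously visited neighbours in column-major scan order:
      // (i-1, j), (i, j-1), and diagonals (i-1, j-1), (i+1, j-1)
      int ni[4] = { i - 1, i,     i - 1, i + 1 };
      int nj[4] = { j,     j - 1, j - 1, j - 1 };
      int nn = diag ? 4 : 2;
      for (int q = 0; q < nn; ++q) {
        if (ni[q] < 0 || ni[q] >= H || nj[q] < 0 || nj[q] >= W) continue;
        int l = lab(ni[q], nj[q]);
        if (l >= 0) {
          if (best < 0) best = l;
          else uf_union(parent, best, l);
        }
      }
      if (best < 0) {
        best = next++;
        parent.push_back(best);
      }
      lab(i, j) = best;
    }
  }
  // resolve labels and renumber consecutively
  std::vector<int> remap(next, 0);
  int count = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (lab(i, j) >= 0) {
        int r = uf_find(parent, lab(i, j));
        if (remap[r] == 0) remap[r] = ++count;
        lab(i, j) = remap[r];
      } else {
        lab(i, j) = 0;
      }
  return lab;
}

// Mean-pool |x| over a grid of stride x stride cells (last cell in each
// dimension may be partial). Returns ceil(H/s) x ceil(W/s).
// [[Rcpp::export]]
NumericMatrix abs_pool_grid_cpp(const NumericMatrix& x, int stride) {
  const int H = x.nrow(), W = x.ncol();
  const int nH = (H + stride - 1) / stride, nW = (W + stride - 1) / stride;
  NumericMatrix out(nH, nW);
  IntegerMatrix cnt(nH, nW);
  for (int j = 0; j < W; ++j) {
    int v = j / stride;
    for (int i = 0; i < H; ++i) {
      int u = i / stride;
      out(u, v) += std::abs(x(i, j));
      cnt(u, v) += 1;
    }
  }
  for (int v = 0; v < nW; ++v)
    for (int u = 0; u < nH; ++u)
      out(u, v) /= cnt(u, v);
  return out;
}

// Harrell's concordance index. Usable pairs: observed times differ and
// the shorter time is an event. Score ties count 1/2.
// [[Rcpp::export]]
List harrell_cindex_cpp(const NumericVector& score,
                        const NumericVector& time,
                        const IntegerVector& event) {
  const int n = score.size();
  double num = 0.0, den = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (time[i] == time[j]) continue;
      const int s = time[i] < time[j] ? i : j;
      const int l = s == i ? j : i;
      if (!event[s]) continue;
      den += 1.0;
      if (score[s] > score[l]) num += 1.0;
      else if (score[s] == score[l]) num += 0.5;
    }
  }
  return List::create(Named("concordant") = num,
                      Named("usable") = den);
}
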