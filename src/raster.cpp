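#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// reflect an index into [0, n) with scipy-style "reflect" boundary
// (d c b a | a b c d | d c b a)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix x, int window) {
  if (window < 1 || window % 2 == 0)
    stop("window must be a positive odd integer");
  int nr = x.nrow(), nc = x.ncol(), r = window / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf(window * window);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = 0;
      for (int dj = -r; dj <= r; ++dj) {
        int jj = reflect_idx(j + dj, nc);
        for (int di = -r; di <= r; ++di)
          buf[k++] = x(reflect_idx(i + di, nr), jj);
      }
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.begin() + k);
      out(i, j) = buf[k / 2];
    }
  }
  return out;
}

// 2-D cross-correlation with reflect padding (CNN-style "conv")
// [[Rcpp::export]]
NumericMatrix conv2d_reflect_cpp(NumericMatrix x, NumericMatrix k) {
  int nr = x.nrow(), nc = x.ncol();
  int kr = k.nrow(), kc = k.ncol();
  if (kr % 2 == 0 || kc % 2 == 0) stop("kernel dimensions must be odd");
  int ri = kr / 2, rj = kc / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int b = 0; b < kc; ++b) {
        int jj = reflect_idx(j + b - rj, nc);
        for (int a = 0; a < kr; ++a)
          acc += x(reflect_idx(i + a - ri, nr), jj) * k(a, b);
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// 1-D squared-distance transform (Felzenszwalb & Huttenlocher)
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -1e30;
  z[1] = 1e30;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// exact squared Euclidean distance to the nearest TRUE pixel
// [[Rcpp::export]]
NumericMatrix edt_sq_cpp(LogicalMatrix src) {
  int nr = src.nrow(), nc = src.ncol();
  NumericMatrix d(nr, nc);
  const double INF = 1e30;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      d(i, j) = src(i, j) ? 0.0 : INF;
  // transform columns
  std::vector<double> f(std::max(nr, nc)), out(std::max(nr, nc));
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = d(i, j);
    dt1d(f, out, nr);
    for (int i = 0; i < nr; ++i) d(i, j) = out[i];
  }
  // transform rows
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = d(i, j);
    dt1d(f, out, nc);
    for (int j = 0; j < nc; ++j) d(i, j) = std::min(out[j], INF);
  }
  return d;
}

// 4-connected component labelling, labels assigned in raster
// (row-major) discovery order
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        const int di[4] = {-1, 1, 0, 0};
        const int dj[4] = {0, 0, -1, 1};
        for (int t = 0; t < 4; ++t) {
          int ni = ci + di[t], nj = cj + dj[t];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// greedy peak picking: candidates are pixels with value >= min_val that
// equal the maximum of their (2r+1)^2 Chebyshev neighbourhood
// (r = min_sep rounded down, at least 1); candidates are visited in
// decreasing value (ties: raster order) and kept if no kept peak lies
// within min_sep (Euclidean). Returns kept linear 0-based indices
// (column-major) in acceptance order.
// [[Rcpp::export]]
IntegerVector local_peaks_cpp(NumericMatrix v, double min_sep, double min_val) {
  int nr = v.nrow(), nc = v.ncol();
  int r = std::max(1, (int)min_sep);
  // separable running max filter over a (2r+1) square window
  NumericMatrix rowmax(nr, nc), winmax(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      double m = v(i, j);
      for (int dj = -r; dj <= r; ++dj) {
        int jj = j + dj;
        if (jj >= 0 && jj < nc && v(i, jj) > m) m = v(i, jj);
      }
      rowmax(i, j) = m;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double m = rowmax(i, j);
      for (int di = -r; di <= r; ++di) {
        int ii = i + di;
        if (ii >= 0 && ii < nr && rowmax(ii, j) > m) m = rowmax(ii, j);
      }
      winmax(i, j) = m;
    }
  struct Cand { double val; int i, j; };
  std::vector<Cand> cand;
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      if (v(i, j) >= min_val && v(i, j) == winmax(i, j))
        cand.push_back({v(i, j), i, j});
  std::stable_sort(cand.begin(), cand.end(),
                   [](const Cand &a, const Cand &b) { return a.val > b.val; });
  double sep2 = min_sep * min_sep;
  std::vector<Cand> kept;
  std::vector<int> idx;
  for (const Cand &c : cand) {
    bool ok = true;
    for (const Cand &k : kept) {
      double di = c.i - k.i, dj = c.j - k.j;
      if (di * di + dj * dj < sep2) { ok = false; break; }
    }
    if (ok) {
      kept.push_back(c);
      idx.push_back(c.i + c.j * nr);
    }
  }
  return wrap(idx);
}

// marker-controlled watershed by priority flooding: markers grow into
// the mask in order of increasing surface value; FIFO tie-break makes
// the result deterministic.
// [[Rcpp::export]]
IntegerMatrix watershed_cpp(NumericMatrix surface, IntegerMatrix markers,
                            LogicalMatrix mask) {
  int nr = surface.nrow(), nc = surface.ncol();
  if (markers.nrow() != nr || markers.ncol() != nc ||
      mask.nrow() != nr || mask.ncol() != nc)
    stop("surface, markers and mask must share dimensions");
  IntegerMatrix lab(nr, nc);
  struct Node { double p; long order; int idx; };
  struct Cmp {
    bool operator()(const Node &a, const Node &b) const {
      if (a.p != b.p) return a.p > b.p;   // min-heap on priority
      return a.order > b.order;           // then FIFO
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  long counter = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (markers(i, j) > 0 && mask(i, j)) {
        lab(i, j) = markers(i, j);
        pq.push({surface(i, j), counter++, i + j * nr});
      }
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    int ci = nd.idx % nr, cj = nd.idx / nr;
    int l = lab(ci, cj);
    for (int t = 0; t < 4; ++t) {
      int ni = ci + di[t], nj = cj + dj[t];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      if (!mask(ni, nj) || lab(ni, nj) != 0) continue;
      lab(ni, nj) = l;
      pq.push({surface(ni, nj), counter++, ni + nj * nr});
    }
  }
  return lab;
}
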