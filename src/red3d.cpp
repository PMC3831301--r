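#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Separable Gaussian blur, kernel truncated at 4 sigma and renormalized.
// Border handling: the kernel is renormalized over the in-frame support, so
// constant images are reproduced exactly everywhere.
// 1D convolution of each length-n column of src (n x m, column-major) with
// the normalized kernel k (length 2*half+1); borders renormalized over the
// in-range support so constant signals are reproduced exactly.
static void conv_columns(const double *src, double *dst, int n, int m,
                         const std::vector<double> &k, int half) {
  for (int c = 0; c < m; ++c) {
    const double *s = src + (size_t)c * n;
    double *d = dst + (size_t)c * n;
    int interior_lo = half, interior_hi = n - half - 1;
    for (int r = interior_lo; r <= interior_hi; ++r) {
      double acc = 0.0;
      const double *sp = s + r - half;
      for (int j = 0; j <= 2 * half; ++j) acc += k[j] * sp[j];
      d[r] = acc;
    }
    for (int r = 0; r < std::min(n, half); ++r) {
      double acc = 0.0, w = 0.0;
      int lo = std::max(0, r - half), hi = std::min(n - 1, r + half);
      for (int j = lo; j <= hi; ++j) { acc += k[j - r + half] * s[j]; w += k[j - r + half]; }
      d[r] = acc / w;
    }
    for (int r = std::max(0, n - half); r < n; ++r) {
      double acc = 0.0, w = 0.0;
      int lo = std::max(0, r - half), hi = std::min(n - 1, r + half);
      for (int j = lo; j <= hi; ++j) { acc += k[j - r + half] * s[j]; w += k[j - r + half]; }
      d[r] = acc / w;
    }
  }
}

static void transpose(const double *src, double *dst, int nr, int nc) {
  const int B = 32;
  for (int cb = 0; cb < nc; cb += B)
    for (int rb = 0; rb < nr; rb += B)
      for (int c = cb; c < std::min(nc, cb + B); ++c)
        for (int r = rb; r < std::min(nr, rb + B); ++r)
          dst[(size_t)r * nc + c] = src[(size_t)c * nr + r];
}

// [[Rcpp::export(name = ".gaussian_blur_cpp")]]
NumericMatrix gaussian_blur_cpp(NumericMatrix img, double sigma) {
  if (sigma <= 0) stop("sigma must be > 0");
  int nr = img.nrow(), nc = img.ncol();
  int half = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * half + 1);
  double ksum = 0.0;
  for (int i = -half; i <= half; ++i) {
    k[i + half] = std::exp(-0.5 * (double)i * (double)i / (sigma * sigma));
    ksum += k[i + half];
  }
  for (double &w : k) w /= ksum;
  size_t sz = (size_t)nr * nc;
  std::vector<double> t1(sz), t2(sz);
  NumericMatrix out(nr, nc);
  conv_columns(&img[0], t1.data(), nr, nc, k, half);  // along y
  transpose(t1.data(), t2.data(), nr, nc);            // t2 is nc x nr
  conv_columns(t2.data(), t1.data(), nc, nr, k, half);  // along x
  transpose(t1.data(), &out[0], nc, nr);
  return out;
}

// 8-connected component labelling of a logical mask; labels start at 1 in
// scan order (column-major), 0 = background.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(1024);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            int r2 = rr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (mask(r2, c2) && lab(r2, c2) == 0) {
              lab(r2, c2) = next;
              stack.push_back(r2 + c2 * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Translate image content by (+dx, +dy) pixels with bilinear interpolation;
// out(y, x) = img(y - dy, x - dx), border replicated.
// [[Rcpp::export(name = ".shift_bilinear_cpp")]]
NumericMatrix shift_bilinear_cpp(NumericMatrix img, double dx, double dy) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    double xs = (double)c - dx;
    double xcl = std::min(std::max(xs, 0.0), (double)(nc - 1));
    int x0 = (int)std::floor(xcl);
    int x1 = std::min(x0 + 1, nc - 1);
    double fx = xcl - x0;
    for (int r = 0; r < nr; ++r) {
      double ys = (double)r - dy;
      double ycl = std::min(std::max(ys, 0.0), (double)(nr - 1));
      int y0 = (int)std::floor(ycl);
      int y1 = std::min(y0 + 1, nr - 1);
      double fy = ycl - y0;
      out(r, c) =
        (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
        fy       * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
    }
  }
  return out;
}

// All pairwise difference vectors with min_len <= |d| <= max_len,
// sign-canonicalized: the component of largest magnitude is made positive.
// [[Rcpp::export(name = ".short_diff_vectors_cpp")]]
NumericMatrix short_diff_vectors_cpp(NumericMatrix pts, double min_len,
                                     double max_len) {
  int n = pts.nrow();
  double lo2 = min_len * min_len, hi2 = max_len * max_len;
  std::vector<double> dx, dy, dz;
  for (int i = 0; i < n; ++i) {
    double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    for (int j = i + 1; j < n; ++j) {
      double vx = pts(j, 0) - xi, vy = pts(j, 1) - yi, vz = pts(j, 2) - zi;
      double l2 = vx * vx + vy * vy + vz * vz;
      if (l2 < lo2 || l2 > hi2) continue;
      double ax = std::fabs(vx), ay = std::fabs(vy), az = std::fabs(vz);
      double lead = (ax >= ay && ax >= az) ? vx : (ay >= az ? vy : vz);
      if (lead < 0) { vx = -vx; vy = -vy; vz = -vz; }
      dx.push_back(vx); dy.push_back(vy); dz.push_back(vz);
    }
  }
  int m = (int)dx.size();
  NumericMatrix out(m, 3);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = dx[i]; out(i, 1) = dy[i]; out(i, 2) = dz[i];
  }
  return out;
}

// Plain O(n^2) DBSCAN on 3-column point matrix. Returns integer labels,
// 0 = noise, clusters numbered from 1 in order of first core point found.
// [[Rcpp::export(name = ".dbscan_cpp")]]
IntegerVector dbscan_cpp(NumericMatrix pts, double eps, int min_pts) {
  int n = pts.nrow();
  double eps2 = eps * eps;
  IntegerVector lab(n);
  std::fill(lab.begin(), lab.end(), 0);
  std::vector<char> visited(n, 0);
  std::vector<int> neigh, seeds;
  int cl = 0;
  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    visited[i] = 1;
    neigh.clear();
    for (int j = 0; j < n; ++j) {
      double d0 = pts(j, 0) - pts(i, 0), d1 = pts(j, 1) - pts(i, 1),
             d2 = pts(j, 2) - pts(i, 2);
      if (d0 * d0 + d1 * d1 + d2 * d2 <= eps2) neigh.push_back(j);
    }
    if ((int)neigh.size() < min_pts) continue;  // noise (may be claimed later)
    ++cl;
    lab[i] = cl;
    seeds = neigh;
    for (size_t s = 0; s < seeds.size(); ++s) {
      int q = seeds[s];
      if (lab[q] == 0) lab[q] = cl;
      if (visited[q]) continue;
      visited[q] = 1;
      std::vector<int> nq;
      for (int j = 0; j < n; ++j) {
        double d0 = pts(j, 0) - pts(q, 0), d1 = pts(j, 1) - pts(q, 1),
               d2 = pts(j, 2) - pts(q, 2);
        if (d0 * d0 + d1 * d1 + d2 * d2 <= eps2) nq.push_back(j);
      }
      if ((int)nq.size() >= min_pts) {
        for (int j : nq)
          if (lab[j] == 0 || !visited[j]) seeds.push_back(j);
      }
    }
  }
  return lab;
}
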