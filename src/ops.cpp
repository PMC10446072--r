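#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Arrays are R 3D arrays dim = c(ny, nx, nz), column-major:
// linear index i = y + ny * (x + nx * z), all 0-based here.

static inline int lin(int y, int x, int z, int ny, int nx) {
  return y + ny * (x + nx * z);
}

// neighbour offsets for 6/18/26 connectivity
static void neigh_offsets(int connectivity, std::vector<int> &dy,
                          std::vector<int> &dx, std::vector<int> &dz) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int s = std::abs(a) + std::abs(b) + std::abs(c);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        dy.push_back(a); dx.push_back(b); dz.push_back(c);
      }
}

// [[Rcpp::export]]
IntegerVector cc_label3_cpp(LogicalVector mask, IntegerVector dim,
                            int connectivity) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  IntegerVector lab(n, 0);
  std::vector<int> dy, dx, dz;
  neigh_offsets(connectivity, dy, dx, dz);
  int k = 0;
  std::vector<int> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    lab[i] = ++k;
    stack.clear();
    stack.push_back((int)i);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int z = cur / (ny * nx), rem = cur % (ny * nx);
      int x = rem / ny, y = rem % ny;
      for (size_t j = 0; j < dy.size(); ++j) {
        int yy = y + dy[j], xx = x + dx[j], zz = z + dz[j];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
          continue;
        int ii = lin(yy, xx, zz, ny, nx);
        if (mask[ii] && !lab[ii]) { lab[ii] = k; stack.push_back(ii); }
      }
    }
  }
  lab.attr("n_objects") = k;
  return lab;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher) with site
// propagation; spacing-aware. f: squared distances, site: index of nearest
// source along the processed line(s) so far.
static void dt1d(std::vector<double> &f, std::vector<int> &site, double s) {
  int n = (int)f.size();
  std::vector<int> v(n); std::vector<double> zb(n + 1);
  std::vector<double> fout(n); std::vector<int> sout(n);
  double s2 = s * s;
  int k = 0;
  v[0] = 0; zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double sq;
    while (true) {
      int p = v[k];
      sq = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (sq <= zb[k]) { --k; } else break;
    }
    ++k; v[k] = q; zb[k] = sq; zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    int p = v[k];
    double d = s * (q - p);
    fout[q] = d * d + f[p];
    sout[q] = site[p];
  }
  f = fout; site = sout;
}

// Squared Euclidean distance (µm) from every voxel to the nearest source
// voxel (source = TRUE), plus the linear index (1-based) of that source.
// [[Rcpp::export]]
List edt_sq3_cpp(LogicalVector source, IntegerVector dim, NumericVector spacing) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  const double INF = 1e20;  // finite sentinel: infinity breaks the
                            // parabola-intersection arithmetic (inf - inf)
  NumericVector d(n);
  IntegerVector nearest(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    d[i] = source[i] ? 0.0 : INF;
    nearest[i] = source[i] ? (int)(i + 1) : NA_INTEGER;
  }
  bool any_src = false;
  for (R_xlen_t i = 0; i < n; ++i) if (source[i]) { any_src = true; break; }
  if (!any_src) return List::create(_["dist_sq"] = d, _["nearest"] = nearest);

  // pass along y
  {
    std::vector<double> f(ny); std::vector<int> st(ny);
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        for (int y = 0; y < ny; ++y) {
          int i = lin(y, x, z, ny, nx); f[y] = d[i]; st[y] = nearest[i];
        }
        dt1d(f, st, spacing[0]);
        for (int y = 0; y < ny; ++y) {
          int i = lin(y, x, z, ny, nx); d[i] = f[y]; nearest[i] = st[y];
        }
      }
  }
  // pass along x
  {
    std::vector<double> f(nx); std::vector<int> st(nx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          int i = lin(y, x, z, ny, nx); f[x] = d[i]; st[x] = nearest[i];
        }
        dt1d(f, st, spacing[1]);
        for (int x = 0; x < nx; ++x) {
          int i = lin(y, x, z, ny, nx); d[i] = f[x]; nearest[i] = st[x];
        }
      }
  }
  // pass along z
  {
    std::vector<double> f(nz); std::vector<int> st(nz);
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        for (int z = 0; z < nz; ++z) {
          int i = lin(y, x, z, ny, nx); f[z] = d[i]; st[z] = nearest[i];
        }
        dt1d(f, st, spacing[2]);
        for (int z = 0; z < nz; ++z) {
          int i = lin(y, x, z, ny, nx); d[i] = f[z]; nearest[i] = st[z];
        }
      }
  }
  return List::create(_["dist_sq"] = d, _["nearest"] = nearest);
}

static inline int reflect(int i, int n) {
  // scipy-style 'reflect' (a b c | c b a)
  if (n == 1) return 0;
  int period = 2 * n;
  i = ((i % period) + period) % period;
  if (i >= n) i = period - 1 - i;
  return i;
}

// [[Rcpp::export]]
NumericVector median3_cpp(NumericVector img, IntegerVector dim, int size) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  int r = size / 2;
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  NumericVector out(n);
  std::vector<double> buf; buf.reserve((size_t)size * size * size);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        buf.clear();
        for (int c = -r; c <= r; ++c) {
          int zz = reflect(z + c, nz);
          for (int b = -r; b <= r; ++b) {
            int xx = reflect(x + b, nx);
            for (int a = -r; a <= r; ++a)
              buf.push_back(img[lin(reflect(y + a, ny), xx, zz, ny, nx)]);
          }
        }
        size_t m = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        out[lin(y, x, z, ny, nx)] = buf[m];
      }
  return out;
}

// 1D correlation along one axis (0 = y, 1 = x, 2 = z), reflect padding.
// [[Rcpp::export]]
NumericVector conv1_axis_cpp(NumericVector img, IntegerVector dim,
                             NumericVector kernel, int axis) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  int kl = kernel.size(), r = kl / 2;
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  NumericVector out(n);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int yy = y, xx = x, zz = z;
          if (axis == 0) yy = reflect(y + t, ny);
          else if (axis == 1) xx = reflect(x + t, nx);
          else zz = reflect(z + t, nz);
          acc += kernel[t + r] * img[lin(yy, xx, zz, ny, nx)];
        }
        out[lin(y, x, z, ny, nx)] = acc;
      }
  return out;
}

// Non-flat (ball-topped) grayscale erosion/dilation applied slice by slice.
// Structuring element b(q) = sqrt(r^2 - |q|^2) - r over |q| <= r (pixels).
// [[Rcpp::export]]
NumericVector ball_morph2_cpp(NumericVector img, IntegerVector dim,
                              double radius, bool dilate) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  int r = (int)std::floor(radius);
  std::vector<int> oy, ox; std::vector<double> oh;
  for (int a = -r; a <= r; ++a)
    for (int b = -r; b <= r; ++b) {
      double d2 = (double)a * a + (double)b * b;
      if (d2 <= radius * radius) {
        oy.push_back(a); ox.push_back(b);
        oh.push_back(std::sqrt(radius * radius - d2) - radius);
      }
    }
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  NumericVector out(n);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        double v = dilate ? -std::numeric_limits<double>::infinity()
                          :  std::numeric_limits<double>::infinity();
        for (size_t j = 0; j < oy.size(); ++j) {
          int yy = y + oy[j], xx = x + ox[j];
          if (yy < 0) yy = 0; if (yy >= ny) yy = ny - 1;
          if (xx < 0) xx = 0; if (xx >= nx) xx = nx - 1;
          double w = img[lin(yy, xx, z, ny, nx)];
          if (dilate) { w += oh[j]; if (w > v) v = w; }
          else        { w -= oh[j]; if (w < v) v = w; }
        }
        out[lin(y, x, z, ny, nx)] = v;
      }
  return out;
}

// Seeded watershed by priority flooding: grow labels from seeds in order of
// increasing elevation, restricted to mask.
// [[Rcpp::export]]
IntegerVector watershed3_cpp(NumericVector elevation, IntegerVector seeds,
                             LogicalVector mask, IntegerVector dim,
                             int connectivity) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  IntegerVector lab(n, 0);
  std::vector<int> dy, dx, dz;
  neigh_offsets(connectivity, dy, dx, dz);
  typedef std::tuple<double, long long, int> Node; // (elev, fifo order, index)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  long long order = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (seeds[i] > 0 && mask[i]) {
      lab[i] = seeds[i];
      pq.push(Node(elevation[i], order++, (int)i));
    }
  while (!pq.empty()) {
    int cur = std::get<2>(pq.top()); pq.pop();
    int z = cur / (ny * nx), rem = cur % (ny * nx);
    int x = rem / ny, y = rem % ny;
    for (size_t j = 0; j < dy.size(); ++j) {
      int yy = y + dy[j], xx = x + dx[j], zz = z + dz[j];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
        continue;
      int ii = lin(yy, xx, zz, ny, nx);
      if (mask[ii] && lab[ii] == 0) {
        lab[ii] = lab[cur];
        pq.push(Node(elevation[ii], order++, ii));
      }
    }
  }
  return lab;
}

// Local maxima: strictly above threshold and >= all neighbours.
// [[Rcpp::export]]
LogicalVector local_max3_cpp(NumericVector img, IntegerVector dim,
                             int connectivity, double threshold) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  LogicalVector out(n, false);
  std::vector<int> dy, dx, dz;
  neigh_offsets(connectivity, dy, dx, dz);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        int i = lin(y, x, z, ny, nx);
        double v = img[i];
        if (!(v > threshold)) continue;
        bool is_max = true;
        for (size_t j = 0; j < dy.size() && is_max; ++j) {
          int yy = y + dy[j], xx = x + dx[j], zz = z + dz[j];
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
            continue;
          if (img[lin(yy, xx, zz, ny, nx)] > v) is_max = false;
        }
        out[i] = is_max;
      }
  return out;
}

// Minimum-cost one-to-one assignment (Hungarian algorithm with potentials,
// O(n^2 m)); rows <= cols required. Returns 1-based column for each row.
// [[Rcpp::export]]
IntegerVector hungarian_cpp(NumericMatrix cost) {
  int nr = cost.nrow(), nc = cost.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(nr + 1, 0.0), v(nc + 1, 0.0);
  std::vector<int> p(nc + 1, 0), way(nc + 1, 0);
  for (int i = 1; i <= nr; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(nc + 1, INF);
    std::vector<char> used(nc + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= nc; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= nc; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector ans(nr, NA_INTEGER);
  for (int j = 1; j <= nc; ++j) if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}

// Per-object accumulators for measure_objects: returns per-label sums.
// [[Rcpp::export]]
List object_stats_cpp(IntegerVector labels, NumericVector intensity,
                      IntegerVector dim, int n_objects) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  NumericVector sy(n_objects), sx(n_objects), sz(n_objects), si(n_objects);
  NumericVector wy(n_objects), wx(n_objects), wz(n_objects);
  IntegerVector cnt(n_objects);
  // per-label per-slice voxel counts for max cross-sectional area
  IntegerMatrix slice_cnt(n_objects, nz);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        int l = labels[lin(y, x, z, ny, nx)];
        if (l <= 0) continue;
        int k = l - 1;
        double w = intensity[lin(y, x, z, ny, nx)];
        cnt[k] += 1;
        si[k] += w;
        sy[k] += y; sx[k] += x; sz[k] += z;
        wy[k] += w * y; wx[k] += w * x; wz[k] += w * z;
        slice_cnt(k, z) += 1;
      }
  IntegerVector max_slice(n_objects);
  for (int k = 0; k < n_objects; ++k) {
    int mx = 0;
    for (int z = 0; z < nz; ++z) if (slice_cnt(k, z) > mx) mx = slice_cnt(k, z);
    max_slice[k] = mx;
  }
  return List::create(_["count"] = cnt, _["sum_intensity"] = si,
                      _["sum_y"] = sy, _["sum_x"] = sx, _["sum_z"] = sz,
                      _["wsum_y"] = wy, _["wsum_x"] = wx, _["wsum_z"] = wz,
                      _["max_slice_count"] = max_slice);
}

// Minimum centre-to-centre distance (µm, squared) from each child object to
// parent voxels, given the EDT-to-parents grid; also nearest parent label.
// [[Rcpp::export]]
List child_min_dist_cpp(IntegerVector child_labels, NumericVector dist_sq,
                        IntegerVector nearest, IntegerVector parent_labels,
                        int n_children) {
  R_xlen_t n = child_labels.size();
  NumericVector best(n_children, std::numeric_limits<double>::infinity());
  IntegerVector best_parent(n_children, NA_INTEGER);
  for (R_xlen_t i = 0; i < n; ++i) {
    int c = child_labels[i];
    if (c <= 0) continue;
    double d = dist_sq[i];
    if (d < best[c - 1]) {
      best[c - 1] = d;
      int src = nearest[i];
      best_parent[c - 1] = (src == NA_INTEGER) ? NA_INTEGER
                                               : parent_labels[src - 1];
    }
  }
  return List::create(_["min_dist_sq"] = best, _["nearest_parent"] = best_parent);
}
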