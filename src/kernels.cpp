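// 3D image kernels used throughout the segmentation pipeline.
//
// All volumes use the package's fixed axis order (plane, row, column):
// an R array with dim = c(nz, ny, nx), so the plane index varies fastest
// in memory. Helper idx() encodes that layout once.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline R_xlen_t idx3(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing with mirror (reflect) boundary handling.
// sigma is per-axis (z, y, x); sigma 0 skips an axis entirely.
// ---------------------------------------------------------------------------

static std::vector<double> gauss_kernel(double sigma) {
  int r = (int)std::ceil(4.0 * sigma);
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    double v = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    k[i + r] = v;
    s += v;
  }
  for (double& v : k) v /= s;
  return k;
}

// reflect index into [0, n-1] (mirror without repeating the edge sample
// for n > 1; clamps for n == 1)
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * (n - 1);
  i = i % period;
  if (i < 0) i += period;
  if (i >= n) i = period - i;
  return i;
}

// [[Rcpp::export(name = ".gaussian_smooth3d")]]
NumericVector gaussian_smooth3d(NumericVector vol, NumericVector sigma) {
  IntegerVector dim = vol.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int n[3] = {nz, ny, nx};
  NumericVector cur = clone(vol);
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    std::vector<double> k = gauss_kernel(s);
    int r = ((int)k.size() - 1) / 2;
    NumericVector out(cur.size());
    out.attr("dim") = dim;
    int len = n[ax];
    // iterate over all lines along axis ax
    for (int z = 0; z < (ax == 0 ? 1 : nz); ++z) {
      for (int y = 0; y < (ax == 1 ? 1 : ny); ++y) {
        for (int x = 0; x < (ax == 2 ? 1 : nx); ++x) {
          for (int t = 0; t < len; ++t) {
            double acc = 0.0;
            for (int j = -r; j <= r; ++j) {
              int tt = reflect(t + j, len);
              int zz = (ax == 0) ? tt : z;
              int yy = (ax == 1) ? tt : y;
              int xx = (ax == 2) ? tt : x;
              acc += k[j + r] * cur[idx3(zz, yy, xx, nz, ny)];
            }
            int zz = (ax == 0) ? t : z;
            int yy = (ax == 1) ? t : y;
            int xx = (ax == 2) ? t : x;
            out[idx3(zz, yy, xx, nz, ny)] = acc;
          }
        }
      }
    }
    cur = out;
  }
  cur.attr("dim") = dim;
  return cur;
}

// ---------------------------------------------------------------------------
// 3D connected-component labelling (6- or 26-connectivity), BFS, labels
// assigned in raster scan order so output is deterministic.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d(LogicalVector mask, int connectivity) {
  IntegerVector dim = mask.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t nvox = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(nvox);
  lab.attr("dim") = dim;

  std::vector<int> dz, dy, dx;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
  int nnb = (int)dz.size();

  std::vector<R_xlen_t> stack;
  int next = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx3(z, y, x, nz, ny);
        if (!mask[i] || lab[i] != 0) continue;
        ++next;
        lab[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          R_xlen_t cur = stack.back(); stack.pop_back();
          int cz = (int)(cur % nz);
          int cy = (int)((cur / nz) % ny);
          int cx = (int)(cur / ((R_xlen_t)nz * ny));
          for (int k = 0; k < nnb; ++k) {
            int zz = cz + dz[k], yy = cy + dy[k], xx = cx + dx[k];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            R_xlen_t j = idx3(zz, yy, xx, nz, ny);
            if (mask[j] && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
        }
      }
  return lab;
}

// ---------------------------------------------------------------------------
// Exact 3D squared Euclidean distance transform (Felzenszwalb-Huttenlocher),
// anisotropy-aware: step[i] is the physical length of one voxel along axis i.
// Returns distance (not squared) to the nearest background (FALSE) voxel.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double>& f, std::vector<double>& d, double w2) {
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector fg, NumericVector step) {
  IntegerVector dim = fg.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int n[3] = {nz, ny, nx};
  R_xlen_t nvox = (R_xlen_t)nz * ny * nx;
  const double BIG = 1e30;
  NumericVector d(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) d[i] = fg[i] ? BIG : 0.0;

  for (int ax = 0; ax < 3; ++ax) {
    int len = n[ax];
    double w2 = step[ax] * step[ax];
    std::vector<double> f(len), out(len);
    for (int z = 0; z < (ax == 0 ? 1 : nz); ++z)
      for (int y = 0; y < (ax == 1 ? 1 : ny); ++y)
        for (int x = 0; x < (ax == 2 ? 1 : nx); ++x) {
          for (int t = 0; t < len; ++t) {
            int zz = (ax == 0) ? t : z, yy = (ax == 1) ? t : y,
                xx = (ax == 2) ? t : x;
            f[t] = d[idx3(zz, yy, xx, nz, ny)];
          }
          dt1d(f, out, w2);
          for (int t = 0; t < len; ++t) {
            int zz = (ax == 0) ? t : z, yy = (ax == 1) ? t : y,
                xx = (ax == 2) ? t : x;
            d[idx3(zz, yy, xx, nz, ny)] = out[t];
          }
        }
  }
  for (R_xlen_t i = 0; i < nvox; ++i)
    d[i] = (d[i] >= BIG) ? R_PosInf : std::sqrt(d[i]);
  d.attr("dim") = dim;
  return d;
}

// ---------------------------------------------------------------------------
// Seeded flooding. Two variants sharing one priority-queue engine:
//  * flood_geodesic: priority = geodesic distance from the seed set
//    (Dijkstra with Euclidean 26-neighbour step lengths) -- used to carve
//    the cell mask into cells from nucleus seeds;
//  * flood_priority: priority = a supplied scalar image (ascending) --
//    classic marker-based watershed when fed the negated distance
//    transform, used to split touching nuclei.
// Ties are broken by insertion order (first-reached seed wins) under a
// deterministic raster initialisation, so outputs are run-to-run stable.
// ---------------------------------------------------------------------------

struct QNode {
  double prio;
  unsigned long long order;
  R_xlen_t vox;
  int label;
};
struct QCmp {
  bool operator()(const QNode& a, const QNode& b) const {
    if (a.prio != b.prio) return a.prio > b.prio;
    return a.order > b.order;
  }
};

static IntegerVector flood_engine(const LogicalVector& mask,
                                  const IntegerVector& seeds,
                                  const NumericVector* prio_img,
                                  const NumericVector* step) {
  IntegerVector dim = mask.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t nvox = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(nvox);
  lab.attr("dim") = dim;

  std::vector<int> dz, dy, dx;
  std::vector<double> slen;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
        double wz = step ? (*step)[0] : 1.0;
        double wy = step ? (*step)[1] : 1.0;
        double wx = step ? (*step)[2] : 1.0;
        slen.push_back(std::sqrt(a * a * wz * wz + b * b * wy * wy +
                                 c * c * wx * wx));
      }
  int nnb = (int)dz.size();

  std::priority_queue<QNode, std::vector<QNode>, QCmp> pq;
  std::vector<double> dist(nvox, std::numeric_limits<double>::infinity());
  std::vector<char> settled(nvox, 0);
  unsigned long long order = 0;

  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx3(z, y, x, nz, ny);
        if (seeds[i] > 0 && mask[i]) {
          double p = prio_img ? (*prio_img)[i] : 0.0;
          dist[i] = p;
          pq.push({p, order++, i, seeds[i]});
        }
      }

  while (!pq.empty()) {
    QNode nd = pq.top(); pq.pop();
    if (settled[nd.vox]) continue;
    settled[nd.vox] = 1;
    lab[nd.vox] = nd.label;
    int cz = (int)(nd.vox % nz);
    int cy = (int)((nd.vox / nz) % ny);
    int cx = (int)(nd.vox / ((R_xlen_t)nz * ny));
    for (int k = 0; k < nnb; ++k) {
      int zz = cz + dz[k], yy = cy + dy[k], xx = cx + dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      R_xlen_t j = idx3(zz, yy, xx, nz, ny);
      if (!mask[j] || settled[j]) continue;
      double np = prio_img ? std::max(nd.prio, (*prio_img)[j])
                           : nd.prio + slen[k];
      if (np < dist[j]) {
        dist[j] = np;
        pq.push({np, order++, j, nd.label});
      }
    }
  }
  return lab;
}

// [[Rcpp::export(name = ".flood_geodesic")]]
IntegerVector flood_geodesic(LogicalVector mask, IntegerVector seeds,
                             NumericVector step) {
  return flood_engine(mask, seeds, nullptr, &step);
}

// [[Rcpp::export(name = ".flood_priority")]]
IntegerVector flood_priority(LogicalVector mask, IntegerVector seeds,
                             NumericVector prio) {
  return flood_engine(mask, seeds, &prio, nullptr);
}

// ---------------------------------------------------------------------------
// Label-preserving morphological erosion: a voxel keeps its label only if
// every structuring-element neighbour (offsets rows: dz, dy, dx) holds the
// same label. Offsets reaching outside the volume count as mismatches.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".erode_labels")]]
IntegerVector erode_labels(IntegerVector lab, IntegerMatrix offsets) {
  IntegerVector dim = lab.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t nvox = (R_xlen_t)nz * ny * nx;
  IntegerVector out(nvox);
  out.attr("dim") = dim;
  int noff = offsets.nrow();
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx3(z, y, x, nz, ny);
        int L = lab[i];
        if (L == 0) continue;
        bool keep = true;
        for (int k = 0; k < noff && keep; ++k) {
          int zz = z + offsets(k, 0), yy = y + offsets(k, 1),
              xx = x + offsets(k, 2);
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) {
            keep = false;
          } else if (lab[idx3(zz, yy, xx, nz, ny)] != L) {
            keep = false;
          }
        }
        if (keep) out[i] = L;
      }
  return out;
}

// ---------------------------------------------------------------------------
// 2D Canny edge detection on one plane + closed-contour filling.
// Steps: Gaussian smooth, Sobel gradients, non-maximum suppression,
// double-threshold hysteresis (8-connected), then hole filling: any
// non-edge pixel not reachable from the plane border through non-edge
// pixels (4-connectivity) is interior and gets filled.
// Thresholds may be absolute or quantiles of the gradient-magnitude image.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".canny_fill_plane")]]
LogicalMatrix canny_fill_plane(NumericMatrix img, double sigma,
                               double low, double high, bool quantiles,
                               double blank_guard) {
  int ny = img.nrow(), nx = img.ncol();
  // smooth (separable, reflect)
  NumericMatrix sm(ny, nx);
  if (sigma > 0) {
    std::vector<double> k = gauss_kernel(sigma);
    int r = ((int)k.size() - 1) / 2;
    NumericMatrix tmp(ny, nx);
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        double acc = 0;
        for (int j = -r; j <= r; ++j) acc += k[j + r] * img(reflect(y + j, ny), x);
        tmp(y, x) = acc;
      }
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double acc = 0;
        for (int j = -r; j <= r; ++j) acc += k[j + r] * tmp(y, reflect(x + j, nx));
        sm(y, x) = acc;
      }
  } else {
    sm = clone(img);
  }

  // Sobel gradients (replicate edges)
  NumericMatrix gx(ny, nx), gy(ny, nx), mag(ny, nx);
  auto at = [&](int y, int x) {
    if (y < 0) y = 0;
    if (y >= ny) y = ny - 1;
    if (x < 0) x = 0;
    if (x >= nx) x = nx - 1;
    return sm(y, x);
  };
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      double sx = (at(y - 1, x + 1) + 2 * at(y, x + 1) + at(y + 1, x + 1)) -
                  (at(y - 1, x - 1) + 2 * at(y, x - 1) + at(y + 1, x - 1));
      double sy = (at(y + 1, x - 1) + 2 * at(y + 1, x) + at(y + 1, x + 1)) -
                  (at(y - 1, x - 1) + 2 * at(y - 1, x) + at(y - 1, x + 1));
      gx(y, x) = sx;
      gy(y, x) = sy;
      mag(y, x) = std::sqrt(sx * sx + sy * sy);
    }

  // blank-plane guard: a plane whose gradient maximum is within
  // blank_guard robust units of its median carries no edges worth
  // detecting (pure noise); skip it so quantile thresholds cannot
  // hallucinate contours on empty planes. Disabled when blank_guard <= 0.
  if (blank_guard > 0) {
    std::vector<double> v(mag.begin(), mag.end());
    std::nth_element(v.begin(), v.begin() + v.size() / 2, v.end());
    double med = v[v.size() / 2];
    double mx = *std::max_element(mag.begin(), mag.end());
    if (mx <= 0 || (med > 0 && mx < blank_guard * med))
      return LogicalMatrix(ny, nx);
  }

  if (quantiles) {
    std::vector<double> v(mag.begin(), mag.end());
    std::sort(v.begin(), v.end());
    auto q = [&](double p) {
      // linear interpolation (type-7 style)
      double h = p * (v.size() - 1);
      size_t lo = (size_t)std::floor(h);
      size_t hi = (size_t)std::ceil(h);
      return v[lo] + (h - lo) * (v[hi] - v[lo]);
    };
    low = q(low);
    high = q(high);
  }

  // non-maximum suppression along quantized gradient direction
  LogicalMatrix nms(ny, nx);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      double m = mag(y, x);
      if (m <= 0) continue;
      double ang = std::atan2(gy(y, x), gx(y, x));
      if (ang < 0) ang += M_PI;
      int dy0, dx0;
      if (ang < M_PI / 8 || ang >= 7 * M_PI / 8) { dy0 = 0; dx0 = 1; }
      else if (ang < 3 * M_PI / 8) { dy0 = 1; dx0 = 1; }
      else if (ang < 5 * M_PI / 8) { dy0 = 1; dx0 = 0; }
      else { dy0 = 1; dx0 = -1; }
      double m1 = (y + dy0 >= 0 && y + dy0 < ny && x + dx0 >= 0 && x + dx0 < nx)
                      ? mag(y + dy0, x + dx0) : 0;
      double m2 = (y - dy0 >= 0 && y - dy0 < ny && x - dx0 >= 0 && x - dx0 < nx)
                      ? mag(y - dy0, x - dx0) : 0;
      if (m >= m1 && m >= m2) nms(y, x) = true;
    }

  // hysteresis
  LogicalMatrix edge(ny, nx);
  std::vector<std::pair<int, int>> stack;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x)
      if (nms(y, x) && mag(y, x) >= high) {
        edge(y, x) = true;
        stack.push_back({y, x});
      }
  while (!stack.empty()) {
    auto [y, x] = stack.back(); stack.pop_back();
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b) {
        int yy = y + a, xx = x + b;
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        if (!edge(yy, xx) && nms(yy, xx) && mag(yy, xx) >= low) {
          edge(yy, xx) = true;
          stack.push_back({yy, xx});
        }
      }
  }

  // fill: flood non-edge background from the border (4-connectivity)
  LogicalMatrix outside(ny, nx);
  stack.clear();
  for (int x = 0; x < nx; ++x) {
    if (!edge(0, x)) { outside(0, x) = true; stack.push_back({0, x}); }
    if (!edge(ny - 1, x)) { outside(ny - 1, x) = true; stack.push_back({ny - 1, x}); }
  }
  for (int y = 0; y < ny; ++y) {
    if (!edge(y, 0)) { outside(y, 0) = true; stack.push_back({y, 0}); }
    if (!edge(y, nx - 1)) { outside(y, nx - 1) = true; stack.push_back({y, nx - 1}); }
  }
  const int d4y[4] = {1, -1, 0, 0};
  const int d4x[4] = {0, 0, 1, -1};
  while (!stack.empty()) {
    auto [y, x] = stack.back(); stack.pop_back();
    for (int k = 0; k < 4; ++k) {
      int yy = y + d4y[k], xx = x + d4x[k];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      if (!edge(yy, xx) && !outside(yy, xx)) {
        outside(yy, xx) = true;
        stack.push_back({yy, xx});
      }
    }
  }
  LogicalMatrix filled(ny, nx);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x)
      filled(y, x) = edge(y, x) || !outside(y, x);
  return filled;
}

// ---------------------------------------------------------------------------
// Per-label tallies used for object tables and plurality voting.
// ---------------------------------------------------------------------------

// volume, centroid and bounding box per label; returns a list of vectors
// [[Rcpp::export(name = ".label_stats")]]
List label_stats(IntegerVector lab) {
  IntegerVector dim = lab.attr("dim");
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int maxlab = 0;
  for (R_xlen_t i = 0; i < lab.size(); ++i)
    if (lab[i] > maxlab) maxlab = lab[i];
  std::vector<double> vol(maxlab, 0), sz(maxlab, 0), sy(maxlab, 0), sx(maxlab, 0);
  std::vector<int> z0(maxlab, INT_MAX), z1(maxlab, -1), y0(maxlab, INT_MAX),
      y1(maxlab, -1), x0(maxlab, INT_MAX), x1(maxlab, -1);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int L = lab[idx3(z, y, x, nz, ny)];
        if (L == 0) continue;
        int k = L - 1;
        vol[k] += 1; sz[k] += z; sy[k] += y; sx[k] += x;
        if (z < z0[k]) z0[k] = z;
        if (z > z1[k]) z1[k] = z;
        if (y < y0[k]) y0[k] = y;
        if (y > y1[k]) y1[k] = y;
        if (x < x0[k]) x0[k] = x;
        if (x > x1[k]) x1[k] = x;
      }
  NumericVector V(maxlab), CZ(maxlab), CY(maxlab), CX(maxlab);
  IntegerVector Z0(maxlab), Z1(maxlab), Y0(maxlab), Y1(maxlab), X0(maxlab),
      X1(maxlab);
  for (int k = 0; k < maxlab; ++k) {
    V[k] = vol[k];
    if (vol[k] > 0) {
      CZ[k] = sz[k] / vol[k] + 1;  // 1-based, matching R indexing
      CY[k] = sy[k] / vol[k] + 1;
      CX[k] = sx[k] / vol[k] + 1;
      Z0[k] = z0[k] + 1; Z1[k] = z1[k] + 1;
      Y0[k] = y0[k] + 1; Y1[k] = y1[k] + 1;
      X0[k] = x0[k] + 1; X1[k] = x1[k] + 1;
    } else {
      CZ[k] = CY[k] = CX[k] = NA_REAL;
      Z0[k] = Z1[k] = Y0[k] = Y1[k] = X0[k] = X1[k] = NA_INTEGER;
    }
  }
  return List::create(_["label"] = seq_len(maxlab), _["volume"] = V,
                      _["centroid_z"] = CZ, _["centroid_y"] = CY,
                      _["centroid_x"] = CX, _["bbox_z0"] = Z0,
                      _["bbox_z1"] = Z1, _["bbox_y0"] = Y0, _["bbox_y1"] = Y1,
                      _["bbox_x0"] = X0, _["bbox_x1"] = X1);
}

// cross-tabulate two label volumes over voxels where both are nonzero;
// returns matrix (rows: labels of a, cols: labels of b) of shared voxels
// [[Rcpp::export(name = ".label_overlap")]]
IntegerMatrix label_overlap(IntegerVector a, IntegerVector b, int na, int nb) {
  IntegerMatrix out(na, nb);
  for (R_xlen_t i = 0; i < a.size(); ++i)
    if (a[i] > 0 && b[i] > 0) out(a[i] - 1, b[i] - 1) += 1;
  return out;
}

// per-punctum voxel counts within each cell label (and count outside cells)
// [[Rcpp::export(name = ".vote_counts")]]
IntegerMatrix vote_counts(IntegerVector obj, IntegerVector cells, int nobj,
                          int ncell) {
  // column ncell (0-based index ncell) holds out-of-cell voxels
  IntegerMatrix out(nobj, ncell + 1);
  for (R_xlen_t i = 0; i < obj.size(); ++i)
    if (obj[i] > 0) {
      int c = cells[i];
      out(obj[i] - 1, c > 0 ? c - 1 : ncell) += 1;
    }
  return out;
}
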