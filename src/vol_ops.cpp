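// Volumetric primitives for anisotropic whole-mouse cryo-image volumes.
// Arrays are column-major with dims (nx, ny, nz): linear index i + nx*(j + ny*k).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // reflect-101 boundary handling
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  if (sigma <= 0) { return std::vector<double>(1, 1.0); }
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;
  return k;
}

// separable 1-D convolution along one axis with reflect padding
static void conv_axis(std::vector<double> &v, int nx, int ny, int nz,
                      const std::vector<double> &ker, int axis) {
  int r = ((int)ker.size() - 1) / 2;
  std::vector<double> out(v.size());
  int n[3] = {nx, ny, nz};
  int na = n[axis];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c[3] = {i, j, k};
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int cc[3] = {i, j, k};
          cc[axis] = reflect_idx(c[axis] + t, na);
          acc += ker[t + r] * v[cc[0] + (size_t)nx * (cc[1] + (size_t)ny * cc[2])];
        }
        out[i + (size_t)nx * (j + (size_t)ny * k)] = acc;
      }
  v.swap(out);
}

// [[Rcpp::export(name = ".gauss3_cpp")]]
NumericVector gauss3_cpp(NumericVector vol, IntegerVector dim, NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  for (int a = 0; a < 3; ++a) {
    if (sigma[a] > 0) conv_axis(v, nx, ny, nz, gauss_kernel(sigma[a]), a);
  }
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}

// Scale-normalized negative-LoG blob response, 2-D per slice, maximum over scales.
// [[Rcpp::export(name = ".log2d_max_cpp")]]
NumericVector log2d_max_cpp(NumericVector vol, IntegerVector dim, NumericVector sigmas) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t npx = (size_t)nx * ny;
  NumericVector out(vol.size());
  std::vector<double> sl(npx), sm(npx);
  for (int k = 0; k < nz; ++k) {
    double *dst = &out[0] + npx * k;
    const double *src = &vol[0] + npx * k;
    for (size_t p = 0; p < npx; ++p) dst[p] = R_NegInf;
    for (int s = 0; s < sigmas.size(); ++s) {
      double sig = sigmas[s];
      std::copy(src, src + npx, sl.begin());
      std::vector<double> ker = gauss_kernel(sig);
      conv_axis(sl, nx, ny, 1, ker, 0);
      conv_axis(sl, nx, ny, 1, ker, 1);
      // 4-neighbour Laplacian with reflect padding, negated, times sigma^2
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          double c = sl[i + (size_t)nx * j];
          double lap = sl[reflect_idx(i - 1, nx) + (size_t)nx * j] +
                       sl[reflect_idx(i + 1, nx) + (size_t)nx * j] +
                       sl[i + (size_t)nx * reflect_idx(j - 1, ny)] +
                       sl[i + (size_t)nx * reflect_idx(j + 1, ny)] - 4.0 * c;
          double resp = -sig * sig * lap;
          double *o = dst + i + (size_t)nx * j;
          if (resp > *o) *o = resp;
        }
    }
  }
  out.attr("dim") = dim;
  return out;
}

static void neighbor_offsets(int conn, int nx, int ny,
                             std::vector<long long> &offs,
                             std::vector<int> &dxs, std::vector<int> &dys, std::vector<int> &dzs) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (conn == 6 && ad != 1) continue;
        offs.push_back((long long)dx + (long long)nx * (dy + (long long)ny * dz));
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
}

// 3-D connected components, labels assigned in scan-order discovery (deterministic)
// [[Rcpp::export(name = ".cc3d_cpp")]]
IntegerVector cc3d_cpp(IntegerVector mask, IntegerVector dim, int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<long long> offs; std::vector<int> dxs, dys, dzs;
  neighbor_offsets(connectivity, nx, ny, offs, dxs, dys, dzs);
  int cur = 0;
  std::vector<size_t> stack;
  for (size_t p = 0; p < n; ++p) {
    if (mask[p] == 0 || lab[p] != 0) continue;
    ++cur;
    lab[p] = cur;
    stack.clear();
    stack.push_back(p);
    while (!stack.empty()) {
      size_t q = stack.back(); stack.pop_back();
      int x = (int)(q % nx), y = (int)((q / nx) % ny), z = (int)(q / ((size_t)nx * ny));
      for (size_t t = 0; t < offs.size(); ++t) {
        int xx = x + dxs[t], yy = y + dys[t], zz = z + dzs[t];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        size_t r = q + offs[t];
        if (mask[r] != 0 && lab[r] == 0) { lab[r] = cur; stack.push_back(r); }
      }
    }
  }
  lab.attr("dim") = dim;
  lab.attr("label_count") = cur;
  return lab;
}

// binary dilation / erosion with an explicit offset list (voxel units)
// [[Rcpp::export(name = ".morph_cpp")]]
IntegerVector morph_cpp(IntegerVector mask, IntegerVector dim, IntegerMatrix offsets, bool dilate) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector out(n);
  if (dilate) {
    for (size_t p = 0; p < n; ++p) {
      if (mask[p] == 0) continue;
      int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / ((size_t)nx * ny));
      for (int t = 0; t < offsets.nrow(); ++t) {
        int xx = x + offsets(t, 0), yy = y + offsets(t, 1), zz = z + offsets(t, 2);
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        out[xx + (size_t)nx * (yy + (size_t)ny * zz)] = 1;
      }
    }
  } else {
    for (size_t p = 0; p < n; ++p) {
      if (mask[p] == 0) continue;
      int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / ((size_t)nx * ny));
      bool keep = true;
      for (int t = 0; t < offsets.nrow() && keep; ++t) {
        int xx = x + offsets(t, 0), yy = y + offsets(t, 1), zz = z + offsets(t, 2);
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) { keep = false; break; }
        if (mask[xx + (size_t)nx * (yy + (size_t)ny * zz)] == 0) keep = false;
      }
      if (keep) out[p] = 1;
    }
  }
  out.attr("dim") = dim;
  return out;
}

// fill background cavities not connected (6-conn) to the volume border
// [[Rcpp::export(name = ".fill_holes_cpp")]]
IntegerVector fill_holes_cpp(IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> outside(n, 0);
  std::vector<size_t> stack;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i != 0 && i != nx - 1 && j != 0 && j != ny - 1 && k != 0 && k != nz - 1) continue;
        size_t p = i + (size_t)nx * (j + (size_t)ny * k);
        if (mask[p] == 0 && !outside[p]) { outside[p] = 1; stack.push_back(p); }
      }
  const long long offs[6] = {-1, 1, -(long long)nx, (long long)nx,
                             -(long long)nx * ny, (long long)nx * ny};
  while (!stack.empty()) {
    size_t q = stack.back(); stack.pop_back();
    int x = (int)(q % nx), y = (int)((q / nx) % ny), z = (int)(q / ((size_t)nx * ny));
    int cs[6][3] = {{x-1,y,z},{x+1,y,z},{x,y-1,z},{x,y+1,z},{x,y,z-1},{x,y,z+1}};
    for (int t = 0; t < 6; ++t) {
      if (cs[t][0] < 0 || cs[t][0] >= nx || cs[t][1] < 0 || cs[t][1] >= ny ||
          cs[t][2] < 0 || cs[t][2] >= nz) continue;
      size_t r = q + offs[t];
      if (mask[r] == 0 && !outside[r]) { outside[r] = 1; stack.push_back(r); }
    }
  }
  IntegerVector out(n);
  for (size_t p = 0; p < n; ++p) out[p] = (mask[p] != 0 || !outside[p]) ? 1 : 0;
  out.attr("dim") = dim;
  return out;
}

// 3x3x3 Prewitt gradient magnitude (derivative [-1,0,1] on one axis,
// box smoothing [1,1,1] on the other two), replicate padding
// [[Rcpp::export(name = ".prewitt3_cpp")]]
NumericVector prewitt3_cpp(NumericVector vol, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n);
  auto at = [&](int x, int y, int z) {
    x = std::min(std::max(x, 0), nx - 1);
    y = std::min(std::max(y, 0), ny - 1);
    z = std::min(std::max(z, 0), nz - 1);
    return vol[x + (size_t)nx * (y + (size_t)ny * z)];
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double gx = 0, gy = 0, gz = 0;
        for (int b = -1; b <= 1; ++b)
          for (int c = -1; c <= 1; ++c) {
            gx += at(i + 1, j + b, k + c) - at(i - 1, j + b, k + c);
            gy += at(i + b, j + 1, k + c) - at(i + b, j - 1, k + c);
            gz += at(i + b, j + c, k + 1) - at(i + b, j + c, k - 1);
          }
        out[i + (size_t)nx * (j + (size_t)ny * k)] = std::sqrt(gx * gx + gy * gy + gz * gz);
      }
  out.attr("dim") = dim;
  return out;
}

// Marker-controlled watershed by priority flooding. Markers > 0 are foreground
// seeds; the volume border is the background marker (label 0 in the output).
// Ties are broken by insertion order (deterministic).
// [[Rcpp::export(name = ".watershed_cpp")]]
IntegerVector watershed_cpp(NumericVector grad, IntegerVector markers, IntegerVector dim,
                            int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<int> lab(n, 0);      // 0 = unassigned
  const int BG = -1;               // background basin
  typedef std::pair<double, std::pair<long long, size_t> > QE; // (value, (counter, idx))
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  long long counter = 0;
  // seed foreground markers in index order, then the border as background
  for (size_t p = 0; p < n; ++p)
    if (markers[p] > 0) { lab[p] = markers[p]; pq.push(QE(R_NegInf, std::make_pair(counter++, p))); }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i != 0 && i != nx - 1 && j != 0 && j != ny - 1 && k != 0 && k != nz - 1) continue;
        size_t p = i + (size_t)nx * (j + (size_t)ny * k);
        if (lab[p] == 0) { lab[p] = BG; pq.push(QE(R_NegInf, std::make_pair(counter++, p))); }
      }
  std::vector<long long> offs; std::vector<int> dxs, dys, dzs;
  neighbor_offsets(connectivity, nx, ny, offs, dxs, dys, dzs);
  while (!pq.empty()) {
    QE e = pq.top(); pq.pop();
    size_t q = e.second.second;
    int x = (int)(q % nx), y = (int)((q / nx) % ny), z = (int)(q / ((size_t)nx * ny));
    for (size_t t = 0; t < offs.size(); ++t) {
      int xx = x + dxs[t], yy = y + dys[t], zz = z + dzs[t];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      size_t r = q + offs[t];
      if (lab[r] == 0) {
        lab[r] = lab[q];
        pq.push(QE(grad[r], std::make_pair(counter++, r)));
      }
    }
  }
  IntegerVector out(n);
  for (size_t p = 0; p < n; ++p) out[p] = (lab[p] == BG) ? 0 : lab[p];
  out.attr("dim") = dim;
  return out;
}

// resampling onto a new grid; ratio = target_spacing / source_spacing per axis
// [[Rcpp::export(name = ".resample3_cpp")]]
NumericVector resample3_cpp(NumericVector vol, IntegerVector dim, IntegerVector outdim,
                            NumericVector ratio, bool nearest) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = outdim[0], oy = outdim[1], oz = outdim[2];
  NumericVector out((size_t)ox * oy * oz);
  auto src = [&](int x, int y, int z) {
    return vol[x + (size_t)nx * (y + (size_t)ny * z)];
  };
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i) {
        double xi = (i + 0.5) * ratio[0] - 0.5;
        double yj = (j + 0.5) * ratio[1] - 0.5;
        double zk = (k + 0.5) * ratio[2] - 0.5;
        double val;
        if (nearest) {
          int x = std::min(std::max((int)std::floor(xi + 0.5), 0), nx - 1);
          int y = std::min(std::max((int)std::floor(yj + 0.5), 0), ny - 1);
          int z = std::min(std::max((int)std::floor(zk + 0.5), 0), nz - 1);
          val = src(x, y, z);
        } else {
          xi = std::min(std::max(xi, 0.0), nx - 1.0);
          yj = std::min(std::max(yj, 0.0), ny - 1.0);
          zk = std::min(std::max(zk, 0.0), nz - 1.0);
          int x0 = (int)std::floor(xi), y0 = (int)std::floor(yj), z0 = (int)std::floor(zk);
          int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1), z1 = std::min(z0 + 1, nz - 1);
          double fx = xi - x0, fy = yj - y0, fz = zk - z0;
          val =
            (1-fx)*(1-fy)*(1-fz)*src(x0,y0,z0) + fx*(1-fy)*(1-fz)*src(x1,y0,z0) +
            (1-fx)*fy*(1-fz)*src(x0,y1,z0)     + fx*fy*(1-fz)*src(x1,y1,z0) +
            (1-fx)*(1-fy)*fz*src(x0,y0,z1)     + fx*(1-fy)*fz*src(x1,y0,z1) +
            (1-fx)*fy*fz*src(x0,y1,z1)         + fx*fy*fz*src(x1,y1,z1);
        }
        out[i + (size_t)ox * (j + (size_t)oy * k)] = val;
      }
  out.attr("dim") = outdim;
  return out;
}

// centered block-mean crop: covers outdim*block voxels around `center` (0-based),
// averaging block cells; voxels outside the volume contribute zero
// [[Rcpp::export(name = ".blockcrop_cpp")]]
NumericVector blockcrop_cpp(NumericVector vol, IntegerVector dim, IntegerVector center,
                            IntegerVector block, IntegerVector outdim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = outdim[0], oy = outdim[1], oz = outdim[2];
  int bx = block[0], by = block[1], bz = block[2];
  int sx = center[0] - (ox * bx) / 2, sy = center[1] - (oy * by) / 2, sz = center[2] - (oz * bz) / 2;
  NumericVector out((size_t)ox * oy * oz);
  double bn = (double)bx * by * bz;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i) {
        double acc = 0.0;
        for (int c = 0; c < bz; ++c) {
          int z = sz + k * bz + c;
          if (z < 0 || z >= nz) continue;
          for (int b = 0; b < by; ++b) {
            int y = sy + j * by + b;
            if (y < 0 || y >= ny) continue;
            for (int a = 0; a < bx; ++a) {
              int x = sx + i * bx + a;
              if (x < 0 || x >= nx) continue;
              acc += vol[x + (size_t)nx * (y + (size_t)ny * z)];
            }
          }
        }
        out[i + (size_t)ox * (j + (size_t)oy * k)] = acc / bn;
      }
  out.attr("dim") = outdim;
  return out;
}

// per-label voxel counts and centroids (0-based voxel coordinates)
// [[Rcpp::export(name = ".label_stats_cpp")]]
List label_stats_cpp(IntegerVector labels, IntegerVector dim, int nlab) {
  int nx = dim[0], ny = dim[1];
  size_t n = labels.size();
  NumericVector count(nlab), cx(nlab), cy(nlab), cz(nlab);
  for (size_t p = 0; p < n; ++p) {
    int l = labels[p];
    if (l <= 0 || l > nlab) continue;
    int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / ((size_t)nx * ny));
    count[l - 1] += 1; cx[l - 1] += x; cy[l - 1] += y; cz[l - 1] += z;
  }
  for (int l = 0; l < nlab; ++l)
    if (count[l] > 0) { cx[l] /= count[l]; cy[l] /= count[l]; cz[l] /= count[l]; }
  return List::create(_["count"] = count, _["cx"] = cx, _["cy"] = cy, _["cz"] = cz);
}
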