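// Small 3D convolutional network: im2col convolutions (BLAS gemm), 'same'
// zero padding, max pooling, global average pooling, dense layers, softmax
// with class-weighted cross entropy, and 2D-affine patch augmentation.
// Activations are (n_voxels, channels) matrices, voxels in (x,y,z) scan
// order; internals run in single precision for memory-bandwidth reasons.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::frowvec;

struct LayerDims { int nx, ny, nz; };

// parsed layer description
struct Layer {
  int type;              // 0 conv, 1 pool, 2 gap, 3 dense
  int kx, ky, kz, out;   // conv
  int sx, sy, sz;        // pool
};

static std::vector<Layer> parse_arch(const List &arch) {
  std::vector<Layer> L;
  for (int i = 0; i < arch.size(); ++i) {
    List lay = arch[i];
    std::string t = as<std::string>(lay["type"]);
    Layer l; l.type = -1; l.kx = l.ky = l.kz = l.out = l.sx = l.sy = l.sz = 0;
    if (t == "conv") {
      l.type = 0;
      IntegerVector k = lay["kernel"];
      l.kx = k[0]; l.ky = k[1]; l.kz = k[2];
      l.out = as<int>(lay["out"]);
    } else if (t == "pool") {
      l.type = 1;
      IntegerVector s = lay["size"];
      l.sx = s[0]; l.sy = s[1]; l.sz = s[2];
    } else if (t == "gap") l.type = 2;
    else if (t == "dense") { l.type = 3; l.out = as<int>(lay["out"]); }
    L.push_back(l);
  }
  return L;
}

struct Weights { std::vector<fmat> W; std::vector<frowvec> b; };

static Weights parse_weights(const List &weights) {
  Weights w;
  for (int i = 0; i < weights.size(); ++i) {
    List wi = weights[i];
    w.W.push_back(arma::conv_to<fmat>::from(as<arma::mat>(wi["W"])));
    w.b.push_back(arma::conv_to<frowvec>::from(as<arma::rowvec>(wi["b"])));
  }
  return w;
}

static fmat im2col3(const fmat &X, int nx, int ny, int nz,
                    int kx, int ky, int kz) {
  int cin = X.n_cols;
  int px = (kx - 1) / 2, py = (ky - 1) / 2, pz = (kz - 1) / 2;
  size_t nvox = (size_t)nx * ny * nz;
  fmat A(nvox, (size_t)kx * ky * kz * cin, arma::fill::zeros);
  for (int kk = 0; kk < kz; ++kk)
    for (int jj = 0; jj < ky; ++jj)
      for (int ii = 0; ii < kx; ++ii) {
        int kidx = ii + kx * (jj + ky * kk);
        int dx = ii - px, dy = jj - py, dz = kk - pz;
        for (int z = 0; z < nz; ++z) {
          int zz = z + dz; if (zz < 0 || zz >= nz) continue;
          for (int y = 0; y < ny; ++y) {
            int yy = y + dy; if (yy < 0 || yy >= ny) continue;
            int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
            if (x0 >= x1) continue;
            size_t rdst = x0 + (size_t)nx * (y + (size_t)ny * z);
            size_t rsrc = (x0 + dx) + (size_t)nx * (yy + (size_t)ny * zz);
            for (int c = 0; c < cin; ++c) {
              const float *s = X.colptr(c) + rsrc;
              float *d = A.colptr((size_t)kidx * cin + c) + rdst;
              std::copy(s, s + (x1 - x0), d);
            }
          }
        }
      }
  return A;
}

static void col2im3(const fmat &dA, fmat &dX, int nx, int ny, int nz,
                    int kx, int ky, int kz) {
  int cin = dX.n_cols;
  int px = (kx - 1) / 2, py = (ky - 1) / 2, pz = (kz - 1) / 2;
  for (int kk = 0; kk < kz; ++kk)
    for (int jj = 0; jj < ky; ++jj)
      for (int ii = 0; ii < kx; ++ii) {
        int kidx = ii + kx * (jj + ky * kk);
        int dx = ii - px, dy = jj - py, dz = kk - pz;
        for (int z = 0; z < nz; ++z) {
          int zz = z + dz; if (zz < 0 || zz >= nz) continue;
          for (int y = 0; y < ny; ++y) {
            int yy = y + dy; if (yy < 0 || yy >= ny) continue;
            int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
            if (x0 >= x1) continue;
            size_t rdst = x0 + (size_t)nx * (y + (size_t)ny * z);
            size_t rsrc = (x0 + dx) + (size_t)nx * (yy + (size_t)ny * zz);
            for (int c = 0; c < cin; ++c) {
              const float *s = dA.colptr((size_t)kidx * cin + c) + rdst;
              float *d = dX.colptr(c) + rsrc;
              for (int t = 0; t < x1 - x0; ++t) d[t] += s[t];
            }
          }
        }
      }
}

struct PoolCache { arma::umat argmax; LayerDims in, out; };

static fmat maxpool3(const fmat &X, LayerDims in, const Layer &l,
                     LayerDims &outd, arma::umat &argmax) {
  int s[3] = {l.sx, l.sy, l.sz};
  outd.nx = std::max(1, in.nx / s[0]);
  outd.ny = std::max(1, in.ny / s[1]);
  outd.nz = std::max(1, in.nz / s[2]);
  size_t nov = (size_t)outd.nx * outd.ny * outd.nz;
  int c = X.n_cols;
  fmat Y(nov, c);
  argmax.set_size(nov, c);
  for (int ch = 0; ch < c; ++ch) {
    const float *xc = X.colptr(ch);
    for (int z = 0; z < outd.nz; ++z)
      for (int y = 0; y < outd.ny; ++y)
        for (int x = 0; x < outd.nx; ++x) {
          size_t ro = x + (size_t)outd.nx * (y + (size_t)outd.ny * z);
          float best = -1e30f; size_t bidx = 0;
          for (int dz = 0; dz < s[2]; ++dz) {
            int zz = z * s[2] + dz; if (zz >= in.nz) continue;
            for (int dy = 0; dy < s[1]; ++dy) {
              int yy = y * s[1] + dy; if (yy >= in.ny) continue;
              for (int dx = 0; dx < s[0]; ++dx) {
                int xx = x * s[0] + dx; if (xx >= in.nx) continue;
                size_t ri = xx + (size_t)in.nx * (yy + (size_t)in.ny * zz);
                float v = xc[ri];
                if (v > best) { best = v; bidx = ri; }
              }
            }
          }
          Y(ro, ch) = best; argmax(ro, ch) = bidx;
        }
  }
  return Y;
}

struct ForwardCache {
  std::vector<fmat> acts;          // per-layer outputs up to GAP input
  std::vector<fmat> ims;           // im2col matrices per conv layer
  std::vector<PoolCache> pools;
  std::vector<int> pool_of_layer;
  std::vector<LayerDims> dims;
  frowvec gap, feat, feat_pre, logits, probs;
  size_t gap_nvox;
};

static void forward_one(const Weights &w, const std::vector<Layer> &layers,
                        const fmat &X0, LayerDims d0, ForwardCache &fc,
                        bool keep_cache) {
  fmat cur = X0;
  LayerDims d = d0;
  int wi = 0;
  int nl = layers.size();
  fc.acts.clear(); fc.ims.clear(); fc.pools.clear();
  fc.pool_of_layer.assign(nl, -1);
  fc.dims.resize(nl);
  for (int li = 0; li < nl; ++li) {
    const Layer &l = layers[li];
    if (l.type == 0) {
      fmat A = im2col3(cur, d.nx, d.ny, d.nz, l.kx, l.ky, l.kz);
      fmat Y = A * w.W[wi];
      Y.each_row() += w.b[wi];
      Y.transform([](float v) { return v > 0 ? v : 0.0f; });
      if (keep_cache) fc.ims.push_back(std::move(A));
      else fc.ims.push_back(fmat());
      cur = std::move(Y);
      ++wi;
    } else if (l.type == 1) {
      PoolCache pc; pc.in = d;
      arma::umat am;
      fmat Y = maxpool3(cur, d, l, pc.out, am);
      pc.argmax = std::move(am);
      d = pc.out;
      fc.pool_of_layer[li] = fc.pools.size();
      fc.pools.push_back(std::move(pc));
      cur = std::move(Y);
    } else if (l.type == 2) {
      fc.gap_nvox = cur.n_rows;
      fc.gap = arma::mean(cur, 0);
      fc.acts.push_back(std::move(cur));
      fc.dims[li] = d;
      fc.feat_pre = fc.gap * w.W[wi] + w.b[wi];
      fc.feat = fc.feat_pre;
      fc.feat.transform([](float v) { return v > 0 ? v : 0.0f; });
      ++wi;
      fc.logits = fc.feat * w.W[wi] + w.b[wi];
      float m = fc.logits.max();
      frowvec e = arma::exp(fc.logits - m);
      fc.probs = e / arma::accu(e);
      return;
    }
    fc.acts.push_back(cur);
    fc.dims[li] = d;
  }
}

static LayerDims dims_from(IntegerVector d) {
  LayerDims x; x.nx = d[0]; x.ny = d[1]; x.nz = d[2]; return x;
}

static fmat sample_mat(const NumericVector &X, int s, size_t nvox, int cin) {
  fmat M(nvox, cin);
  size_t per = nvox * cin;
  const double *base = &X[0] + (size_t)s * per;
  for (int c = 0; c < cin; ++c) {
    float *d = M.colptr(c);
    const double *src = base + (size_t)c * nvox;
    for (size_t i = 0; i < nvox; ++i) d[i] = (float)src[i];
  }
  return M;
}

// [[Rcpp::export(name = ".cnn_forward_cpp")]]
List cnn_forward_cpp(List weights, List arch, NumericVector X, IntegerVector dim) {
  // X dims: (nx, ny, nz, cin, B)
  LayerDims d0 = dims_from(dim);
  int cin = dim[3], B = dim[4];
  size_t nvox = (size_t)d0.nx * d0.ny * d0.nz;
  Weights w = parse_weights(weights);
  std::vector<Layer> layers = parse_arch(arch);
  NumericMatrix probs(B, 2);
  int fw = -1;
  NumericMatrix feats;
  for (int s = 0; s < B; ++s) {
    fmat X0 = sample_mat(X, s, nvox, cin);
    ForwardCache fc;
    forward_one(w, layers, X0, d0, fc, false);
    if (fw < 0) { fw = fc.feat.n_elem; feats = NumericMatrix(B, fw); }
    probs(s, 0) = fc.probs[0]; probs(s, 1) = fc.probs[1];
    for (int t = 0; t < fw; ++t) feats(s, t) = fc.feat[t];
  }
  return List::create(_["probs"] = probs, _["features"] = feats);
}

// output of the last conv layer (pre-GAP) for one sample; used by the
// empirical receptive-field probe
// [[Rcpp::export(name = ".cnn_convstack_cpp")]]
NumericVector cnn_convstack_cpp(List weights, List arch, NumericVector X,
                                IntegerVector dim) {
  LayerDims d0 = dims_from(dim);
  int cin = dim[3];
  size_t nvox = (size_t)d0.nx * d0.ny * d0.nz;
  Weights w = parse_weights(weights);
  std::vector<Layer> layers = parse_arch(arch);
  fmat X0 = sample_mat(X, 0, nvox, cin);
  ForwardCache fc;
  forward_one(w, layers, X0, d0, fc, false);
  const fmat &last = fc.acts.back();
  LayerDims dl = d0;
  for (size_t li = 0; li < layers.size(); ++li) {
    if (layers[li].type == 2) break;
    dl = fc.dims[li];
  }
  NumericVector out(last.n_elem);
  for (size_t i = 0; i < last.n_elem; ++i) out[i] = last[i];
  out.attr("dim") = IntegerVector::create(dl.nx, dl.ny, dl.nz, last.n_cols);
  return out;
}

// loss and gradients for a batch; y in {0,1} (1 = cancer positive, class 2),
// class weights (w1 negatives, w2 positives); natural log; probability of
// the true class clamped at 1e-7
// [[Rcpp::export(name = ".cnn_grad_cpp")]]
List cnn_grad_cpp(List weights, List arch, NumericVector X, IntegerVector dim,
                  IntegerVector y, double w1, double w2) {
  LayerDims d0 = dims_from(dim);
  int cin = dim[3], B = dim[4];
  size_t nvox = (size_t)d0.nx * d0.ny * d0.nz;
  Weights w = parse_weights(weights);
  std::vector<Layer> layers = parse_arch(arch);
  int nW = w.W.size();
  std::vector<fmat> gW(nW);
  std::vector<frowvec> gb(nW);
  for (int i = 0; i < nW; ++i) {
    gW[i] = arma::zeros<fmat>(w.W[i].n_rows, w.W[i].n_cols);
    gb[i] = arma::zeros<frowvec>(w.b[i].n_elem);
  }
  int gapLayer = -1;
  for (size_t li = 0; li < layers.size(); ++li)
    if (layers[li].type == 2) { gapLayer = li; break; }
  double loss = 0.0;
  for (int s = 0; s < B; ++s) {
    fmat X0 = sample_mat(X, s, nvox, cin);
    ForwardCache fc;
    forward_one(w, layers, X0, d0, fc, true);
    int cls = y[s] == 1 ? 1 : 0;
    float cw = cls == 1 ? (float)w2 : (float)w1;
    double p = std::max((double)fc.probs[cls], 1e-7);
    loss += -cw * std::log(p);
    frowvec dlog = fc.probs;
    dlog[cls] -= 1.0f;
    dlog *= cw;
    int wi = nW - 1;
    // logits dense
    gW[wi] += fc.feat.t() * dlog;
    gb[wi] += dlog;
    frowvec dfeat = dlog * w.W[wi].t();
    for (arma::uword t = 0; t < dfeat.n_elem; ++t)
      if (fc.feat_pre[t] <= 0) dfeat[t] = 0.0f;
    --wi;
    // feature dense
    gW[wi] += fc.gap.t() * dfeat;
    gb[wi] += dfeat;
    frowvec dgap = dfeat * w.W[wi].t();
    --wi;
    // GAP
    const fmat &lastact = fc.acts.back();
    fmat dcur(lastact.n_rows, lastact.n_cols);
    for (arma::uword c = 0; c < dcur.n_cols; ++c)
      dcur.col(c).fill(dgap[c] / (float)fc.gap_nvox);
    // conv/pool stack backward
    for (int li = gapLayer - 1; li >= 0; --li) {
      const Layer &l = layers[li];
      if (l.type == 0) {
        const fmat &act = fc.acts[li];
        for (arma::uword t = 0; t < dcur.n_elem; ++t)
          if (act[t] <= 0) dcur[t] = 0.0f;
        gW[wi] += fc.ims[wi].t() * dcur;
        gb[wi] += arma::sum(dcur, 0);
        if (li > 0) {
          fmat dA = dcur * w.W[wi].t();
          const fmat &prev = fc.acts[li - 1];
          LayerDims dprev = fc.dims[li - 1];
          fmat dX(prev.n_rows, prev.n_cols, arma::fill::zeros);
          col2im3(dA, dX, dprev.nx, dprev.ny, dprev.nz, l.kx, l.ky, l.kz);
          dcur = std::move(dX);
        }
        --wi;
      } else if (l.type == 1) {
        const PoolCache &pc = fc.pools[fc.pool_of_layer[li]];
        fmat dX((size_t)pc.in.nx * pc.in.ny * pc.in.nz, dcur.n_cols,
                arma::fill::zeros);
        for (arma::uword c = 0; c < dcur.n_cols; ++c)
          for (arma::uword r = 0; r < dcur.n_rows; ++r)
            dX(pc.argmax(r, c), c) += dcur(r, c);
        dcur = std::move(dX);
      }
    }
  }
  loss /= B;
  List gout(nW);
  for (int i = 0; i < nW; ++i) {
    gout[i] = List::create(
      _["W"] = wrap(arma::conv_to<arma::mat>::from(gW[i] / (float)B)),
      _["b"] = wrap(arma::conv_to<arma::rowvec>::from(gb[i] / (float)B)));
  }
  return List::create(_["loss"] = loss, _["grads"] = gout);
}

// 2D affine augmentation applied identically to every z-slice and channel:
// zoom, rotation (degrees), horizontal/vertical flips, brightness scaling.
// Bilinear interpolation, outside voxels -> 0, output clipped to [0,1].
// [[Rcpp::export(name = ".augment_cpp")]]
NumericVector augment_cpp(NumericVector patch, IntegerVector dim, double zoom,
                          double rot_deg, bool fliph, bool flipv, double brightness) {
  int nx = dim[0], ny = dim[1], nz = dim[2], nc = dim.size() > 3 ? dim[3] : 1;
  NumericVector out(patch.size());
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  double th = rot_deg * M_PI / 180.0;
  double cth = std::cos(th), sth = std::sin(th);
  size_t npx = (size_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double u = i - cx, v = j - cy;
      if (fliph) u = -u;
      if (flipv) v = -v;
      double xs = (cth * u + sth * v) / zoom + cx;
      double ys = (-sth * u + cth * v) / zoom + cy;
      bool inside = xs >= 0 && xs <= nx - 1 && ys >= 0 && ys <= ny - 1;
      int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      double fx = xs - x0, fy = ys - y0;
      int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1);
      for (int k = 0; k < nz; ++k)
        for (int c = 0; c < nc; ++c) {
          size_t base = npx * (k + (size_t)nz * c);
          double val = 0.0;
          if (inside) {
            const double *p = &patch[0] + base;
            val = (1-fx)*(1-fy)*p[x0 + (size_t)nx*y0] + fx*(1-fy)*p[x1 + (size_t)nx*y0] +
                  (1-fx)*fy*p[x0 + (size_t)nx*y1]     + fx*fy*p[x1 + (size_t)nx*y1];
          }
          val *= brightness;
          if (val < 0) val = 0; if (val > 1) val = 1;
          out[i + (size_t)nx * j + base] = val;
        }
    }
  out.attr("dim") = dim;
  return out;
}
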