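// Low-level 3D tensor primitives: same-padded 3D convolution (im2col + GEMM),
// 2x max-pooling, nearest-neighbour upsampling, trilinear warping with
// analytic gradients, separable Gaussian smoothing and connected-component
// labelling.  Tensors are R arrays in column-major order, spatial dims first,
// channels last: x[i, j, k, c].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Hand-rolled single-precision GEMM kernels for the thin matrices this
// package produces (few output channels): BLAS spends most of its time on
// packing overhead there.  Wide products are dispatched to BLAS.
static const arma::uword kSmallN = 16;

// C = A * B  (A: MxK, B: KxN, N small)
static arma::fmat gemm_nn(const arma::fmat& A, const arma::fmat& B) {
  const arma::uword M = A.n_rows, K = A.n_cols, N = B.n_cols;
  if (N > kSmallN) return A * B;
  arma::fmat C(M, N, arma::fill::zeros);
  for (arma::uword k = 0; k < K; ++k) {
    const float* a = A.colptr(k);
    for (arma::uword j = 0; j < N; ++j) {
      const float bkj = B(k, j);
      if (bkj == 0.0f) continue;
      float* c = C.colptr(j);
      for (arma::uword i = 0; i < M; ++i) c[i] += a[i] * bkj;
    }
  }
  return C;
}

// C = A^T * B  (A: MxK, B: MxN, N small) -- the weight-gradient product.
// Single pass over A with N accumulators per column; B stays in cache.
static arma::fmat gemm_tn(const arma::fmat& A, const arma::fmat& B) {
  const arma::uword M = A.n_rows, K = A.n_cols, N = B.n_cols;
  if (N > kSmallN) return A.t() * B;
  arma::fmat C(K, N);
  const float* bp[kSmallN];
  for (arma::uword j = 0; j < N; ++j) bp[j] = B.colptr(j);
  for (arma::uword k = 0; k < K; ++k) {
    const float* a = A.colptr(k);
    float acc[kSmallN] = {0};
    for (arma::uword i = 0; i < M; ++i) {
      const float av = a[i];
      for (arma::uword j = 0; j < N; ++j) acc[j] += av * bp[j][i];
    }
    for (arma::uword j = 0; j < N; ++j) C(k, j) = acc[j];
  }
  return C;
}

// C = A * B^T  (A: MxN, B: KxN, N small) -- the input-gradient product.
// Single pass over C: each output column is a fixed linear combination of
// the N columns of A.
static arma::fmat gemm_nt(const arma::fmat& A, const arma::fmat& B) {
  const arma::uword M = A.n_rows, N = A.n_cols, K = B.n_rows;
  if (N > kSmallN) return A * B.t();
  arma::fmat C(M, K);
  const float* ap[kSmallN];
  for (arma::uword j = 0; j < N; ++j) ap[j] = A.colptr(j);
  for (arma::uword k = 0; k < K; ++k) {
    float w[kSmallN];
    for (arma::uword j = 0; j < N; ++j) w[j] = B(k, j);
    float* c = C.colptr(k);
    for (arma::uword i = 0; i < M; ++i) {
      float acc = 0.0f;
      for (arma::uword j = 0; j < N; ++j) acc += ap[j][i] * w[j];
      c[i] = acc;
    }
  }
  return C;
}

// Build the im2col matrix: one row per output voxel, one column per
// (channel, kernel-offset) pair, offsets varying fastest along axis 1.
// Zero padding (the canonical U-Net choice).  Stored in single precision:
// the GEMMs dominate training time and float halves their memory traffic.
static arma::fmat im2col3(const double* x, int d1, int d2, int d3, int cin,
                          int k) {
  const int r = (k - 1) / 2;
  const int k3 = k * k * k;
  const arma::uword n = (arma::uword)d1 * d2 * d3;
  arma::fmat M(n, (arma::uword)k3 * cin, arma::fill::zeros);
  const R_xlen_t plane = (R_xlen_t)d1 * d2;
  const R_xlen_t vol = plane * d3;
  for (int c = 0; c < cin; ++c) {
    const double* xc = x + (R_xlen_t)c * vol;
    int o = 0;
    for (int oc = -r; oc <= r; ++oc) {
      for (int ob = -r; ob <= r; ++ob) {
        for (int oa = -r; oa <= r; ++oa, ++o) {
          float* col = M.colptr((arma::uword)c * k3 + o);
          const int i0 = std::max(0, -oa), i1 = std::min(d1, d1 - oa);
          for (int kk = 0; kk < d3; ++kk) {
            const int sk = kk + oc;
            if (sk < 0 || sk >= d3) continue;
            for (int jj = 0; jj < d2; ++jj) {
              const int sj = jj + ob;
              if (sj < 0 || sj >= d2) continue;
              const double* src = xc + (R_xlen_t)sk * plane +
                                  (R_xlen_t)sj * d1 + oa;
              float* dst = col + (R_xlen_t)kk * plane + (R_xlen_t)jj * d1;
              for (int ii = i0; ii < i1; ++ii) dst[ii] = (float)src[ii];
            }
          }
        }
      }
    }
  }
  return M;
}

// Scatter-add of a column layout back into an image: adjoint of im2col3.
static void col2im3(const arma::fmat& M, double* gx, int d1, int d2, int d3,
                    int cin, int k) {
  const int r = (k - 1) / 2;
  const int k3 = k * k * k;
  const R_xlen_t plane = (R_xlen_t)d1 * d2;
  const R_xlen_t vol = plane * d3;
  for (int c = 0; c < cin; ++c) {
    double* gc = gx + (R_xlen_t)c * vol;
    int o = 0;
    for (int oc = -r; oc <= r; ++oc) {
      for (int ob = -r; ob <= r; ++ob) {
        for (int oa = -r; oa <= r; ++oa, ++o) {
          const float* col = M.colptr((arma::uword)c * k3 + o);
          const int i0 = std::max(0, -oa), i1 = std::min(d1, d1 - oa);
          for (int kk = 0; kk < d3; ++kk) {
            const int sk = kk + oc;
            if (sk < 0 || sk >= d3) continue;
            for (int jj = 0; jj < d2; ++jj) {
              const int sj = jj + ob;
              if (sj < 0 || sj >= d2) continue;
              double* dst = gc + (R_xlen_t)sk * plane + (R_xlen_t)sj * d1 + oa;
              const float* src = col + (R_xlen_t)kk * plane +
                                 (R_xlen_t)jj * d1;
              for (int ii = i0; ii < i1; ++ii) dst[ii] += (double)src[ii];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3d_forward")]]
NumericVector conv3d_forward(NumericVector x, IntegerVector dims,
                             NumericMatrix w, NumericVector b, int k) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], cin = dims[3];
  const int cout = w.ncol();
  arma::fmat M = im2col3(x.begin(), d1, d2, d3, cin, k);
  arma::fmat W = arma::conv_to<arma::fmat>::from(
      arma::mat(w.begin(), w.nrow(), cout, false, true));
  arma::fmat Y = gemm_nn(M, W);
  Y.each_row() += arma::conv_to<arma::frowvec>::from(
      arma::rowvec(b.begin(), cout, false, true));
  NumericVector out(Y.n_elem);
  std::copy(Y.begin(), Y.end(), out.begin());
  out.attr("dim") = IntegerVector::create(d1, d2, d3, cout);
  return out;
}

// Forward pass that also hands back the im2col matrix (as an external
// pointer) so the backward pass need not rebuild it.
// [[Rcpp::export(name = ".conv3d_forward_cached")]]
List conv3d_forward_cached(NumericVector x, IntegerVector dims,
                           NumericMatrix w, NumericVector b, int k) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], cin = dims[3];
  const int cout = w.ncol();
  XPtr<arma::fmat> M(new arma::fmat(im2col3(x.begin(), d1, d2, d3, cin, k)),
                     true);
  arma::fmat W = arma::conv_to<arma::fmat>::from(
      arma::mat(w.begin(), w.nrow(), cout, false, true));
  arma::fmat Y = gemm_nn(*M, W);
  Y.each_row() += arma::conv_to<arma::frowvec>::from(
      arma::rowvec(b.begin(), cout, false, true));
  NumericVector out(Y.n_elem);
  std::copy(Y.begin(), Y.end(), out.begin());
  out.attr("dim") = IntegerVector::create(d1, d2, d3, cout);
  return List::create(_["y"] = out, _["M"] = M);
}

// [[Rcpp::export(name = ".conv3d_backward")]]
List conv3d_backward(NumericVector x, IntegerVector dims, NumericMatrix w,
                     NumericVector gy, int k, SEXP mcache = R_NilValue) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], cin = dims[3];
  const int cout = w.ncol();
  const arma::uword n = (arma::uword)d1 * d2 * d3;
  arma::fmat Mlocal;
  const arma::fmat* Mp;
  if (mcache != R_NilValue) {
    Mp = XPtr<arma::fmat>(mcache).get();
  } else {
    Mlocal = im2col3(x.begin(), d1, d2, d3, cin, k);
    Mp = &Mlocal;
  }
  const arma::fmat& M = *Mp;
  arma::fmat W = arma::conv_to<arma::fmat>::from(
      arma::mat(w.begin(), w.nrow(), cout, false, true));
  arma::fmat GY = arma::conv_to<arma::fmat>::from(
      arma::mat(gy.begin(), n, cout, false, true));
  arma::fmat GW = gemm_tn(M, GY);
  arma::frowvec GB = arma::sum(GY, 0);
  arma::fmat GM = gemm_nt(GY, W);
  NumericVector gx((R_xlen_t)n * cin);
  col2im3(GM, gx.begin(), d1, d2, d3, cin, k);
  gx.attr("dim") = IntegerVector::create(d1, d2, d3, cin);
  NumericMatrix gw(GW.n_rows, GW.n_cols);
  std::copy(GW.begin(), GW.end(), gw.begin());
  NumericVector gbv(GB.n_elem);
  std::copy(GB.begin(), GB.end(), gbv.begin());
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gbv);
}

// Leaky rectifier forward / backward (slope 0 gives plain ReLU).  The
// backward mask is taken from the pre-activation sign.
// [[Rcpp::export(name = ".act_forward")]]
NumericVector act_forward(NumericVector z, double slope) {
  NumericVector y(z.size());
  for (R_xlen_t i = 0; i < z.size(); ++i)
    y[i] = z[i] > 0 ? z[i] : slope * z[i];
  y.attr("dim") = z.attr("dim");
  return y;
}

// [[Rcpp::export(name = ".act_backward")]]
NumericVector act_backward(NumericVector g, NumericVector z, double slope) {
  NumericVector gz(g.size());
  for (R_xlen_t i = 0; i < g.size(); ++i)
    gz[i] = z[i] > 0 ? g[i] : slope * g[i];
  gz.attr("dim") = g.attr("dim");
  return gz;
}

// [[Rcpp::export(name = ".maxpool3d_forward")]]
List maxpool3d_forward(NumericVector x, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], c = dims[3];
  const int o1 = d1 / 2, o2 = d2 / 2, o3 = d3 / 2;
  const R_xlen_t nin = (R_xlen_t)d1 * d2 * d3;
  const R_xlen_t nout = (R_xlen_t)o1 * o2 * o3;
  NumericVector y(nout * c);
  IntegerVector idx(nout * c);
  const double* px = x.begin();
  for (int ch = 0; ch < c; ++ch) {
    const double* xc = px + (R_xlen_t)ch * nin;
    for (int kk = 0; kk < o3; ++kk)
      for (int jj = 0; jj < o2; ++jj)
        for (int ii = 0; ii < o1; ++ii) {
          double best = -HUGE_VAL;
          R_xlen_t bidx = 0;
          for (int dc = 0; dc < 2; ++dc)
            for (int db = 0; db < 2; ++db)
              for (int da = 0; da < 2; ++da) {
                R_xlen_t p = (R_xlen_t)(2 * kk + dc) * d1 * d2 +
                             (R_xlen_t)(2 * jj + db) * d1 + (2 * ii + da);
                if (xc[p] > best) { best = xc[p]; bidx = p; }
              }
          R_xlen_t q = (R_xlen_t)ch * nout + (R_xlen_t)kk * o1 * o2 +
                       (R_xlen_t)jj * o1 + ii;
          y[q] = best;
          idx[q] = (int)((R_xlen_t)ch * nin + bidx);
        }
  }
  y.attr("dim") = IntegerVector::create(o1, o2, o3, c);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool3d_backward")]]
NumericVector maxpool3d_backward(IntegerVector idx, NumericVector gy,
                                 IntegerVector in_dims) {
  const R_xlen_t n = (R_xlen_t)in_dims[0] * in_dims[1] * in_dims[2] *
                     in_dims[3];
  NumericVector gx(n);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  gx.attr("dim") = in_dims;
  return gx;
}

// [[Rcpp::export(name = ".upsample3d_forward")]]
NumericVector upsample3d_forward(NumericVector x, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], c = dims[3];
  const int o1 = 2 * d1, o2 = 2 * d2, o3 = 2 * d3;
  NumericVector y((R_xlen_t)o1 * o2 * o3 * c);
  const double* px = x.begin();
  double* py = y.begin();
  for (int ch = 0; ch < c; ++ch)
    for (int kk = 0; kk < o3; ++kk)
      for (int jj = 0; jj < o2; ++jj) {
        const double* row = px + (((R_xlen_t)ch * d3 + kk / 2) * d2 +
                                  jj / 2) * d1;
        double* out = py + (((R_xlen_t)ch * o3 + kk) * o2 + jj) * o1;
        for (int ii = 0; ii < o1; ++ii) out[ii] = row[ii / 2];
      }
  y.attr("dim") = IntegerVector::create(o1, o2, o3, c);
  return y;
}

// [[Rcpp::export(name = ".upsample3d_backward")]]
NumericVector upsample3d_backward(NumericVector gy, IntegerVector in_dims) {
  const int d1 = in_dims[0], d2 = in_dims[1], d3 = in_dims[2], c = in_dims[3];
  const int o1 = 2 * d1, o2 = 2 * d2, o3 = 2 * d3;
  NumericVector gx((R_xlen_t)d1 * d2 * d3 * c);
  const double* pg = gy.begin();
  double* px = gx.begin();
  for (int ch = 0; ch < c; ++ch)
    for (int kk = 0; kk < o3; ++kk)
      for (int jj = 0; jj < o2; ++jj) {
        double* row = px + (((R_xlen_t)ch * d3 + kk / 2) * d2 + jj / 2) * d1;
        const double* in = pg + (((R_xlen_t)ch * o3 + kk) * o2 + jj) * o1;
        for (int ii = 0; ii < o1; ++ii) row[ii / 2] += in[ii];
      }
  gx.attr("dim") = in_dims;
  return gx;
}

// Trilinear sampling of img at (i + u1, j + u2, k + u3), coordinates clamped
// to the image extent (clamp-to-edge border).  df holds displacements in
// voxel units, component order matching the spatial axis order.
// [[Rcpp::export(name = ".warp3d_forward")]]
NumericVector warp3d_forward(NumericVector img, NumericVector df,
                             IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector out(n);
  const double* p = img.begin();
  const double* u = df.begin();
  const R_xlen_t plane = (R_xlen_t)d1 * d2;
  R_xlen_t v = 0;
  for (int kk = 0; kk < d3; ++kk)
    for (int jj = 0; jj < d2; ++jj)
      for (int ii = 0; ii < d1; ++ii, ++v) {
        double s1 = ii + u[v], s2 = jj + u[v + n], s3 = kk + u[v + 2 * n];
        s1 = std::min(std::max(s1, 0.0), (double)(d1 - 1));
        s2 = std::min(std::max(s2, 0.0), (double)(d2 - 1));
        s3 = std::min(std::max(s3, 0.0), (double)(d3 - 1));
        const int i0 = clampi((int)std::floor(s1), 0, d1 - 1);
        const int j0 = clampi((int)std::floor(s2), 0, d2 - 1);
        const int k0 = clampi((int)std::floor(s3), 0, d3 - 1);
        const int i1 = std::min(i0 + 1, d1 - 1);
        const int j1 = std::min(j0 + 1, d2 - 1);
        const int k1 = std::min(k0 + 1, d3 - 1);
        const double f1 = s1 - i0, f2 = s2 - j0, f3 = s3 - k0;
        double acc = 0.0;
        for (int c3 = 0; c3 < 2; ++c3)
          for (int c2 = 0; c2 < 2; ++c2)
            for (int c1 = 0; c1 < 2; ++c1) {
              const double w = (c1 ? f1 : 1 - f1) * (c2 ? f2 : 1 - f2) *
                               (c3 ? f3 : 1 - f3);
              acc += w * p[(R_xlen_t)(c3 ? k1 : k0) * plane +
                           (R_xlen_t)(c2 ? j1 : j0) * d1 + (c1 ? i1 : i0)];
            }
        out[v] = acc;
      }
  out.attr("dim") = IntegerVector::create(d1, d2, d3);
  return out;
}

// Gradients of the trilinear warp w.r.t. the image and the displacement
// field.  Where a sampling coordinate is clamped the derivative w.r.t. the
// displacement is zero along that axis.
// [[Rcpp::export(name = ".warp3d_backward")]]
List warp3d_backward(NumericVector img, NumericVector df, IntegerVector dims,
                     NumericVector gout) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector gimg(n), gdf(3 * n);
  const double* p = img.begin();
  const double* u = df.begin();
  const double* go = gout.begin();
  const R_xlen_t plane = (R_xlen_t)d1 * d2;
  R_xlen_t v = 0;
  for (int kk = 0; kk < d3; ++kk)
    for (int jj = 0; jj < d2; ++jj)
      for (int ii = 0; ii < d1; ++ii, ++v) {
        const double g = go[v];
        double s1 = ii + u[v], s2 = jj + u[v + n], s3 = kk + u[v + 2 * n];
        const bool in1 = s1 > 0.0 && s1 < d1 - 1;
        const bool in2 = s2 > 0.0 && s2 < d2 - 1;
        const bool in3 = s3 > 0.0 && s3 < d3 - 1;
        s1 = std::min(std::max(s1, 0.0), (double)(d1 - 1));
        s2 = std::min(std::max(s2, 0.0), (double)(d2 - 1));
        s3 = std::min(std::max(s3, 0.0), (double)(d3 - 1));
        const int i0 = clampi((int)std::floor(s1), 0, d1 - 1);
        const int j0 = clampi((int)std::floor(s2), 0, d2 - 1);
        const int k0 = clampi((int)std::floor(s3), 0, d3 - 1);
        const int i1 = std::min(i0 + 1, d1 - 1);
        const int j1 = std::min(j0 + 1, d2 - 1);
        const int k1 = std::min(k0 + 1, d3 - 1);
        const double f1 = s1 - i0, f2 = s2 - j0, f3 = s3 - k0;
        double g1 = 0.0, g2 = 0.0, g3 = 0.0;
        for (int c3 = 0; c3 < 2; ++c3)
          for (int c2 = 0; c2 < 2; ++c2)
            for (int c1 = 0; c1 < 2; ++c1) {
              const double w1 = c1 ? f1 : 1 - f1;
              const double w2 = c2 ? f2 : 1 - f2;
              const double w3 = c3 ? f3 : 1 - f3;
              const R_xlen_t q = (R_xlen_t)(c3 ? k1 : k0) * plane +
                                 (R_xlen_t)(c2 ? j1 : j0) * d1 +
                                 (c1 ? i1 : i0);
              gimg[q] += g * w1 * w2 * w3;
              const double val = p[q];
              g1 += (c1 ? 1.0 : -1.0) * w2 * w3 * val;
              g2 += (c2 ? 1.0 : -1.0) * w1 * w3 * val;
              g3 += (c3 ? 1.0 : -1.0) * w1 * w2 * val;
            }
        if (in1) gdf[v] = g * g1;
        if (in2) gdf[v + n] = g * g2;
        if (in3) gdf[v + 2 * n] = g * g3;
      }
  gimg.attr("dim") = IntegerVector::create(d1, d2, d3);
  gdf.attr("dim") = IntegerVector::create(d1, d2, d3, 3);
  return List::create(_["gimg"] = gimg, _["gdf"] = gdf);
}

// Connected-component labelling of a binary 3D mask with 6- or
// 26-connectivity; labels start at 1 in scan order of first contact.
// [[Rcpp::export(name = ".label_components3d")]]
IntegerVector label_components3d(IntegerVector mask, IntegerVector dims,
                                 int connectivity) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  std::vector<std::array<int, 3>> offs;
  for (int oc = -1; oc <= 1; ++oc)
    for (int ob = -1; ob <= 1; ++ob)
      for (int oa = -1; oa <= 1; ++oa) {
        if (oa == 0 && ob == 0 && oc == 0) continue;
        if (connectivity == 6 && std::abs(oa) + std::abs(ob) + std::abs(oc) != 1)
          continue;
        offs.push_back({oa, ob, oc});
      }
  int next = 0;
  const R_xlen_t plane = (R_xlen_t)d1 * d2;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t v = stack.back();
      stack.pop_back();
      const int kk = (int)(v / plane);
      const int jj = (int)((v - (R_xlen_t)kk * plane) / d1);
      const int ii = (int)(v % d1);
      for (const auto& o : offs) {
        const int a = ii + o[0], b = jj + o[1], c = kk + o[2];
        if (a < 0 || a >= d1 || b < 0 || b >= d2 || c < 0 || c >= d3) continue;
        const R_xlen_t q = (R_xlen_t)c * plane + (R_xlen_t)b * d1 + a;
        if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Separable Gaussian smoothing with replicate borders; kernel truncated at
// three standard deviations.
// [[Rcpp::export(name = ".gaussian_smooth3d")]]
NumericVector gaussian_smooth3d(NumericVector x, IntegerVector dims,
                                double sigma) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  const R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  std::vector<double> cur(x.begin(), x.begin() + n), nxt(n);
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i)
    s += kern[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
  for (auto& kv : kern) kv /= s;
  const R_xlen_t stride[3] = {1, (R_xlen_t)d[0], (R_xlen_t)d[0] * d[1]};
  for (int ax = 0; ax < 3; ++ax) {
    for (int kk = 0; kk < d[2]; ++kk)
      for (int jj = 0; jj < d[1]; ++jj)
        for (int ii = 0; ii < d[0]; ++ii) {
          const int pos[3] = {ii, jj, kk};
          const R_xlen_t base = (R_xlen_t)kk * stride[2] + jj * stride[1] + ii;
          double acc = 0.0;
          for (int t = -r; t <= r; ++t) {
            const int pt = clampi(pos[ax] + t, 0, d[ax] - 1);
            acc += kern[t + r] * cur[base + ((R_xlen_t)pt - pos[ax]) * stride[ax]];
          }
          nxt[base] = acc;
        }
    cur.swap(nxt);
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = dims;
  return out;
}
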