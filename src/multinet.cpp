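// Native forward/backward pass for the two-stream visual-vestibular network.
//
// The visual stream is a valid 3D convolution (x-y-t, collapsing all frames)
// implemented as im2col + BLAS GEMM, rectified, then 2x2 max-pooled with
// stride 2 and ceil-mode edge handling.  Everything downstream is dense.
// Examples are processed in fixed-size chunks so the im2col buffer stays
// bounded at full scale; the batch loss is a per-example mean, so chunked
// accumulation is exact.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct NetDims {
  int H, F, ks, K;      // input side, frames, kernel side, kernel count
  int C;                // conv output side (valid): H - ks + 1
  int P;                // pooled side: ceil(C / 2)
  int n_mt, n_pivc, n_mstd, n_vest, n_out, n_axes;
};

NetDims read_dims(const List& params, const IntegerVector& visdim) {
  NetDims d;
  arma::mat conv_w = as<arma::mat>(params["conv_w"]);
  arma::mat mt_w   = as<arma::mat>(params["mt_w"]);
  arma::mat pivc_w = as<arma::mat>(params["pivc_w"]);
  arma::mat mstd_w = as<arma::mat>(params["mstd_w"]);
  arma::mat out_w  = as<arma::mat>(params["out_w"]);
  d.H = visdim[0];
  d.F = visdim[2];
  d.K = conv_w.n_cols;
  int ks2f = conv_w.n_rows;
  d.ks = (int) std::lround(std::sqrt((double) ks2f / d.F));
  if (d.ks * d.ks * d.F != ks2f)
    stop("conv kernel rows (%d) not a square times %d frames", ks2f, d.F);
  if (visdim[1] != d.H) stop("visual input must be square");
  d.C = d.H - d.ks + 1;
  if (d.C < 1) stop("input side %d too small for kernel side %d", d.H, d.ks);
  d.P = (d.C + 1) / 2;
  d.n_mt = mt_w.n_rows;
  if ((int) mt_w.n_cols != d.K * d.P * d.P)
    stop("mt_w has %d columns; expected %d (= %d kernels x %d^2 pooled)",
         (int) mt_w.n_cols, d.K * d.P * d.P, d.K, d.P);
  d.n_pivc = pivc_w.n_rows;
  d.n_vest = pivc_w.n_cols;
  d.n_mstd = mstd_w.n_rows;
  if ((int) mstd_w.n_cols != d.n_mt + d.n_pivc)
    stop("mstd_w has %d columns; expected %d", (int) mstd_w.n_cols,
         d.n_mt + d.n_pivc);
  d.n_out = out_w.n_rows;
  if (d.n_out % 3 != 0) stop("output layer must have 3 units per axis");
  d.n_axes = d.n_out / 3;
  if ((int) out_w.n_cols != d.n_mstd) stop("out_w / mstd_w size mismatch");
  return d;
}

// Fill the im2col buffer for examples [e0, e0+m): one column per patch,
// kernel taps ordered x (fastest), y, t to match conv_w's kernel layout.
void im2col(const double* vis, const NetDims& d, int e0, int m, arma::mat& X) {
  const int H = d.H, ks = d.ks, C = d.C, F = d.F;
  const size_t ex_stride = (size_t) H * H * F;
  X.set_size((size_t) ks * ks * F, (size_t) C * C * m);
  double* xp = X.memptr();
  for (int e = 0; e < m; ++e) {
    const double* v = vis + (e0 + e) * ex_stride;
    for (int py = 0; py < C; ++py) {
      for (int px = 0; px < C; ++px) {
        for (int t = 0; t < F; ++t) {
          const double* src = v + (size_t) t * H * H + (size_t) py * H + px;
          for (int ky = 0; ky < ks; ++ky) {
            std::memcpy(xp, src + (size_t) ky * H, ks * sizeof(double));
            xp += ks;
          }
        }
      }
    }
  }
}

// Max-pool 2x2 stride 2 (ceil mode) of the rectified conv maps.
// v1: (K x C*C*m) column blocks per patch? -- here v1 is K x (C*C) per
// example laid out as columns = patches of one example after another.
// pooled: (K*P*P) x m ordered map-major (kernel k's P x P map, column-major).
void maxpool(const arma::mat& v1, const NetDims& d, int m,
             arma::mat& pooled, arma::umat& argmax) {
  const int C = d.C, P = d.P, K = d.K;
  pooled.set_size((size_t) K * P * P, m);
  argmax.set_size((size_t) K * P * P, m);
  for (int e = 0; e < m; ++e) {
    const size_t pbase = (size_t) e * C * C;
    for (int k = 0; k < K; ++k) {
      for (int jy = 0; jy < P; ++jy) {
        for (int jx = 0; jx < P; ++jx) {
          double best = -arma::datum::inf;
          size_t best_col = 0;
          for (int dy = 0; dy < 2; ++dy) {
            int y = 2 * jy + dy; if (y >= C) continue;
            for (int dx = 0; dx < 2; ++dx) {
              int x = 2 * jx + dx; if (x >= C) continue;
              size_t col = pbase + (size_t) y * C + x;
              double val = v1(k, col);
              if (val > best) { best = val; best_col = col; }
            }
          }
          size_t row = (size_t) k * P * P + (size_t) jy * P + jx;
          pooled(row, e) = best;
          argmax(row, e) = best_col;
        }
      }
    }
  }
}

inline double sigmoid(double r) { return 1.0 / (1.0 + std::exp(-r)); }

// numerically stable binary cross-entropy of a logit r against label y
inline double bce_logit(double r, double y) {
  return std::max(r, 0.0) - r * y + std::log1p(std::exp(-std::fabs(r)));
}

struct ChunkState {                 // per-chunk forward intermediates
  arma::mat Xcol, v1, pooled, mt_pre, pivc_pre, mstd_pre;
  arma::mat mt, pivc, mstd, out_pre;
  arma::umat argmax;
};

void forward_chunk(const double* vis, const arma::mat& vest, const List& params,
                   const NetDims& d, int e0, int m,
                   const arma::uvec& silence, ChunkState& st) {
  arma::mat conv_w = as<arma::mat>(params["conv_w"]);
  arma::vec conv_b = as<arma::vec>(params["conv_b"]);
  arma::mat mt_w   = as<arma::mat>(params["mt_w"]);
  arma::vec mt_b   = as<arma::vec>(params["mt_b"]);
  arma::mat pivc_w = as<arma::mat>(params["pivc_w"]);
  arma::vec pivc_b = as<arma::vec>(params["pivc_b"]);
  arma::mat mstd_w = as<arma::mat>(params["mstd_w"]);
  arma::vec mstd_c = as<arma::vec>(params["mstd_c"]);
  arma::mat out_w  = as<arma::mat>(params["out_w"]);
  arma::vec out_b  = as<arma::vec>(params["out_b"]);

  im2col(vis, d, e0, m, st.Xcol);
  st.v1 = conv_w.t() * st.Xcol;          // K x (C*C*m)
  st.v1.each_col() += conv_b;
  st.v1.transform([](double x) { return x > 0.0 ? x : 0.0; });
  maxpool(st.v1, d, m, st.pooled, st.argmax);

  st.mt_pre = mt_w * st.pooled;
  st.mt_pre.each_col() += mt_b;
  st.mt = arma::clamp(st.mt_pre, 0.0, arma::datum::inf);

  st.pivc_pre = pivc_w * vest.cols(e0, e0 + m - 1);
  st.pivc_pre.each_col() += pivc_b;
  st.pivc = arma::clamp(st.pivc_pre, 0.0, arma::datum::inf);

  arma::mat h = arma::join_cols(st.mt, st.pivc);
  h.each_col() += mstd_c;                // learnable input-offset terms
  st.mstd_pre = mstd_w * h;
  st.mstd = arma::clamp(st.mstd_pre, 0.0, arma::datum::inf);
  for (arma::uword i = 0; i < silence.n_elem; ++i)
    st.mstd.row(silence[i]).zeros();     // artificial lesion

  st.out_pre = out_w * st.mstd;
  st.out_pre.each_col() += out_b;
}

} // namespace

// [[Rcpp::export]]
List cpp_forward(List params, NumericVector vis, NumericMatrix vest,
                 IntegerVector silence, bool keep_maps) {
  IntegerVector visdim = vis.attr("dim");
  if (visdim.size() != 4) stop("visual input must be a H x H x frames x n array");
  NetDims d = read_dims(params, visdim);
  int n = visdim[3];
  arma::mat vestm(vest.begin(), vest.nrow(), vest.ncol(), false);
  if ((int) vestm.n_rows != d.n_vest || (int) vestm.n_cols != n)
    stop("vestibular input must be %d x %d", d.n_vest, n);
  arma::uvec sil(silence.size());
  for (int i = 0; i < silence.size(); ++i) {
    if (silence[i] < 1 || silence[i] > d.n_mstd) stop("invalid MSTd unit index");
    sil[i] = silence[i] - 1;
  }

  int chunk = std::max(1, (int) (4000000.0 / ((double) d.ks * d.ks * d.F * d.C * d.C)));
  arma::mat fusion(d.n_axes, n), scission(d.n_axes, n), causal(d.n_axes, n);
  arma::mat mstd(d.n_mstd, n), mt(d.n_mt, n), pivc(d.n_pivc, n);
  arma::mat v1_all, pooled_all;
  if (keep_maps) {
    v1_all.set_size(d.K, (size_t) d.C * d.C * n);
    pooled_all.set_size((size_t) d.K * d.P * d.P, n);
  }

  ChunkState st;
  for (int e0 = 0; e0 < n; e0 += chunk) {
    int m = std::min(chunk, n - e0);
    forward_chunk(REAL(vis), vestm, params, d, e0, m, sil, st);
    fusion.cols(e0, e0 + m - 1)   = st.out_pre.rows(0, d.n_axes - 1);
    scission.cols(e0, e0 + m - 1) = st.out_pre.rows(d.n_axes, 2 * d.n_axes - 1);
    arma::mat cz = st.out_pre.rows(2 * d.n_axes, 3 * d.n_axes - 1);
    cz.transform([](double r) { return sigmoid(r); });
    causal.cols(e0, e0 + m - 1) = cz;
    mstd.cols(e0, e0 + m - 1) = st.mstd;
    mt.cols(e0, e0 + m - 1) = st.mt;
    pivc.cols(e0, e0 + m - 1) = st.pivc;
    if (keep_maps) {
      v1_all.cols((size_t) e0 * d.C * d.C, (size_t) (e0 + m) * d.C * d.C - 1) = st.v1;
      pooled_all.cols(e0, e0 + m - 1) = st.pooled;
    }
  }

  List out = List::create(
    _["fusion"] = fusion, _["scission"] = scission, _["causal"] = causal,
    _["mstd"] = mstd, _["mt"] = mt, _["pivc"] = pivc);
  if (keep_maps) {
    out["v1"] = v1_all;
    out["pooled"] = pooled_all;
    out["v1_side"] = d.C;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_loss_grad(List params, NumericVector vis, NumericMatrix vest,
                   NumericMatrix lab_fusion, NumericMatrix lab_scission,
                   NumericMatrix lab_causal, double w_scission, double w_bce) {
  IntegerVector visdim = vis.attr("dim");
  if (visdim.size() != 4) stop("visual input must be a H x H x frames x n array");
  NetDims d = read_dims(params, visdim);
  int n = visdim[3];
  arma::mat vestm(vest.begin(), vest.nrow(), vest.ncol(), false);
  arma::mat yf(lab_fusion.begin(), lab_fusion.nrow(), n, false);
  arma::mat ys(lab_scission.begin(), lab_scission.nrow(), n, false);
  arma::mat yc(lab_causal.begin(), lab_causal.nrow(), n, false);

  arma::mat conv_w = as<arma::mat>(params["conv_w"]);
  arma::mat mt_w   = as<arma::mat>(params["mt_w"]);
  arma::mat pivc_w = as<arma::mat>(params["pivc_w"]);
  arma::mat mstd_w = as<arma::mat>(params["mstd_w"]);
  arma::vec mstd_c = as<arma::vec>(params["mstd_c"]);
  arma::mat out_w  = as<arma::mat>(params["out_w"]);

  arma::mat g_conv_w(arma::size(conv_w), arma::fill::zeros);
  arma::vec g_conv_b(d.K, arma::fill::zeros);
  arma::mat g_mt_w(arma::size(mt_w), arma::fill::zeros);
  arma::vec g_mt_b(d.n_mt, arma::fill::zeros);
  arma::mat g_pivc_w(arma::size(pivc_w), arma::fill::zeros);
  arma::vec g_pivc_b(d.n_pivc, arma::fill::zeros);
  arma::mat g_mstd_w(arma::size(mstd_w), arma::fill::zeros);
  arma::vec g_mstd_c(d.n_mt + d.n_pivc, arma::fill::zeros);
  arma::mat g_out_w(arma::size(out_w), arma::fill::zeros);
  arma::vec g_out_b(d.n_out, arma::fill::zeros);

  double loss_f = 0.0, loss_s = 0.0, loss_c = 0.0;
  const double inv_an = 1.0 / ((double) d.n_axes * n);
  arma::uvec sil;   // no lesioning during training
  int chunk = std::max(1, (int) (4000000.0 / ((double) d.ks * d.ks * d.F * d.C * d.C)));
  ChunkState st;

  for (int e0 = 0; e0 < n; e0 += chunk) {
    int m = std::min(chunk, n - e0);
    forward_chunk(REAL(vis), vestm, params, d, e0, m, sil, st);

    arma::mat f = st.out_pre.rows(0, d.n_axes - 1);
    arma::mat s = st.out_pre.rows(d.n_axes, 2 * d.n_axes - 1);
    arma::mat r = st.out_pre.rows(2 * d.n_axes, 3 * d.n_axes - 1);
    arma::mat ef = f - yf.cols(e0, e0 + m - 1);
    arma::mat es = s - ys.cols(e0, e0 + m - 1);
    loss_f += arma::accu(arma::square(ef));
    loss_s += arma::accu(arma::square(es));
    arma::mat p = r;
    p.transform([](double x) { return sigmoid(x); });
    for (int e = 0; e < m; ++e)
      for (int a = 0; a < d.n_axes; ++a)
        loss_c += bce_logit(r(a, e), yc(a, e0 + e));

    // derivative of the composite loss w.r.t. output pre-activations
    arma::mat d_out(d.n_out, m);
    d_out.rows(0, d.n_axes - 1) = 2.0 * inv_an * ef;
    d_out.rows(d.n_axes, 2 * d.n_axes - 1) = 2.0 * w_scission * inv_an * es;
    d_out.rows(2 * d.n_axes, 3 * d.n_axes - 1) =
      w_bce * inv_an * (p - yc.cols(e0, e0 + m - 1));

    g_out_w += d_out * st.mstd.t();
    g_out_b += arma::sum(d_out, 1);

    arma::mat d_mstd = out_w.t() * d_out;
    d_mstd.elem(arma::find(st.mstd_pre <= 0)).zeros();
    arma::mat h = arma::join_cols(st.mt, st.pivc);
    h.each_col() += mstd_c;
    g_mstd_w += d_mstd * h.t();
    g_mstd_c += mstd_w.t() * arma::sum(d_mstd, 1);

    arma::mat d_h = mstd_w.t() * d_mstd;
    arma::mat d_mt = d_h.rows(0, d.n_mt - 1);
    d_mt.elem(arma::find(st.mt_pre <= 0)).zeros();
    g_mt_w += d_mt * st.pooled.t();
    g_mt_b += arma::sum(d_mt, 1);

    arma::mat d_pivc = d_h.rows(d.n_mt, d.n_mt + d.n_pivc - 1);
    d_pivc.elem(arma::find(st.pivc_pre <= 0)).zeros();
    g_pivc_w += d_pivc * vestm.cols(e0, e0 + m - 1).t();
    g_pivc_b += arma::sum(d_pivc, 1);

    // route pooled-layer gradient back through the argmax, gate by relu
    arma::mat d_pooled = mt_w.t() * d_mt;        // (K*P*P) x m
    arma::mat d_v1(d.K, (size_t) d.C * d.C * m, arma::fill::zeros);
    for (int e = 0; e < m; ++e) {
      for (int k = 0; k < d.K; ++k) {
        for (int j = 0; j < d.P * d.P; ++j) {
          size_t row = (size_t) k * d.P * d.P + j;
          d_v1(k, st.argmax(row, e)) += d_pooled(row, e);
        }
      }
    }
    d_v1.elem(arma::find(st.v1 <= 0)).zeros();   // v1 > 0 iff pre > 0
    g_conv_w += st.Xcol * d_v1.t();
    g_conv_b += arma::sum(d_v1, 1);
  }

  loss_f *= inv_an; loss_s *= inv_an; loss_c *= inv_an;
  double loss = loss_f + w_scission * loss_s + w_bce * loss_c;

  return List::create(
    _["loss"] = loss,
    _["loss_fusion"] = loss_f, _["loss_scission"] = loss_s,
    _["loss_causal"] = loss_c,
    _["grads"] = List::create(
      _["conv_w"] = g_conv_w, _["conv_b"] = g_conv_b,
      _["mt_w"] = g_mt_w, _["mt_b"] = g_mt_b,
      _["pivc_w"] = g_pivc_w, _["pivc_b"] = g_pivc_b,
      _["mstd_w"] = g_mstd_w, _["mstd_c"] = g_mstd_c,
      _["out_w"] = g_out_w, _["out_b"] = g_out_b));
}

// Bilinear affine resampling of a scene for each of F frames.
// Output pixel (ix, iy), 0-based, maps to scene position
//   src = off[, t] + M[,, t] %*% (ix - c, iy - c),  c = (N - 1) / 2,
// in 0-based scene coordinates (first index x, second y).  Samples are
// clamped to the scene border; callers size the scene so clamping is never
// reached for supported motions.
// [[Rcpp::export]]
NumericVector cpp_warp_affine(NumericMatrix scene, int out_side,
                              NumericVector M, NumericMatrix off) {
  IntegerVector mdim = M.attr("dim");
  if (mdim.size() != 3 || mdim[0] != 2 || mdim[1] != 2)
    stop("M must be a 2 x 2 x frames array");
  int F = mdim[2], N = out_side;
  if (off.nrow() != 2 || off.ncol() != F) stop("off must be 2 x frames");
  int SX = scene.nrow(), SY = scene.ncol();
  NumericVector out((size_t) N * N * F);
  out.attr("dim") = IntegerVector::create(N, N, F);
  double c = (N - 1) / 2.0;
  const double* sc = scene.begin();
  for (int t = 0; t < F; ++t) {
    double m11 = M[4 * t], m21 = M[4 * t + 1], m12 = M[4 * t + 2], m22 = M[4 * t + 3];
    double ox = off(0, t), oy = off(1, t);
    double* op = out.begin() + (size_t) t * N * N;
    for (int iy = 0; iy < N; ++iy) {
      double uy = iy - c;
      for (int ix = 0; ix < N; ++ix) {
        double ux = ix - c;
        double sx = ox + m11 * ux + m12 * uy;
        double sy = oy + m21 * ux + m22 * uy;
        if (sx < 0) sx = 0;
        if (sx > SX - 1) sx = SX - 1;
        if (sy < 0) sy = 0;
        if (sy > SY - 1) sy = SY - 1;
        int x0 = (int) std::floor(sx), y0 = (int) std::floor(sy);
        if (x0 > SX - 2) x0 = SX - 2;
        if (y0 > SY - 2) y0 = SY - 2;
        double fx = sx - x0, fy = sy - y0;
        const double* s00 = sc + (size_t) y0 * SX + x0;
        double v = (1 - fx) * (1 - fy) * s00[0] + fx * (1 - fy) * s00[1]
                 + (1 - fx) * fy * s00[SX] + fx * fy * s00[SX + 1];
        op[(size_t) iy * N + ix] = v;
      }
    }
  }
  return out;
}
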