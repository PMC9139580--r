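// Low-level tensor primitives for the spatiotemporal network.
//
// Feature maps are stored channel-first: a batch of N maps with C channels of
// size H x W is a flat column-major array indexed (c, h, w, n), c fastest.
// Convolutions are stride-1 with symmetric zero padding (k odd); GEMMs run in
// single precision through Armadillo, gradients are returned in double.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::fvec as_float(const NumericVector& x) {
  arma::fvec out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = static_cast<float>(x[i]);
  return out;
}

static NumericVector as_double(const arma::fvec& x) {
  NumericVector out(x.n_elem);
  for (arma::uword i = 0; i < x.n_elem; ++i) out[i] = static_cast<double>(x[i]);
  return out;
}

// im2col for (C,H,W,N) input, kernel k x k, pad p, stride 1.
// Output: (C*k*k) x (H*W*N); row index r = c + C*(u + k*v) for kernel offset
// (u, v); column index = h + H*w + H*W*n.
static arma::fmat im2col(const arma::fvec& x, int C, int H, int W, int N,
                         int k, int p) {
  const int Ho = H + 2 * p - k + 1;
  const int Wo = W + 2 * p - k + 1;
  arma::fmat cols(C * k * k, (arma::uword)Ho * Wo * N, arma::fill::zeros);
  const float* xp = x.memptr();
  for (int n = 0; n < N; ++n) {
    const float* xn = xp + (size_t)n * C * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        float* col = cols.colptr((arma::uword)ho + (arma::uword)Ho * wo +
                                 (arma::uword)Ho * Wo * n);
        for (int v = 0; v < k; ++v) {
          int wi = wo + v - p;
          if (wi < 0 || wi >= W) continue;
          for (int u = 0; u < k; ++u) {
            int hi = ho + u - p;
            if (hi < 0 || hi >= H) continue;
            const float* src = xn + (size_t)C * (hi + (size_t)H * wi);
            float* dst = col + (size_t)C * (u + (size_t)k * v);
            std::memcpy(dst, src, sizeof(float) * C);
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col: scatter-add columns back into an image tensor.
static arma::fvec col2im(const arma::fmat& cols, int C, int H, int W, int N,
                         int k, int p) {
  const int Ho = H + 2 * p - k + 1;
  const int Wo = W + 2 * p - k + 1;
  arma::fvec x((arma::uword)C * H * W * N, arma::fill::zeros);
  float* xp = x.memptr();
  for (int n = 0; n < N; ++n) {
    float* xn = xp + (size_t)n * C * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const float* col = cols.colptr((arma::uword)ho + (arma::uword)Ho * wo +
                                       (arma::uword)Ho * Wo * n);
        for (int v = 0; v < k; ++v) {
          int wi = wo + v - p;
          if (wi < 0 || wi >= W) continue;
          for (int u = 0; u < k; ++u) {
            int hi = ho + u - p;
            if (hi < 0 || hi >= H) continue;
            float* dst = xn + (size_t)C * (hi + (size_t)H * wi);
            const float* src = col + (size_t)C * (u + (size_t)k * v);
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  return x;
}

// Forward 2D convolution. w is (F x C*k*k), b length F. Returns (F,Ho,Wo,N).
// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
NumericVector cpp_conv2d_fwd(NumericVector x, IntegerVector dims,
                             NumericMatrix w, NumericVector b, int k, int p) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int F = w.nrow();
  arma::fvec xf = as_float(x);
  arma::fmat cols = im2col(xf, C, H, W, N, k, p);
  arma::fmat wf(F, w.ncol());
  for (int j = 0; j < w.ncol(); ++j)
    for (int i = 0; i < F; ++i) wf(i, j) = (float)w(i, j);
  arma::fmat out = wf * cols;
  arma::fvec bf(F);
  for (int i = 0; i < F; ++i) bf[i] = (float)b[i];
  out.each_col() += bf;
  const int Ho = H + 2 * p - k + 1, Wo = W + 2 * p - k + 1;
  NumericVector res = as_double(arma::vectorise(out));
  res.attr("dim") = IntegerVector::create(F, Ho, Wo, N);
  return res;
}

// Backward 2D convolution: returns dw, db and (optionally) dx.
// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, IntegerVector dims, NumericMatrix w,
                    NumericVector dout, int k, int p, bool need_dx) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int F = w.nrow();
  const int Ho = H + 2 * p - k + 1, Wo = W + 2 * p - k + 1;
  arma::fvec xf = as_float(x);
  arma::fmat cols = im2col(xf, C, H, W, N, k, p);
  arma::fvec df = as_float(dout);
  arma::fmat dmat(df.memptr(), F, (arma::uword)Ho * Wo * N, false, true);
  arma::fmat dw = dmat * cols.t();
  arma::fvec db = arma::sum(dmat, 1);
  NumericMatrix dwR(F, w.ncol());
  for (int j = 0; j < w.ncol(); ++j)
    for (int i = 0; i < F; ++i) dwR(i, j) = (double)dw(i, j);
  List out = List::create(Named("dw") = dwR, Named("db") = as_double(db));
  if (need_dx) {
    arma::fmat wf(F, w.ncol());
    for (int j = 0; j < w.ncol(); ++j)
      for (int i = 0; i < F; ++i) wf(i, j) = (float)w(i, j);
    arma::fmat dcols = wf.t() * dmat;
    NumericVector dx = as_double(col2im(dcols, C, H, W, N, k, p));
    dx.attr("dim") = IntegerVector::create(C, H, W, N);
    out["dx"] = dx;
  }
  return out;
}

// 2x2 max pooling, stride 2. Returns pooled tensor and 1-based argmax indices
// into the input vector (for the backward pass).
// [[Rcpp::export(name = ".cpp_maxpool2_fwd")]]
List cpp_maxpool2_fwd(NumericVector x, IntegerVector dims) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)C * Ho * Wo * N);
  IntegerVector idx((R_xlen_t)C * Ho * Wo * N);
  const double* xp = REAL(x);
  double* op = REAL(out);
  int* ip = INTEGER(idx);
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int c = 0; c < C; ++c) {
          size_t best = 0;
          double bv = -HUGE_VAL;
          for (int v = 0; v < 2; ++v)
            for (int u = 0; u < 2; ++u) {
              size_t id = (size_t)c +
                          (size_t)C * ((2 * ho + u) +
                                       (size_t)H * ((2 * wo + v) + (size_t)W * n));
              if (xp[id] > bv) { bv = xp[id]; best = id; }
            }
          size_t od = (size_t)c +
                      (size_t)C * (ho + (size_t)Ho * (wo + (size_t)Wo * n));
          op[od] = bv;
          ip[od] = (int)(best + 1);
        }
  out.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  return List::create(Named("out") = out, Named("idx") = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool2_bwd")]]
NumericVector cpp_maxpool2_bwd(NumericVector dout, IntegerVector idx,
                               IntegerVector in_dims) {
  R_xlen_t n_in = (R_xlen_t)in_dims[0] * in_dims[1] * in_dims[2] * in_dims[3];
  NumericVector dx(n_in);
  double* dp = REAL(dx);
  const double* dop = REAL(dout);
  const int* ip = INTEGER(idx);
  for (R_xlen_t i = 0; i < dout.size(); ++i) dp[ip[i] - 1] += dop[i];
  dx.attr("dim") = in_dims;
  return dx;
}

// f x f average pooling, stride f (used as a fixed downsampling stem).
// [[Rcpp::export(name = ".cpp_avgpool_fwd")]]
NumericVector cpp_avgpool_fwd(NumericVector x, IntegerVector dims, int f) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int Ho = H / f, Wo = W / f;
  NumericVector out((R_xlen_t)C * Ho * Wo * N);
  const double* xp = REAL(x);
  double* op = REAL(out);
  const double inv = 1.0 / (f * f);
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int c = 0; c < C; ++c) {
          double s = 0;
          for (int v = 0; v < f; ++v)
            for (int u = 0; u < f; ++u)
              s += xp[(size_t)c +
                      (size_t)C * ((f * ho + u) +
                                   (size_t)H * ((f * wo + v) + (size_t)W * n))];
          op[(size_t)c + (size_t)C * (ho + (size_t)Ho * (wo + (size_t)Wo * n))] =
              s * inv;
        }
  out.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  return out;
}

// Global average pooling over the spatial axes: (C,H,W,N) -> (C,N).
// [[Rcpp::export(name = ".cpp_gap_fwd")]]
NumericMatrix cpp_gap_fwd(NumericVector x, IntegerVector dims) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  NumericMatrix out(C, N);
  const double* xp = REAL(x);
  const double inv = 1.0 / ((double)H * W);
  for (int n = 0; n < N; ++n) {
    double* op = &out(0, n);
    const double* xn = xp + (size_t)n * C * H * W;
    for (size_t hw = 0; hw < (size_t)H * W; ++hw)
      for (int c = 0; c < C; ++c) op[c] += xn[(size_t)C * hw + c];
    for (int c = 0; c < C; ++c) op[c] *= inv;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_gap_bwd")]]
NumericVector cpp_gap_bwd(NumericMatrix dout, IntegerVector dims) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  NumericVector dx((R_xlen_t)C * H * W * N);
  double* dp = REAL(dx);
  const double inv = 1.0 / ((double)H * W);
  for (int n = 0; n < N; ++n) {
    double* dn = dp + (size_t)n * C * H * W;
    for (size_t hw = 0; hw < (size_t)H * W; ++hw)
      for (int c = 0; c < C; ++c) dn[(size_t)C * hw + c] = dout(c, n) * inv;
  }
  dx.attr("dim") = dims;
  return dx;
}

// ---------------------------------------------------------------------------
// Fused spatial-extractor pass. All per-frame convolution blocks run in
// single precision with activations and backward caches kept on the C++ heap
// (an external pointer), avoiding double<->float round trips per layer.
// `blocks` gives the number of convolutions per max-pooled block.

struct BackboneCache {
  std::vector<arma::fvec> inputs;          // conv layer inputs
  std::vector<std::vector<int>> in_dims;   // dims of each conv input
  std::vector<std::vector<unsigned char>> masks;  // ReLU masks per conv
  std::vector<std::vector<size_t>> pool_idx;      // argmax per block pool
  std::vector<std::vector<int>> pool_in_dims;
  std::vector<int> gap_dims;
  arma::fvec scratch;                      // running backward gradient
};

static arma::fmat weights_to_fmat(const NumericMatrix& w) {
  arma::fmat wf(w.nrow(), w.ncol());
  for (int j = 0; j < w.ncol(); ++j)
    for (int i = 0; i < w.nrow(); ++i) wf(i, j) = (float)w(i, j);
  return wf;
}

// in-place 2x2 max pool on float tensor; records argmax into input
static arma::fvec fmaxpool2(const arma::fvec& x, int C, int H, int W, int N,
                            std::vector<size_t>& idx) {
  const int Ho = H / 2, Wo = W / 2;
  arma::fvec out((arma::uword)C * Ho * Wo * N);
  idx.resize((size_t)C * Ho * Wo * N);
  const float* xp = x.memptr();
  float* op = out.memptr();
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int c = 0; c < C; ++c, ++o) {
          size_t best = 0; float bv = -HUGE_VALF;
          for (int v = 0; v < 2; ++v)
            for (int u = 0; u < 2; ++u) {
              size_t id = (size_t)c + (size_t)C *
                          ((2 * ho + u) + (size_t)H * ((2 * wo + v) +
                                                       (size_t)W * n));
              if (xp[id] > bv) { bv = xp[id]; best = id; }
            }
          op[o] = bv; idx[o] = best;
        }
  return out;
}

// [[Rcpp::export(name = ".cpp_backbone_fwd")]]
List cpp_backbone_fwd(NumericVector x, IntegerVector dims, List weights,
                      IntegerVector blocks, int stem_pool, bool keep_cache) {
  int C = dims[0], H = dims[1], W = dims[2];
  const int N = dims[3];
  arma::fvec a(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) a[i] = (float)x[i];
  if (stem_pool > 1) {
    const int Ho = H / stem_pool, Wo = W / stem_pool;
    arma::fvec st((arma::uword)C * Ho * Wo * N, arma::fill::zeros);
    const float inv = 1.0f / (stem_pool * stem_pool);
    const float* xp = a.memptr(); float* op = st.memptr();
    for (int n = 0; n < N; ++n)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          for (int c = 0; c < C; ++c) {
            float s = 0;
            for (int v = 0; v < stem_pool; ++v)
              for (int u = 0; u < stem_pool; ++u)
                s += xp[(size_t)c + (size_t)C *
                        ((stem_pool * ho + u) +
                         (size_t)H * ((stem_pool * wo + v) + (size_t)W * n))];
            op[(size_t)c + (size_t)C *
               (ho + (size_t)Ho * (wo + (size_t)Wo * n))] = s * inv;
          }
    a = std::move(st); H = Ho; W = Wo;
  }
  BackboneCache* cache = keep_cache ? new BackboneCache() : nullptr;
  int li = 0;
  const int k = 3, p = 1;
  for (int bi = 0; bi < blocks.size(); ++bi) {
    for (int ci = 0; ci < blocks[bi]; ++ci, ++li) {
      List lw = weights[li];
      arma::fmat wf = weights_to_fmat(lw["w"]);
      NumericVector bR = lw["b"];
      const int F = wf.n_rows;
      if (keep_cache) {
        cache->inputs.push_back(a);
        cache->in_dims.push_back({C, H, W, N});
      }
      arma::fmat cols = im2col(a, C, H, W, N, k, p);
      arma::fmat z = wf * cols;
      arma::fvec bf(F);
      for (int i = 0; i < F; ++i) bf[i] = (float)bR[i];
      z.each_col() += bf;
      // ReLU in place, recording the mask
      std::vector<unsigned char> mask;
      if (keep_cache) mask.resize(z.n_elem);
      float* zp = z.memptr();
      for (size_t i = 0; i < z.n_elem; ++i) {
        bool pos = zp[i] > 0;
        if (keep_cache) mask[i] = pos;
        if (!pos) zp[i] = 0;
      }
      if (keep_cache) cache->masks.push_back(std::move(mask));
      a = arma::vectorise(z);
      C = F;
    }
    std::vector<size_t> idx;
    arma::fvec pooled = fmaxpool2(a, C, H, W, N, idx);
    if (keep_cache) {
      cache->pool_idx.push_back(std::move(idx));
      cache->pool_in_dims.push_back({C, H, W, N});
    }
    a = std::move(pooled); H /= 2; W /= 2;
  }
  if (keep_cache) cache->gap_dims = {C, H, W, N};
  // global average pooling -> F x N double matrix
  NumericMatrix feat(C, N);
  const double inv = 1.0 / ((double)H * W);
  const float* ap = a.memptr();
  for (int n = 0; n < N; ++n) {
    double* fp = &feat(0, n);
    const float* an = ap + (size_t)n * C * H * W;
    for (size_t hw = 0; hw < (size_t)H * W; ++hw)
      for (int c = 0; c < C; ++c) fp[c] += an[(size_t)C * hw + c];
    for (int c = 0; c < C; ++c) fp[c] *= inv;
  }
  List out = List::create(Named("feat") = feat);
  if (keep_cache)
    out["cache"] = XPtr<BackboneCache>(cache, true);
  return out;
}

// [[Rcpp::export(name = ".cpp_backbone_bwd")]]
List cpp_backbone_bwd(SEXP cache_ptr, List weights, IntegerVector blocks,
                      NumericMatrix dfeat) {
  XPtr<BackboneCache> cache(cache_ptr);
  const int k = 3, p = 1;
  // GAP backward
  {
    const std::vector<int>& gd = cache->gap_dims;
    int C = gd[0], H = gd[1], W = gd[2], N = gd[3];
    arma::fvec da((arma::uword)C * H * W * N);
    const float inv = 1.0f / ((float)H * W);
    float* dp = da.memptr();
    for (int n = 0; n < N; ++n) {
      float* dn = dp + (size_t)n * C * H * W;
      for (size_t hw = 0; hw < (size_t)H * W; ++hw)
        for (int c = 0; c < C; ++c)
          dn[(size_t)C * hw + c] = (float)dfeat(c, n) * inv;
    }
    cache->scratch = std::move(da);
  }
  int li = (int)cache->inputs.size();
  List grads(li);
  for (int bi = blocks.size() - 1; bi >= 0; --bi) {
    // undo the block's max pool
    {
      const std::vector<int>& pd = cache->pool_in_dims[bi];
      arma::fvec dx((arma::uword)pd[0] * pd[1] * pd[2] * pd[3],
                    arma::fill::zeros);
      const std::vector<size_t>& idx = cache->pool_idx[bi];
      const float* dop = cache->scratch.memptr();
      float* dxp = dx.memptr();
      for (size_t i = 0; i < idx.size(); ++i) dxp[idx[i]] += dop[i];
      cache->scratch = std::move(dx);
    }
    for (int ci = blocks[bi] - 1; ci >= 0; --ci) {
      --li;
      List lw = weights[li];
      arma::fmat wf = weights_to_fmat(lw["w"]);
      const std::vector<int>& id = cache->in_dims[li];
      const int C = id[0], H = id[1], W = id[2], N = id[3];
      const int F = wf.n_rows;
      // ReLU backward in place on the scratch gradient
      {
        const std::vector<unsigned char>& mask = cache->masks[li];
        float* sp = cache->scratch.memptr();
        for (size_t i = 0; i < mask.size(); ++i)
          if (!mask[i]) sp[i] = 0;
      }
      arma::fmat dz(cache->scratch.memptr(), F,
                    (arma::uword)H * W * N, false, true);
      arma::fmat cols = im2col(cache->inputs[li], C, H, W, N, k, p);
      arma::fmat dw = dz * cols.t();
      arma::fvec db = arma::sum(dz, 1);
      NumericMatrix dwR(F, (int)wf.n_cols);
      for (arma::uword j = 0; j < wf.n_cols; ++j)
        for (int i = 0; i < F; ++i) dwR(i, j) = (double)dw(i, j);
      NumericVector dbR(F);
      for (int i = 0; i < F; ++i) dbR[i] = (double)db[i];
      grads[li] = List::create(Named("w") = dwR, Named("b") = dbR);
      if (li > 0) {
        arma::fmat dcols = wf.t() * dz;
        cache->scratch = col2im(dcols, C, H, W, N, k, p);
      }
    }
  }
  return grads;
}
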