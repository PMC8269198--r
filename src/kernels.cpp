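// Low-level numerical kernels: im2col convolutions with stride/dilation/groups,
// 2x2 max pooling with argmax bookkeeping (SegNet-style unpooling), nearest and
// bilinear resampling with exact adjoints, 8-connected component labeling,
// mean-shift mode seeking, and a generic coordinate-map resampler used by the
// augmentation module.
//
// Tensor layout throughout: column-major R arrays dim (H, W, C, N); element
// (h, w, c, n) lives at h + H*(w + W*(c + C*n)). Weights dim (KH, KW, Cin/g, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad, int dil) {
  return (in + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// Build the im2col matrix for one sample and one channel group.
// Rows indexed (kh, kw, c) column-major (kh fastest); columns by (ho, wo), ho fastest.
static void im2col(const double* x, int H, int W, int c0, int Cg,
                   int KH, int KW, int stride, int pad, int dil,
                   int Ho, int Wo, arma::mat& K) {
  for (int c = 0; c < Cg; ++c) {
    const double* xc = x + (size_t)(c0 + c) * H * W;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        int row = kh + KH * (kw + KW * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kw * dil;
          bool wok = (wi >= 0 && wi < W);
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + kh * dil;
            double v = 0.0;
            if (wok && hi >= 0 && hi < H) v = xc[hi + (size_t)H * wi];
            K(row, ho + (size_t)Ho * wo) = v;
          }
        }
      }
    }
  }
}

// Scatter-add the adjoint of im2col back into the input gradient.
static void col2im(const arma::mat& dK, double* dx, int H, int W, int c0, int Cg,
                   int KH, int KW, int stride, int pad, int dil, int Ho, int Wo) {
  for (int c = 0; c < Cg; ++c) {
    double* dxc = dx + (size_t)(c0 + c) * H * W;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        int row = kh + KH * (kw + KW * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kw * dil;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + kh * dil;
            if (hi < 0 || hi >= H) continue;
            dxc[hi + (size_t)H * wi] += dK(row, ho + (size_t)Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad, int dil, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int KH = wd[0], KW = wd[1], Cg = wd[2], Cout = wd[3];
  if (Cin != Cg * groups) stop("conv2d: channel/group mismatch");
  int CoutG = Cout / groups;
  int Ho = out_size(H, KH, stride, pad, dil), Wo = out_size(W, KW, stride, pad, dil);
  if (Ho < 1 || Wo < 1) stop("conv2d: output would be empty");
  NumericVector y(Ho * Wo * (size_t)Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat K(KH * KW * Cg, (size_t)Ho * Wo);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (size_t)n * H * W * Cin;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, g * Cg, Cg, KH, KW, stride, pad, dil, Ho, Wo, K);
      arma::mat Wm(const_cast<double*>(w.begin()) + (size_t)g * KH * KW * Cg * CoutG,
                   KH * KW * Cg, CoutG, false, true);
      arma::mat Y = K.t() * Wm; // (HoWo x CoutG)
      for (int co = 0; co < CoutG; ++co) {
        double bias = b[g * CoutG + co];
        double* yc = yp + (size_t)n * Ho * Wo * Cout + (size_t)(g * CoutG + co) * Ho * Wo;
        const double* src = Y.colptr(co);
        for (size_t i = 0; i < (size_t)Ho * Wo; ++i) yc[i] = src[i] + bias;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad, int dil, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int KH = wd[0], KW = wd[1], Cg = wd[2], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  int CoutG = Cout / groups;
  NumericVector dx(x.size()); dx.attr("dim") = xd;
  NumericVector dw(w.size()); dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat K(KH * KW * Cg, (size_t)Ho * Wo);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (size_t)n * H * W * Cin;
    double* dxn = dx.begin() + (size_t)n * H * W * Cin;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, g * Cg, Cg, KH, KW, stride, pad, dil, Ho, Wo, K);
      arma::mat dY((size_t)Ho * Wo, CoutG);
      for (int co = 0; co < CoutG; ++co) {
        const double* dyc = dyp + (size_t)n * Ho * Wo * Cout + (size_t)(g * CoutG + co) * Ho * Wo;
        std::copy(dyc, dyc + (size_t)Ho * Wo, dY.colptr(co));
        double s = 0.0;
        for (size_t i = 0; i < (size_t)Ho * Wo; ++i) s += dyc[i];
        db[g * CoutG + co] += s;
      }
      arma::mat dWm = K * dY; // (KHKWCg x CoutG)
      double* dwg = dw.begin() + (size_t)g * KH * KW * Cg * CoutG;
      for (size_t i = 0; i < dWm.n_elem; ++i) dwg[i] += dWm.memptr()[i];
      arma::mat Wm(const_cast<double*>(w.begin()) + (size_t)g * KH * KW * Cg * CoutG,
                   KH * KW * Cg, CoutG, false, true);
      arma::mat dK = Wm * dY.t(); // (KHKWCg x HoWo)
      col2im(dK, dxn, H, W, g * Cg, Cg, KH, KW, stride, pad, dil, Ho, Wo);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2. Returns pooled values and 1-based linear argmax
// indices into the (H, W) plane of each channel/sample slab.
// [[Rcpp::export(name = ".cpp_maxpool2_fwd")]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  for (int s = 0; s < C * N; ++s) {
    const double* xs = xp + (size_t)s * H * W;
    double* ys = y.begin() + (size_t)s * Ho * Wo;
    int* is = idx.begin() + (size_t)s * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        int h0 = 2 * ho, w0 = 2 * wo;
        int best = h0 + H * w0;
        double bv = xs[best];
        int cand[3] = { h0 + 1 + H * w0, h0 + H * (w0 + 1), h0 + 1 + H * (w0 + 1) };
        for (int k = 0; k < 3; ++k) if (xs[cand[k]] > bv) { bv = xs[cand[k]]; best = cand[k]; }
        ys[ho + (size_t)Ho * wo] = bv;
        is[ho + (size_t)Ho * wo] = best + 1;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool2_bwd")]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int s = 0; s < C * N; ++s) {
    const double* dys = dy.begin() + (size_t)s * Ho * Wo;
    const int* is = idx.begin() + (size_t)s * Ho * Wo;
    double* dxs = dx.begin() + (size_t)s * H * W;
    for (size_t i = 0; i < (size_t)Ho * Wo; ++i) dxs[is[i] - 1] += dys[i];
  }
  return dx;
}

// SegNet-style unpooling: place values at recorded argmax positions.
// [[Rcpp::export(name = ".cpp_maxunpool2_fwd")]]
NumericVector cpp_maxunpool2_fwd(NumericVector x, IntegerVector idx, int H, int W) {
  return cpp_maxpool2_bwd(x, idx, H, W); // identical scatter
}

// [[Rcpp::export(name = ".cpp_maxunpool2_bwd")]]
NumericVector cpp_maxunpool2_bwd(NumericVector dy, IntegerVector idx, int Ho, int Wo) {
  IntegerVector yd = dy.attr("dim");
  int H = yd[0], W = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((size_t)Ho * Wo * C * N);
  dx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int s = 0; s < C * N; ++s) {
    const double* dys = dy.begin() + (size_t)s * H * W;
    const int* is = idx.begin() + (size_t)s * Ho * Wo;
    double* dxs = dx.begin() + (size_t)s * Ho * Wo;
    for (size_t i = 0; i < (size_t)Ho * Wo; ++i) dxs[i] = dys[is[i] - 1];
  }
  return dx;
}

// [[Rcpp::export(name = ".cpp_upsample_nearest2_fwd")]]
NumericVector cpp_upsample_nearest2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((size_t)4 * H * W * C * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C, N);
  for (int s = 0; s < C * N; ++s) {
    const double* xs = x.begin() + (size_t)s * H * W;
    double* ys = y.begin() + (size_t)s * 4 * H * W;
    for (int w = 0; w < 2 * W; ++w)
      for (int h = 0; h < 2 * H; ++h)
        ys[h + (size_t)2 * H * w] = xs[h / 2 + (size_t)H * (w / 2)];
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_upsample_nearest2_bwd")]]
NumericVector cpp_upsample_nearest2_bwd(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  int H2 = yd[0], W2 = yd[1], C = yd[2], N = yd[3];
  int H = H2 / 2, W = W2 / 2;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int s = 0; s < C * N; ++s) {
    const double* dys = dy.begin() + (size_t)s * H2 * W2;
    double* dxs = dx.begin() + (size_t)s * H * W;
    for (int w = 0; w < W2; ++w)
      for (int h = 0; h < H2; ++h)
        dxs[h / 2 + (size_t)H * (w / 2)] += dys[h + (size_t)H2 * w];
  }
  return dx;
}

// Bilinear resize (half-pixel centers, PyTorch align_corners=FALSE convention).
static inline void bilin_coef(int i, int In, int On, int& i0, int& i1, double& a) {
  double src = ((double)i + 0.5) * In / On - 0.5;
  if (src < 0) src = 0;
  if (src > In - 1) src = In - 1;
  i0 = (int)std::floor(src);
  i1 = std::min(i0 + 1, In - 1);
  a = src - i0;
}

// [[Rcpp::export(name = ".cpp_upsample_bilinear_fwd")]]
NumericVector cpp_upsample_bilinear_fwd(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> ah(Ho), aw(Wo);
  for (int h = 0; h < Ho; ++h) bilin_coef(h, H, Ho, h0[h], h1[h], ah[h]);
  for (int w = 0; w < Wo; ++w) bilin_coef(w, W, Wo, w0[w], w1[w], aw[w]);
  for (int s = 0; s < C * N; ++s) {
    const double* xs = x.begin() + (size_t)s * H * W;
    double* ys = y.begin() + (size_t)s * Ho * Wo;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        double v00 = xs[h0[h] + (size_t)H * w0[w]], v10 = xs[h1[h] + (size_t)H * w0[w]];
        double v01 = xs[h0[h] + (size_t)H * w1[w]], v11 = xs[h1[h] + (size_t)H * w1[w]];
        double top = v00 * (1 - ah[h]) + v10 * ah[h];
        double bot = v01 * (1 - ah[h]) + v11 * ah[h];
        ys[h + (size_t)Ho * w] = top * (1 - aw[w]) + bot * aw[w];
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_upsample_bilinear_bwd")]]
NumericVector cpp_upsample_bilinear_bwd(NumericVector dy, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> ah(Ho), aw(Wo);
  for (int h = 0; h < Ho; ++h) bilin_coef(h, H, Ho, h0[h], h1[h], ah[h]);
  for (int w = 0; w < Wo; ++w) bilin_coef(w, W, Wo, w0[w], w1[w], aw[w]);
  for (int s = 0; s < C * N; ++s) {
    const double* dys = dy.begin() + (size_t)s * Ho * Wo;
    double* dxs = dx.begin() + (size_t)s * H * W;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        double g = dys[h + (size_t)Ho * w];
        dxs[h0[h] + (size_t)H * w0[w]] += g * (1 - ah[h]) * (1 - aw[w]);
        dxs[h1[h] + (size_t)H * w0[w]] += g * ah[h] * (1 - aw[w]);
        dxs[h0[h] + (size_t)H * w1[w]] += g * (1 - ah[h]) * aw[w];
        dxs[h1[h] + (size_t)H * w1[w]] += g * ah[h] * aw[w];
      }
    }
  }
  return dx;
}

// 8-connected component labeling of a logical matrix, two-pass union-find.
// Labels assigned in raster (column-major) discovery order, 1..M.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);
  auto find = [&](int a) { while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; } return a; };
  auto unite = [&](int a, int b) { a = find(a); b = find(b); if (a != b) parent[std::max(a, b)] = std::min(a, b); };
  int next = 1;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      if (!mask(h, w)) continue;
      int nb[4][2] = { {h - 1, w}, {h - 1, w - 1}, {h, w - 1}, {h + 1, w - 1} };
      int cur = 0;
      for (int k = 0; k < 4; ++k) {
        int hh = nb[k][0], ww = nb[k][1];
        if (hh < 0 || hh >= H || ww < 0) continue;
        int l = lab(hh, ww);
        if (l > 0) { if (cur == 0) cur = l; else unite(cur, l); }
      }
      if (cur == 0) { cur = next++; parent.push_back(cur); }
      lab(h, w) = cur;
    }
  }
  std::vector<int> remap(next, 0);
  int m = 0;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      if (lab(h, w) > 0) {
        int r = find(lab(h, w));
        if (remap[r] == 0) remap[r] = ++m;
        lab(h, w) = remap[r];
      }
  return lab;
}

// Flat-kernel mean shift. X: n x d points; seeds: subset of row indices (1-based)
// to iterate; each seed climbs to its mode; modes closer than merge_tol are
// fused (order of discovery wins); every point is assigned to the nearest mode.
// [[Rcpp::export(name = ".cpp_mean_shift")]]
List cpp_mean_shift(NumericMatrix X, IntegerVector seeds, double bandwidth,
                    int max_iter, double tol) {
  int n = X.nrow(), d = X.ncol();
  double bw2 = bandwidth * bandwidth;
  std::vector< std::vector<double> > modes;
  std::vector<double> m(d), newm(d);
  for (int si = 0; si < seeds.size(); ++si) {
    int s = seeds[si] - 1;
    for (int j = 0; j < d; ++j) m[j] = X(s, j);
    for (int it = 0; it < max_iter; ++it) {
      std::fill(newm.begin(), newm.end(), 0.0);
      int cnt = 0;
      for (int i = 0; i < n; ++i) {
        double dist2 = 0.0;
        for (int j = 0; j < d; ++j) { double t = X(i, j) - m[j]; dist2 += t * t; }
        if (dist2 <= bw2) { for (int j = 0; j < d; ++j) newm[j] += X(i, j); ++cnt; }
      }
      if (cnt == 0) break;
      double move2 = 0.0;
      for (int j = 0; j < d; ++j) {
        newm[j] /= cnt;
        double t = newm[j] - m[j];
        move2 += t * t;
        m[j] = newm[j];
      }
      if (move2 < tol * tol) break;
    }
    bool merged = false;
    for (size_t k = 0; k < modes.size(); ++k) {
      double dist2 = 0.0;
      for (int j = 0; j < d; ++j) { double t = modes[k][j] - m[j]; dist2 += t * t; }
      if (dist2 <= bw2) { merged = true; break; }
    }
    if (!merged) modes.push_back(std::vector<double>(m));
  }
  int K = (int)modes.size();
  IntegerVector assign(n);
  NumericMatrix modemat(std::max(K, 1), d);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < d; ++j) modemat(k, j) = modes[k][j];
  for (int i = 0; i < n; ++i) {
    int best = 1; double bestd = R_PosInf;
    for (int k = 0; k < K; ++k) {
      double dist2 = 0.0;
      for (int j = 0; j < d; ++j) { double t = X(i, j) - modes[k][j]; dist2 += t * t; }
      if (dist2 < bestd) { bestd = dist2; best = k + 1; }
    }
    assign[i] = K > 0 ? best : 0;
  }
  return List::create(_["modes"] = modemat, _["assignment"] = assign, _["k"] = K);
}

// Generic backward-warp resampler: out(h, w, c) = img(ymap(h, w), xmap(h, w), c)
// with bilinear or nearest interpolation; maps are 1-based row/col coordinates;
// out-of-range samples take `fill`.
// [[Rcpp::export(name = ".cpp_resample_map")]]
NumericVector cpp_resample_map(NumericVector img, NumericMatrix ymap, NumericMatrix xmap,
                               bool bilinear, double fill) {
  IntegerVector xd = img.attr("dim");
  int H = xd[0], W = xd[1], C = xd.size() >= 3 ? xd[2] : 1;
  int Ho = ymap.nrow(), Wo = ymap.ncol();
  NumericVector out((size_t)Ho * Wo * C);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const double* ic = img.begin() + (size_t)c * H * W;
    double* oc = out.begin() + (size_t)c * Ho * Wo;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        double sy = ymap(h, w) - 1.0, sx = xmap(h, w) - 1.0;
        double v = fill;
        if (bilinear) {
          if (sy >= 0 && sy <= H - 1 && sx >= 0 && sx <= W - 1) {
            int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
            int y1 = std::min(y0 + 1, H - 1), x1 = std::min(x0 + 1, W - 1);
            double ay = sy - y0, ax = sx - x0;
            v = ic[y0 + (size_t)H * x0] * (1 - ay) * (1 - ax)
              + ic[y1 + (size_t)H * x0] * ay * (1 - ax)
              + ic[y0 + (size_t)H * x1] * (1 - ay) * ax
              + ic[y1 + (size_t)H * x1] * ay * ax;
          }
        } else {
          int yn = (int)std::lround(sy), xn = (int)std::lround(sx);
          if (yn >= 0 && yn < H && xn >= 0 && xn < W) v = ic[yn + (size_t)H * xn];
        }
        oc[h + (size_t)Ho * w] = v;
      }
    }
  }
  return out;
}
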