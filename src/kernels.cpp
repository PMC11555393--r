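// Hot-path kernels for the runnable network.
//
// Tensors arrive as R numeric arrays in the package's internal
// [height, width, batch, channels] layout (column-major), so the
// innermost spatial index is contiguous.  The R implementations in
// R/nn-ops.R ("*_ref") are the reference semantics; the test suite
// checks these kernels against them and against finite differences.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d tensor");
  return d;
}

// grouped convolution, stride 1, odd kernel, "same" padding
// x: [H,W,N,Cin], W: [k,k,Cin/g,Cout] -> out [H,W,N,Cout]
// [[Rcpp::export(name = ".conv2d_fwd_cpp")]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector Wt,
                             NumericVector b, int groups) {
  IntegerVector dx = dims4(x), dw = dims4(Wt);
  const int H = dx[0], Wd = dx[1], N = dx[2], Cin = dx[3];
  const int k = dw[0], cing = dw[2], cout = dw[3];
  const int coutg = cout / groups;
  const int p = (k - 1) / 2;
  if (Cin != cing * groups) stop("channel/group mismatch");
  NumericVector out(static_cast<R_xlen_t>(H) * Wd * N * cout);
  out.attr("dim") = IntegerVector::create(H, Wd, N, cout);
  const double* px = x.begin();
  double* po = out.begin();
  const double* pw = Wt.begin();
  const R_xlen_t planeX = static_cast<R_xlen_t>(H) * Wd;  // per (n,c)
  for (int gi = 0; gi < groups; ++gi) {
    for (int cg = 0; cg < coutg; ++cg) {
      const int co = gi * coutg + cg;
      // bias fill
      double* ob = po + planeX * N * co;
      const double bv = b[co];
      for (R_xlen_t i = 0; i < planeX * N; ++i) ob[i] = bv;
      for (int ci_g = 0; ci_g < cing; ++ci_g) {
        const int ci = gi * cing + ci_g;
        const double* xb = px + planeX * N * ci;
        for (int dy = -p; dy <= p; ++dy) {
          for (int dxo = -p; dxo <= p; ++dxo) {
            const double wv =
              pw[(dy + p) + k * ((dxo + p) + k * (ci_g + cing * co))];
            if (wv == 0.0) continue;
            const int h0 = std::max(0, -dy), h1 = H - 1 - std::max(0, dy);
            const int w0 = std::max(0, -dxo), w1 = Wd - 1 - std::max(0, dxo);
            if (h1 < h0 || w1 < w0) continue;
            const int len = h1 - h0 + 1;
            for (int n = 0; n < N; ++n) {
              for (int w = w0; w <= w1; ++w) {
                double* o = ob + h0 + H * (w + Wd * n);
                const double* s = xb + (h0 + dy) + H * ((w + dxo) + Wd * n);
                for (int h = 0; h < len; ++h) o[h] += wv * s[h];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// backward: returns list(dx, dW, db)
// [[Rcpp::export(name = ".conv2d_bwd_cpp")]]
List conv2d_bwd_cpp(NumericVector x, NumericVector Wt, NumericVector dout,
                    int groups) {
  IntegerVector dx_ = dims4(x), dw = dims4(Wt);
  const int H = dx_[0], Wd = dx_[1], N = dx_[2];
  const int k = dw[0], cing = dw[2], cout = dw[3];
  const int coutg = cout / groups;
  const int p = (k - 1) / 2;
  NumericVector dxv(x.size());
  dxv.attr("dim") = x.attr("dim");
  NumericVector dW(Wt.size());
  dW.attr("dim") = Wt.attr("dim");
  NumericVector db(cout);
  const double* px = x.begin();
  const double* pd = dout.begin();
  const double* pw = Wt.begin();
  double* pdx = dxv.begin();
  double* pdw = dW.begin();
  const R_xlen_t planeX = static_cast<R_xlen_t>(H) * Wd;
  for (int gi = 0; gi < groups; ++gi) {
    for (int cg = 0; cg < coutg; ++cg) {
      const int co = gi * coutg + cg;
      const double* dob = pd + planeX * N * co;
      double acc = 0.0;
      for (R_xlen_t i = 0; i < planeX * N; ++i) acc += dob[i];
      db[co] = acc;
      for (int ci_g = 0; ci_g < cing; ++ci_g) {
        const int ci = gi * cing + ci_g;
        const double* xb = px + planeX * N * ci;
        double* dxb = pdx + planeX * N * ci;
        for (int dy = -p; dy <= p; ++dy) {
          for (int dxo = -p; dxo <= p; ++dxo) {
            const R_xlen_t widx =
              (dy + p) + k * ((dxo + p) + k * (ci_g + cing * co));
            const double wv = pw[widx];
            const int h0 = std::max(0, -dy), h1 = H - 1 - std::max(0, dy);
            const int w0 = std::max(0, -dxo), w1 = Wd - 1 - std::max(0, dxo);
            if (h1 < h0 || w1 < w0) continue;
            const int len = h1 - h0 + 1;
            double wacc = 0.0;
            for (int n = 0; n < N; ++n) {
              for (int w = w0; w <= w1; ++w) {
                const double* o = dob + h0 + H * (w + Wd * n);
                const double* s = xb + (h0 + dy) + H * ((w + dxo) + Wd * n);
                double* ds = dxb + (h0 + dy) + H * ((w + dxo) + Wd * n);
                for (int h = 0; h < len; ++h) {
                  wacc += o[h] * s[h];
                  ds[h] += wv * o[h];
                }
              }
            }
            pdw[widx] = wacc;
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dxv, _["dW"] = dW, _["db"] = db);
}

// non-affine batch norm over (H, W, N) per channel, training mode
// [[Rcpp::export(name = ".bn_fwd_cpp")]]
List bn_fwd_cpp(NumericVector x, double eps) {
  IntegerVector d = dims4(x);
  const R_xlen_t M = static_cast<R_xlen_t>(d[0]) * d[1] * d[2];
  const int C = d[3];
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  NumericVector mu(C), va(C), ivar(C);
  const double* px = x.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = px + M * c;
    double s = 0.0;
    for (R_xlen_t i = 0; i < M; ++i) s += xc[i];
    const double m = s / M;
    double v = 0.0;
    for (R_xlen_t i = 0; i < M; ++i) { const double t = xc[i] - m; v += t * t; }
    v /= M;
    const double iv = 1.0 / std::sqrt(v + eps);
    double* oc = po + M * c;
    for (R_xlen_t i = 0; i < M; ++i) oc[i] = (xc[i] - m) * iv;
    mu[c] = m; va[c] = v; ivar[c] = iv;
  }
  return List::create(_["out"] = out, _["mu"] = mu, _["var"] = va,
                      _["ivar"] = ivar);
}

// [[Rcpp::export(name = ".bn_bwd_cpp")]]
NumericVector bn_bwd_cpp(NumericVector dout, NumericVector xhat,
                         NumericVector ivar) {
  IntegerVector d = dims4(dout);
  const R_xlen_t M = static_cast<R_xlen_t>(d[0]) * d[1] * d[2];
  const int C = d[3];
  NumericVector dx(dout.size());
  dx.attr("dim") = dout.attr("dim");
  const double* pd = dout.begin();
  const double* ph = xhat.begin();
  double* px = dx.begin();
  for (int c = 0; c < C; ++c) {
    const double* dc = pd + M * c;
    const double* hc = ph + M * c;
    double* xc = px + M * c;
    double s1 = 0.0, s2 = 0.0;
    for (R_xlen_t i = 0; i < M; ++i) { s1 += dc[i]; s2 += dc[i] * hc[i]; }
    const double iv = ivar[c];
    for (R_xlen_t i = 0; i < M; ++i)
      xc[i] = (dc[i] - s1 / M - hc[i] * s2 / M) * iv;
  }
  return dx;
}

// 2x2 stride-2 ceil-mode pooling; kind 0 = max, 1 = avg
// returns list(out, arg) where arg codes the winning cell (max) or the
// valid-cell count (avg)
// [[Rcpp::export(name = ".pool2_fwd_cpp")]]
List pool2_fwd_cpp(NumericVector x, int kind) {
  IntegerVector d = dims4(x);
  const int H = d[0], Wd = d[1], NC = d[2] * d[3];
  const int Ho = (int)std::ceil((H - 2) / 2.0) + 1;
  const int Wo = (int)std::ceil((Wd - 2) / 2.0) + 1;
  NumericVector out(static_cast<R_xlen_t>(Ho) * Wo * NC);
  out.attr("dim") = IntegerVector::create(Ho, Wo, d[2], d[3]);
  IntegerVector arg(out.size());
  const double* px = x.begin();
  double* po = out.begin();
  int* pa = arg.begin();
  for (int q = 0; q < NC; ++q) {
    const double* xq = px + static_cast<R_xlen_t>(H) * Wd * q;
    double* oq = po + static_cast<R_xlen_t>(Ho) * Wo * q;
    int* aq = pa + static_cast<R_xlen_t>(Ho) * Wo * q;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double best = -INFINITY, sum = 0.0;
        int bidx = 0, cnt = 0;
        for (int j = 0; j < 2; ++j) {
          const int w = 2 * wo + j;
          if (w >= Wd) continue;
          for (int i = 0; i < 2; ++i) {
            const int h = 2 * ho + i;
            if (h >= H) continue;
            const double v = xq[h + H * w];
            ++cnt; sum += v;
            if (v > best) { best = v; bidx = i + 2 * j; }
          }
        }
        if (kind == 0) { oq[ho + Ho * wo] = best; aq[ho + Ho * wo] = bidx; }
        else { oq[ho + Ho * wo] = sum / cnt; aq[ho + Ho * wo] = cnt; }
      }
    }
  }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export(name = ".pool2_bwd_cpp")]]
NumericVector pool2_bwd_cpp(NumericVector dout, IntegerVector arg,
                            IntegerVector in_dim, int kind) {
  IntegerVector d = dims4(dout);
  const int Ho = d[0], Wo = d[1], NC = d[2] * d[3];
  const int H = in_dim[0], Wd = in_dim[1];
  NumericVector dx(static_cast<R_xlen_t>(H) * Wd * NC);
  dx.attr("dim") = in_dim;
  const double* pd = dout.begin();
  const int* pa = arg.begin();
  double* px = dx.begin();
  for (int q = 0; q < NC; ++q) {
    const double* dq = pd + static_cast<R_xlen_t>(Ho) * Wo * q;
    const int* aq = pa + static_cast<R_xlen_t>(Ho) * Wo * q;
    double* xq = px + static_cast<R_xlen_t>(H) * Wd * q;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const double g = dq[ho + Ho * wo];
        if (kind == 0) {
          const int bidx = aq[ho + Ho * wo];
          const int h = 2 * ho + (bidx % 2), w = 2 * wo + (bidx / 2);
          xq[h + H * w] += g;
        } else {
          const int cnt = aq[ho + Ho * wo];
          const double gv = g / cnt;
          for (int j = 0; j < 2; ++j) {
            const int w = 2 * wo + j;
            if (w >= Wd) continue;
            for (int i = 0; i < 2; ++i) {
              const int h = 2 * ho + i;
              if (h >= H) continue;
              xq[h + H * w] += gv;
            }
          }
        }
      }
    }
  }
  return dx;
}
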